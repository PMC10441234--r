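# Probe manifest for the epitranscriptomic array: every probe maps to a
# transcript/gene and carries a class; spike-in probes anchor normalization.

PROBE_CLASSES <- c("mRNA", "lncRNA", "spike_pos", "spike_neg")

# Transcripts carried to MeRIP-qPCR validation; present verbatim in the
# default manifest at fixed slots so worked examples are reproducible.
VALIDATION_IDS <- c(
  CSMD1 = "ENST00000537824",
  CD27  = "ENST00000266557",
  USP44 = "ENST00000258499",
  TIAL1 = "ENST00000436547",
  MUC12 = "ENST00000536621"
)

DESIGN_COLUMNS <- c("probe_id", "transcript_id", "gene_symbol", "probe_class")

#' Construct an array design (probe manifest)
#'
#' An array design is the ordered probe manifest of one array layout: probe
#' id, target transcript id, gene symbol and probe class. Classes are
#' \code{mRNA}, \code{lncRNA}, \code{spike_pos} (methylated spike-in RNA,
#' recovered in the IP fraction) and \code{spike_neg} (unmethylated spike-in,
#' recovered in the supernatant). Every design must contain at least one
#' spike-in of each class, because channel normalization is anchored on them.
#'
#' @param probes data.frame with columns \code{probe_id}, \code{transcript_id},
#'   \code{gene_symbol}, \code{probe_class}.
#' @param design_name character label for the layout.
#' @return An object of class \code{array_design}: a list with elements
#'   \code{probes} and \code{design_name}.
#' @seealso [default_design()], [read_design()], [write_design()]
#' @export
array_design <- function(probes, design_name = "custom") {
  probes <- validate_design_probes(probes)
  structure(list(probes = probes, design_name = design_name),
            class = "array_design")
}

validate_design_probes <- function(probes) {
  if (!is.data.frame(probes)) stopf("probes must be a data.frame")
  missing_cols <- setdiff(DESIGN_COLUMNS, names(probes))
  if (length(missing_cols))
    stopf("probe manifest lacks column(s): %s", fmt_ids(missing_cols))
  probes <- probes[DESIGN_COLUMNS]
  for (col in DESIGN_COLUMNS)
    probes[[col]] <- as.character(probes[[col]])
  bad_class <- setdiff(unique(probes$probe_class), PROBE_CLASSES)
  if (length(bad_class))
    stopf("unknown probe_class value(s): %s", fmt_ids(bad_class))
  dup <- probes$probe_id[duplicated(probes$probe_id)]
  if (length(dup))
    stopf("duplicate probe_id: %s", fmt_ids(unique(dup)))
  for (cls in c("spike_pos", "spike_neg")) {
    if (!any(probes$probe_class == cls))
      stopf("design contains no %s spike-in probes", cls)
  }
  rownames(probes) <- NULL
  probes
}

#' Default synthetic array design
#'
#' Builds the default manifest emulating a commercial human mRNA
#' epitranscriptomic layout: 35,175 mRNA probes plus a configurable number
#' of positive and negative spike-in probes (8 each by default). Transcript
#' ids are deterministic \code{ENSTSIM}-style strings; the five transcripts
#' used for qPCR validation (see [validation_transcripts()]) are injected
#' verbatim at fixed slots. No randomness is involved: two calls always
#' return identical designs.
#'
#' @param n_mrna number of mRNA probes.
#' @param n_spike_pos,n_spike_neg number of spike-in probes per class.
#' @param design_name label for the layout.
#' @return An \code{array_design}.
#' @examples
#' d <- default_design(n_mrna = 100)
#' table(d$probes$probe_class)
#' @export
default_design <- function(n_mrna = 35175L, n_spike_pos = 8L,
                           n_spike_neg = 8L,
                           design_name = "epitx_8x60k_sim") {
  if (!is_count(n_mrna) || n_mrna < 1) stopf("n_mrna must be a positive count")
  if (!is_count(n_spike_pos) || n_spike_pos < 1 ||
      !is_count(n_spike_neg) || n_spike_neg < 1)
    stopf("spike-in counts must be positive")
  idx <- seq_len(n_mrna)
  tid <- sprintf("ENSTSIM%08d", idx)
  sym <- sprintf("SIMG%05d", idx)
  # fixed slots for the validation transcripts (1000, 2000, ... when the
  # design is large enough, otherwise the head of the manifest)
  k <- length(VALIDATION_IDS)
  slots <- if (n_mrna >= 1000L * k) 1000L * seq_len(k) else seq_len(min(k, n_mrna))
  tid[slots] <- VALIDATION_IDS[seq_along(slots)]
  sym[slots] <- names(VALIDATION_IDS)[seq_along(slots)]
  mrna <- data.frame(
    probe_id = sprintf("PRB%08d", idx),
    transcript_id = tid,
    gene_symbol = sym,
    probe_class = "mRNA",
    stringsAsFactors = FALSE
  )
  pos <- data.frame(
    probe_id = sprintf("SPKP%02d", seq_len(n_spike_pos)),
    transcript_id = sprintf("CTA850_%02d", seq_len(n_spike_pos)),
    gene_symbol = "CTA850",
    probe_class = "spike_pos",
    stringsAsFactors = FALSE
  )
  neg <- data.frame(
    probe_id = sprintf("SPKN%02d", seq_len(n_spike_neg)),
    transcript_id = sprintf("CTA650_%02d", seq_len(n_spike_neg)),
    gene_symbol = "CTA650",
    probe_class = "spike_neg",
    stringsAsFactors = FALSE
  )
  array_design(rbind(mrna, pos, neg), design_name = design_name)
}

#' Probe ids of one class
#' @param design an \code{array_design}.
#' @param classes probe classes to select.
#' @return character vector of probe ids.
#' @export
design_probe_ids <- function(design, classes) {
  stopifnot(inherits(design, "array_design"))
  classes <- match.arg(classes, PROBE_CLASSES, several.ok = TRUE)
  design$probes$probe_id[design$probes$probe_class %in% classes]
}

#' Write / read an array design as TSV
#'
#' The on-disk format is UTF-8 tab-separated text with the exact header
#' \code{probe_id transcript_id gene_symbol probe_class} and no row names,
#' so manifests diff cleanly under version control. \code{read_design}
#' validates the file: duplicated probe ids are a format error and a design
#' without both spike-in classes is rejected, naming the missing class.
#'
#' @param design an \code{array_design}.
#' @param path file path.
#' @return \code{write_design} returns \code{path} invisibly;
#'   \code{read_design} returns an \code{array_design}.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  write_tsv(design$probes, path)
}

#' @rdname write_design
#' @param design_name label for the layout read from \code{path}.
#' @export
read_design <- function(path, design_name = basename(path)) {
  if (!file.exists(path)) stopf("design file not found: %s", path)
  probes <- read.delim(path, colClasses = "character",
                       check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(probes), DESIGN_COLUMNS))
    stopf("design file header must be exactly: %s",
          paste(DESIGN_COLUMNS, collapse = "\t"))
  array_design(probes, design_name = design_name)
}

#' @export
print.array_design <- function(x, ...) {
  cls <- table(factor(x$probes$probe_class, levels = PROBE_CLASSES))
  cat(sprintf("Array design '%s': %d probes\n", x$design_name,
              nrow(x$probes)))
  cat(sprintf("  mRNA %d | lncRNA %d | spike_pos %d | spike_neg %d\n",
              cls[["mRNA"]], cls[["lncRNA"]], cls[["spike_pos"]],
              cls[["spike_neg"]]))
  invisible(x)
}

#' Microarray calls for the five qPCR-validated transcripts
#'
#' Returns the published microarray fold changes, direction calls and
#' p-values of the five transcripts (CD27, CSMD1, USP44, TIAL1, MUC12)
#' selected for MeRIP-qPCR validation, shipped as a plain-text fixture.
#' Useful as a worked classification example for [classify_direction()].
#'
#' @return data.frame with columns \code{transcript_id}, \code{gene_symbol},
#'   \code{fold_change}, \code{regulation}, \code{p_value}.
#' @examples
#' v <- validation_transcripts()
#' classify_direction(v$fold_change, v$p_value)
#' @export
validation_transcripts <- function() {
  path <- system.file("extdata", "validation_transcripts.tsv",
                      package = "meripchip", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "numeric",
                            "character", "numeric"))
}
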
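# Intensity matrices: probes x samples for one channel (IP or Sup), raw or
# spike-in normalized, with per-sample group labels carried as an attribute.

#' Construct an intensity matrix
#'
#' A numeric probes-by-samples matrix for a single channel. \code{channel}
#' records which fraction was hybridized in that dye (\code{"IP"} = Cy5,
#' \code{"Sup"} = Cy3), \code{scale} whether values are raw fluorescence
#' (nonnegative, linear) or spike-in normalized log2 values. Group labels
#' are a named character vector over the sample columns.
#'
#' @param values numeric matrix with probe ids as rownames and sample ids as
#'   colnames.
#' @param channel \code{"IP"} or \code{"Sup"}.
#' @param scale \code{"raw"} or \code{"normalized"}.
#' @param groups named character vector of group labels, names = sample ids.
#'   Defaults to the text before the final \code{_<number>} of each sample id.
#' @return An \code{intensity_matrix}.
#' @export
intensity_matrix <- function(values, channel = c("IP", "Sup"),
                             scale = c("raw", "normalized"),
                             groups = NULL) {
  channel <- match.arg(channel)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must carry probe ids (rownames) and sample ids (colnames)")
  if (scale == "raw" && any(values < 0))
    stopf("raw intensities must be nonnegative")
  if (is.null(groups)) groups <- groups_from_names(colnames(values))
  groups <- groups[colnames(values)]
  if (anyNA(groups)) stopf("groups must cover every sample column")
  structure(values, channel = channel, scale = scale, groups = groups,
            class = c("intensity_matrix", "matrix", "array"))
}

groups_from_names <- function(ids) {
  setNames(sub("_[0-9]+$", "", ids), ids)
}

im_channel <- function(x) attr(x, "channel")
im_scale <- function(x) attr(x, "scale")

#' Group labels of an intensity or quantification matrix
#' @param x object carrying a \code{groups} attribute.
#' @return named character vector, names = sample ids.
#' @export
sample_groups <- function(x) attr(x, "groups")

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("Intensity matrix [%s, %s]: %d probes x %d samples\n",
              im_channel(x), im_scale(x), nrow(x), ncol(x)))
  g <- table(sample_groups(x))
  cat("  groups:", paste(sprintf("%s=%d", names(g), g), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an intensity matrix as TSV
#'
#' Layout: comment lines \code{# channel=...} and \code{# scale=...}, then a
#' header \code{probe_id} followed by sample ids, one row per probe. Sample
#' ids encode the group as \code{<group>_<index>} (e.g. \code{chol_1},
#' \code{skin_3}).
#'
#' @param x an \code{intensity_matrix}.
#' @param path file path.
#' @return \code{write_intensity_tsv} returns \code{path} invisibly;
#'   \code{read_intensity_tsv} an \code{intensity_matrix}.
#' @export
write_intensity_tsv <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# channel=%s", im_channel(x)), con)
  writeLines(sprintf("# scale=%s", im_scale(x)), con)
  df <- data.frame(probe_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_tsv
#' @export
read_intensity_tsv <- function(path) {
  if (!file.exists(path)) stopf("intensity file not found: %s", path)
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default) {
    hit <- grep(sprintf("^#\\s*%s=", key), meta, value = TRUE)
    if (length(hit)) sub(sprintf("^#\\s*%s=", key), "", hit[1]) else default
  }
  channel <- get_meta("channel", "IP")
  scale <- get_meta("scale", "raw")
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    stopf("first column of an intensity TSV must be probe_id")
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stopf("non-numeric intensities in %s", path)
  rownames(m) <- df$probe_id
  intensity_matrix(m, channel = channel, scale = scale)
}
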
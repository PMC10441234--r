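# Numeric QC gates applied before hybridization and after MeRIP:
# RNA purity ratios, labeling yield / specific activity, and spike-in
# enrichment efficiency. Each gate returns a small classed record so the
# pipeline report can echo the measured values next to their thresholds.

qc_result <- function(pass, reasons, metrics) {
  structure(list(pass = pass, reasons = reasons, metrics = metrics),
            class = "merip_qc")
}

#' @export
print.merip_qc <- function(x, ...) {
  cat(if (x$pass) "QC PASS" else "QC FAIL", "\n")
  for (k in names(x$metrics))
    cat(sprintf("  %s = %s\n", k, format(x$metrics[[k]])))
  if (length(x$reasons))
    cat("  reasons:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' RNA purity gate (spectrophotometric ratios)
#'
#' Pure RNA should have an A260/A280 ratio close to 2.0 — ratios between 1.8
#' and 2.1 inclusive are acceptable — and an A260/A230 ratio strictly above
#' 1.8. Failure reports name each violated rule.
#'
#' @param a260_a280,a260_a230 absorbance ratios (positive).
#' @return A \code{merip_qc} record with \code{pass}, \code{reasons} and the
#'   measured values.
#' @examples
#' rna_purity_qc(2.0, 2.0)$pass
#' @export
rna_purity_qc <- function(a260_a280, a260_a230) {
  if (!is_scalar_num(a260_a280) || a260_a280 <= 0 ||
      !is_scalar_num(a260_a230) || a260_a230 <= 0)
    stopf("absorbance ratios must be positive numbers")
  reasons <- character()
  if (a260_a280 < 1.8 || a260_a280 > 2.1)
    reasons <- c(reasons, sprintf(
      "A260/A280 = %.3f outside the acceptable range [1.8, 2.1]", a260_a280))
  if (a260_a230 <= 1.8)
    reasons <- c(reasons, sprintf(
      "A260/A230 = %.3f not above 1.8", a260_a230))
  qc_result(length(reasons) == 0L, reasons,
            list(a260_a280 = a260_a280, a260_a230 = a260_a230))
}

#' Specific activity of labeled cRNA
#'
#' Dye incorporation per mass of cRNA:
#' \deqn{SA = \frac{pmol\ dye\ per\ \mu l}{\mu g\ cRNA\ per\ \mu l}}
#'
#' @param dye_pmol_per_ul dye concentration (pmol/ul), nonnegative.
#' @param crna_ug_per_ul cRNA concentration (ug/ul), strictly positive.
#' @return pmol dye per ug cRNA.
#' @examples
#' specific_activity(4.0, 0.5)  # 8 pmol/ug
#' @export
specific_activity <- function(dye_pmol_per_ul, crna_ug_per_ul) {
  if (!is_scalar_num(dye_pmol_per_ul) || dye_pmol_per_ul < 0)
    stopf("dye concentration must be nonnegative")
  if (!is_scalar_num(crna_ug_per_ul) || crna_ug_per_ul <= 0)
    stopf("cRNA concentration must be positive")
  dye_pmol_per_ul / crna_ug_per_ul
}

#' Hybridization go/no-go gate on labeling yield and specific activity
#'
#' Two-color labeling proceeds unless the yield is below 825 ng AND the
#' specific activity is below 8.0 pmol dye per ug cRNA; one-color labeling
#' proceeds unless the yield is below 1.65 ug (1650 ng) AND the specific
#' activity is below 9.0. Both bounds are strict ("below"), so a measurement
#' exactly on a threshold passes. The conjunctive rule is applied literally;
#' \code{strict = TRUE} switches to the more conservative disjunction
#' (either shortfall stops hybridization).
#'
#' @param mode \code{"two_color"} or \code{"one_color"}.
#' @param yield_ng cRNA yield in nanograms.
#' @param dye_pmol_per_ul,crna_ug_per_ul concentrations defining the
#'   specific activity; alternatively supply \code{sa} directly.
#' @param sa specific activity (pmol/ug), overriding the concentrations.
#' @param strict if TRUE, stop when either metric is below threshold.
#' @return A \code{merip_qc} record; \code{$pass} is TRUE when hybridization
#'   may proceed, and the metrics echo measured values and thresholds.
#' @examples
#' labeling_qc("two_color", yield_ng = 900, sa = 7.0)$pass  # yield rescues
#' @export
labeling_qc <- function(mode = c("two_color", "one_color"), yield_ng,
                        dye_pmol_per_ul = NULL, crna_ug_per_ul = NULL,
                        sa = NULL, strict = FALSE) {
  mode <- match.arg(mode)
  if (!is_scalar_num(yield_ng) || yield_ng <= 0)
    stopf("yield_ng must be positive")
  if (is.null(sa))
    sa <- specific_activity(dye_pmol_per_ul, crna_ug_per_ul)
  if (!is_scalar_num(sa) || sa < 0) stopf("specific activity must be >= 0")
  th <- switch(mode,
               two_color = c(yield = 825, sa = 8.0),
               one_color = c(yield = 1650, sa = 9.0))
  low_yield <- yield_ng < th[["yield"]]
  low_sa <- sa < th[["sa"]]
  stop_hyb <- if (strict) (low_yield || low_sa) else (low_yield && low_sa)
  reasons <- character()
  if (stop_hyb) {
    if (low_yield)
      reasons <- c(reasons, sprintf("yield %.1f ng below %.0f ng",
                                    yield_ng, th[["yield"]]))
    if (low_sa)
      reasons <- c(reasons, sprintf(
        "specific activity %.2f below %.1f pmol/ug", sa, th[["sa"]]))
  }
  qc_result(!stop_hyb, reasons,
            list(mode = mode, yield_ng = yield_ng, specific_activity = sa,
                 yield_threshold_ng = th[["yield"]],
                 sa_threshold = th[["sa"]], strict = strict))
}

#' MeRIP spike-in enrichment efficiency gate
#'
#' qPCR of the methylated (positive) and unmethylated (negative) spike-in
#' controls checks that the immunoprecipitation actually enriched for m6A:
#' the gate passes when the positive/negative enrichment ratio reaches
#' \code{min_ratio} (inclusive bound).
#'
#' @param pos_enrichment,neg_enrichment nonnegative enrichment values
#'   (e.g. percent input) of the two controls.
#' @param min_ratio minimal acceptable positive/negative ratio.
#' @return A \code{merip_qc} record.
#' @export
merip_spikein_qc <- function(pos_enrichment, neg_enrichment,
                             min_ratio = 5.0) {
  if (!is_scalar_num(pos_enrichment) || pos_enrichment < 0 ||
      !is_scalar_num(neg_enrichment) || neg_enrichment < 0)
    stopf("enrichment values must be nonnegative")
  ratio <- pos_enrichment / max(neg_enrichment, 1e-12)
  pass <- ratio >= min_ratio
  reasons <- if (pass) character() else
    sprintf("positive/negative enrichment ratio %.2f below %.1f",
            ratio, min_ratio)
  qc_result(pass, reasons,
            list(pos_enrichment = pos_enrichment,
                 neg_enrichment = neg_enrichment,
                 ratio = ratio, min_ratio = min_ratio))
}

#' Serialize QC records to a key-value summary block
#'
#' @param records named list of \code{merip_qc} records.
#' @return character vector of \code{key=value} lines, one block per record.
#' @export
qc_summary <- function(records) {
  stopifnot(is.list(records), length(names(records)) == length(records))
  unlist(lapply(names(records), function(nm) {
    r <- records[[nm]]
    stopifnot(inherits(r, "merip_qc"))
    c(sprintf("%s.pass=%s", nm, tolower(as.character(r$pass))),
      vapply(names(r$metrics), function(k)
        sprintf("%s.%s=%s", nm, k, format(r$metrics[[k]], trim = TRUE)),
        character(1)),
      if (length(r$reasons))
        sprintf("%s.reason=%s", nm, r$reasons))
  }), use.names = FALSE)
}
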
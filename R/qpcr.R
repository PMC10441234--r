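# MeRIP-qPCR validation analysis: percent input, spike-in control
# normalization, and between-group comparison with figure-style star codes.

#' Percent input from IP and input Ct values
#'
#' The input aliquot is only a fraction of the material entering the IP, so
#' its Ct is first dilution-adjusted:
#' \deqn{Ct_{input}^{adj} = Ct_{input} - \log_E(1 / input\_fraction)}
#' \deqn{\%input = 100 \cdot E^{(Ct_{input}^{adj} - Ct_{IP})}}
#' with amplification efficiency E = 2 (perfect doubling) by default.
#' Adding a constant to both Ct values leaves the result unchanged.
#'
#' @param ct_ip,ct_input cycle-threshold values (> 0).
#' @param input_fraction fraction of material reserved as input, in (0, 1].
#' @param efficiency amplification factor per cycle.
#' @return percent input (nonnegative).
#' @examples
#' percent_input(20, 20, input_fraction = 0.1)  # 10
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.1,
                          efficiency = 2) {
  if (!is.numeric(ct_ip) || !is.numeric(ct_input) ||
      any(ct_ip <= 0) || any(ct_input <= 0))
    stopf("Ct values must be positive")
  if (!is_scalar_num(input_fraction) || input_fraction <= 0 ||
      input_fraction > 1)
    stopf("input_fraction must lie in (0, 1]")
  if (!is_scalar_num(efficiency) || efficiency <= 1)
    stopf("efficiency must exceed 1")
  adj <- ct_input - log(1 / input_fraction, base = efficiency)
  100 * efficiency^(adj - ct_ip)
}

#' Control-normalized relative enrichment from a Ct table
#'
#' Per sample and target, the replicate Ct values are converted to percent
#' input, replicates are averaged (mean of percent input, not of Ct), and
#' every target's mean percent input is divided by the same sample's
#' positive-control (CTA850) percent input, giving relative enrichment.
#' The negative control's percent input is reported as the background
#' floor, and samples whose positive/negative control ratio fails
#' [merip_spikein_qc()] are flagged.
#'
#' @param records a \code{qpcr_table} (long format: \code{sample_id},
#'   \code{group}, \code{target_id}, \code{role}, \code{replicate},
#'   \code{ct}).
#' @param input_fraction fraction of material reserved as input; defaults
#'   to the table's \code{input_fraction} attribute.
#' @param efficiency amplification factor per cycle.
#' @param pos_control,neg_control control target ids.
#' @param min_ratio spike-in QC threshold, see [merip_spikein_qc()].
#' @return data.frame of class \code{qpcr_norm}: one row per sample and
#'   non-control target with \code{pct_input}, \code{rel_enrichment},
#'   \code{pos_pct_input}, \code{neg_pct_input} and \code{qc_pass}.
#' @export
control_normalize <- function(records, input_fraction = NULL,
                              efficiency = 2, pos_control = "CTA850",
                              neg_control = "CTA650", min_ratio = 5.0) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "group", "target_id", "role", "replicate", "ct")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stopf("Ct table lacks column(s): %s", fmt_ids(missing_cols))
  input_fraction <- input_fraction %||%
    attr(records, "input_fraction") %||% 0.1

  samples <- unique(records$sample_id)
  for (ctl in c(pos_control, neg_control)) {
    lacking <- samples[!samples %in%
                         records$sample_id[records$target_id == ctl]]
    if (length(lacking))
      stopf("control target %s missing in sample(s): %s", ctl,
            fmt_ids(lacking))
  }

  # mean Ct -> percent input per (sample, target): pair replicate means
  mean_ct <- function(role) {
    sub <- records[records$role == role, ]
    stats::aggregate(ct ~ sample_id + group + target_id, data = sub,
                     FUN = mean)
  }
  ip <- mean_ct("IP")
  inp <- mean_ct("input")
  key <- function(d) paste(d$sample_id, d$target_id)
  m <- match(key(ip), key(inp))
  if (anyNA(m)) stopf("IP reactions without matching input reactions")
  # replicates are combined as the mean of replicate %input values
  pct_rep <- function(sample, target) {
    ip_ct <- records$ct[records$sample_id == sample &
                          records$target_id == target &
                          records$role == "IP"]
    in_ct <- records$ct[records$sample_id == sample &
                          records$target_id == target &
                          records$role == "input"]
    mean(percent_input(ip_ct, mean(in_ct), input_fraction, efficiency))
  }
  ip$pct_input <- mapply(pct_rep, ip$sample_id, ip$target_id)

  ctl_pct <- function(ctl) {
    v <- ip$pct_input[ip$target_id == ctl]
    setNames(v, ip$sample_id[ip$target_id == ctl])
  }
  pos_pct <- ctl_pct(pos_control)
  neg_pct <- ctl_pct(neg_control)
  qc_pass <- vapply(samples, function(s)
    merip_spikein_qc(pos_pct[[s]], neg_pct[[s]], min_ratio)$pass,
    logical(1))

  out <- ip[!ip$target_id %in% c(pos_control, neg_control), ]
  out$rel_enrichment <- out$pct_input / pos_pct[out$sample_id]
  out$pos_pct_input <- unname(pos_pct[out$sample_id])
  out$neg_pct_input <- unname(neg_pct[out$sample_id])
  out$qc_pass <- unname(qc_pass[out$sample_id])
  out$ct <- NULL
  rownames(out) <- NULL
  structure(out, input_fraction = input_fraction,
            class = c("qpcr_norm", "data.frame"))
}

#' Significance star code
#'
#' Figure-legend convention: \code{*} p < 0.05, \code{**} p < 0.01,
#' \code{***} p < 0.001, \code{****} p < 0.0001, \code{ns} otherwise.
#'
#' @param p p-values.
#' @return character vector of star codes.
#' @export
star_code <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Between-group comparison of relative enrichment for one target
#'
#' Two-sided Welch t-test on the per-sample relative enrichment of
#' \code{target_id}, cholesteatoma vs. skin. Samples failing the spike-in
#' QC are excluded by default.
#'
#' @param normalized a \code{qpcr_norm} from [control_normalize()].
#' @param target_id transcript to compare.
#' @param group1,group2 reference and case group labels.
#' @param exclude_flagged drop samples with \code{qc_pass == FALSE}.
#' @return An object of class \code{qpcr_compare}: group means, direction
#'   (sign of group2 - group1), p-value and star code.
#' @export
group_compare <- function(normalized, target_id, group1 = "skin",
                          group2 = "chol", exclude_flagged = TRUE) {
  stopifnot(inherits(normalized, "qpcr_norm"))
  d <- normalized[normalized$target_id == target_id, ]
  if (!nrow(d)) stopf("target %s not present in the normalized table", target_id)
  if (exclude_flagged) d <- d[d$qc_pass, ]
  x1 <- d$rel_enrichment[d$group == group1]
  x2 <- d$rel_enrichment[d$group == group2]
  if (length(x1) < 2 || length(x2) < 2)
    stopf("need at least 2 samples per group for %s (found %d and %d)",
          target_id, length(x1), length(x2))
  p <- test_transcript(x1, x2)
  diff <- mean(x2) - mean(x1)
  structure(list(target_id = target_id,
                 mean_group1 = mean(x1), mean_group2 = mean(x2),
                 n_group1 = length(x1), n_group2 = length(x2),
                 direction = if (diff > 0) "up" else if (diff < 0) "down" else "none",
                 p_value = p, stars = star_code(p),
                 group1 = group1, group2 = group2),
            class = "qpcr_compare")
}

#' @export
print.qpcr_compare <- function(x, ...) {
  cat(sprintf("%s: %s %.3f vs %s %.3f (%s, p = %.3g %s)\n",
              x$target_id, x$group2, x$mean_group2, x$group1, x$mean_group1,
              x$direction, x$p_value,
              if (x$stars == "ns") "ns" else x$stars))
  invisible(x)
}
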
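# Differential methylation / expression calling between the two groups on
# log2 normalized quantities, using fold-change plus p-value thresholds
# (FC >= 3 or <= 1/3 and p < 0.05 by default).

#' Between-group fold change on log2 values
#'
#' The ratio of geometric means, \code{2^(mean(group2) - mean(group1))}.
#' Swapping the groups gives the reciprocal.
#'
#' @param values_group1,values_group2 numeric log2 vectors (reference group
#'   first).
#' @return linear fold change (group2 / group1).
#' @export
fold_change <- function(values_group1, values_group2) {
  if (!length(values_group1) || !length(values_group2))
    stopf("both groups must be nonempty")
  2^(mean(values_group2) - mean(values_group1))
}

#' Two-sample test on one transcript's log2 values
#'
#' Two-sided Welch (unequal variance) t-test by default; Student's pooled
#' test with \code{var_equal = TRUE}. Degenerate inputs where both groups
#' are (numerically) constant return p = 1 when the means agree — no
#' evidence of a difference — and p = 0 when they differ.
#'
#' @param values_group1,values_group2 numeric log2 vectors of length >= 2.
#' @param var_equal use the pooled-variance Student test.
#' @return two-sided p-value.
#' @export
test_transcript <- function(values_group1, values_group2,
                            var_equal = FALSE) {
  if (length(values_group1) < 2 || length(values_group2) < 2)
    stopf("each group needs at least 2 values")
  degenerate <- function() {
    d <- mean(values_group2) - mean(values_group1)
    tol <- 1e-12 * max(1, abs(mean(values_group1)), abs(mean(values_group2)))
    if (abs(d) <= tol) 1 else 0
  }
  if (var(values_group1) + var(values_group2) < 1e-24) return(degenerate())
  tryCatch(
    t.test(values_group2, values_group1, var.equal = var_equal)$p.value,
    error = function(e) degenerate()
  )
}

#' Direction call from fold change and p-value
#'
#' Applies the filtering rule: positive direction when \code{fc >= fc_hi}
#' and \code{p < alpha}, negative when \code{fc <= fc_lo} and
#' \code{p < alpha}, otherwise \code{none}. Fold-change bounds are
#' inclusive, the p bound strict. Direction names depend on the axis:
#' hyper/hypo for methylation, up/down for expression.
#'
#' @param fc linear fold changes (group2/group1).
#' @param p p-values.
#' @param fc_hi,fc_lo fold-change thresholds (\code{fc_hi > 1 > fc_lo > 0}).
#' @param alpha significance level.
#' @param axis \code{"methylation"} or \code{"expression"}.
#' @return character vector of direction calls.
#' @examples
#' classify_direction(c(3.27, 0.023, 2.0), c(0.0009, 0.0004, 1e-4))
#' @export
classify_direction <- function(fc, p, fc_hi = 3, fc_lo = 1 / 3,
                               alpha = 0.05,
                               axis = c("methylation", "expression")) {
  axis <- match.arg(axis)
  check_thresholds(fc_hi, fc_lo, alpha)
  if (length(fc) != length(p)) stopf("fc and p must have equal length")
  lab <- if (axis == "methylation") c("hyper", "hypo") else c("up", "down")
  out <- rep("none", length(fc))
  out[fc >= fc_hi & p < alpha] <- lab[1]
  out[fc <= fc_lo & p < alpha] <- lab[2]
  out
}

check_thresholds <- function(fc_hi, fc_lo, alpha) {
  if (!(is_scalar_num(fc_hi) && is_scalar_num(fc_lo) &&
        fc_hi > 1 && fc_lo < 1 && fc_lo > 0))
    stopf("fold-change thresholds must satisfy fc_hi > 1 > fc_lo > 0")
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must lie in (0, 1)")
  invisible(NULL)
}

#' Call differential methylation or expression
#'
#' Per transcript: group means on the log2 scale, linear fold change
#' (group2/group1, cholesteatoma/skin by default), a two-sample p-value and
#' the direction call of [classify_direction()]. The test is Welch's by
#' default; \code{adjust = TRUE} adds a Benjamini-Hochberg column
#' \code{q_bh} (reported alongside, never used for the direction call,
#' which filters on raw p).
#'
#' @param mat transcripts-by-samples matrix of log2 values (e.g.
#'   \code{m6a_quantity} or \code{expression} from [quantify()]).
#' @param groups named group labels over the sample columns; defaults to the
#'   matrix's \code{groups} attribute.
#' @param group1,group2 labels of the reference and case group.
#' @param axis \code{"methylation"} or \code{"expression"}.
#' @param fc_hi,fc_lo,alpha thresholds, see [classify_direction()].
#' @param test \code{"welch"} or \code{"student"}.
#' @param adjust add BH-adjusted q-values.
#' @param design optional \code{array_design} used to attach gene symbols.
#' @return data.frame of class \code{merip_diff} with columns
#'   \code{transcript_id}, optional \code{gene_symbol},
#'   \code{mean_log2_group1}, \code{mean_log2_group2}, \code{log2_fc},
#'   \code{fold_change}, \code{p_value}, optional \code{q_bh},
#'   \code{direction}; thresholds and group labels are kept as attributes.
#' @export
call_differential <- function(mat, groups = NULL, group1 = "skin",
                              group2 = "chol",
                              axis = c("methylation", "expression"),
                              fc_hi = 3, fc_lo = 1 / 3, alpha = 0.05,
                              test = c("welch", "student"),
                              adjust = FALSE, design = NULL) {
  axis <- match.arg(axis)
  test <- match.arg(test)
  check_thresholds(fc_hi, fc_lo, alpha)
  groups <- groups %||% attr(mat, "groups")
  if (is.null(groups)) stopf("no group labels supplied")
  groups <- groups[colnames(mat)]
  i1 <- which(groups == group1)
  i2 <- which(groups == group2)
  if (length(i1) < 2 || length(i2) < 2)
    stopf("both groups need at least 2 samples (found %d '%s', %d '%s')",
          length(i1), group1, length(i2), group2)
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  p <- vapply(seq_len(nrow(mat)), function(t)
    test_transcript(mat[t, i1], mat[t, i2], var_equal = test == "student"),
    numeric(1))
  l2fc <- m2 - m1
  fc <- 2^l2fc
  out <- data.frame(transcript_id = rownames(mat),
                    mean_log2_group1 = unname(m1),
                    mean_log2_group2 = unname(m2),
                    log2_fc = unname(l2fc), fold_change = unname(fc),
                    p_value = p, stringsAsFactors = FALSE)
  if (!is.null(design)) {
    pr <- design$probes
    out$gene_symbol <- pr$gene_symbol[match(out$transcript_id,
                                            pr$transcript_id)]
    out <- out[c("transcript_id", "gene_symbol",
                 setdiff(names(out), c("transcript_id", "gene_symbol")))]
  }
  if (adjust) out$q_bh <- p.adjust(p, method = "BH")
  out$direction <- classify_direction(fc, p, fc_hi, fc_lo, alpha, axis)
  structure(out, axis = axis, fc_hi = fc_hi, fc_lo = fc_lo, alpha = alpha,
            test = test, group1 = group1, group2 = group2,
            class = c("merip_diff", "data.frame"))
}

direction_levels <- function(axis) {
  if (axis == "methylation") c("hyper", "hypo", "none")
  else c("up", "down", "none")
}

#' @export
print.merip_diff <- function(x, n = 6L, ...) {
  axis <- attr(x, "axis")
  cnt <- table(factor(x$direction, levels = direction_levels(axis)))
  cat(sprintf("Differential %s calls: %d transcripts (%s vs %s)\n", axis,
              nrow(x), attr(x, "group2"), attr(x, "group1")))
  cat(sprintf("  FC >= %.4g or <= %.4g, p < %g [%s t-test]\n",
              attr(x, "fc_hi"), attr(x, "fc_lo"), attr(x, "alpha"),
              attr(x, "test")))
  cat("  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @export
summary.merip_diff <- function(object, ...) {
  axis <- attr(object, "axis")
  cnt <- table(factor(object$direction, levels = direction_levels(axis)))
  structure(list(axis = axis, counts = cnt,
                 fc_hi = attr(object, "fc_hi"),
                 fc_lo = attr(object, "fc_lo"),
                 alpha = attr(object, "alpha"),
                 n = nrow(object)),
            class = "summary.merip_diff")
}

#' @export
print.summary.merip_diff <- function(x, ...) {
  cat(sprintf("%s: %d transcripts, %s\n", x$axis, x$n,
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' Volcano plot table
#'
#' Plot-ready columns: \code{log2_fc}, \code{neg_log10_p} (with p = 0
#' mapped to the cap, 320 by default) and the direction call; the per
#' direction tallies are attached as attribute \code{counts}.
#'
#' @param diff a \code{merip_diff}.
#' @param cap upper bound for \code{-log10(p)}.
#' @return data.frame with attribute \code{counts}.
#' @export
volcano_table <- function(diff, cap = 320) {
  stopifnot(inherits(diff, "merip_diff"))
  nl <- ifelse(diff$p_value <= 0, cap, pmin(-log10(diff$p_value), cap))
  out <- data.frame(transcript_id = diff$transcript_id,
                    log2_fc = diff$log2_fc, neg_log10_p = nl,
                    direction = diff$direction, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(diff$direction,
                                      levels = direction_levels(attr(diff, "axis"))))
  out
}

#' @export
plot.merip_diff <- function(x, cap = 320, ...) {
  v <- volcano_table(x, cap = cap)
  axis <- attr(x, "axis")
  lv <- direction_levels(axis)
  col <- setNames(c("red", "blue", "grey60"), lv)
  plot(v$log2_fc, v$neg_log10_p, pch = 16, cex = 0.4,
       col = col[v$direction],
       xlab = "log2 fold change", ylab = "-log10 p",
       main = sprintf("Differential %s", axis), ...)
  abline(v = log2(c(attr(x, "fc_lo"), attr(x, "fc_hi"))), lty = 2)
  abline(h = -log10(attr(x, "alpha")), lty = 2)
  legend("topright", legend = lv, col = col, pch = 16, cex = 0.8)
  invisible(x)
}
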
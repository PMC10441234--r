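# Four-quadrant association: cross-classification of transcripts by their
# differential-methylation and differential-expression calls.

QUADRANTS <- c("hyper_up", "hyper_down", "hypo_up", "hypo_down")

QUADRANT_COLORS <- c(hyper_up = "red", hyper_down = "green",
                     hypo_down = "blue", hypo_up = "purple")

#' Assign transcripts to methylation-expression quadrants
#'
#' A transcript enters a quadrant exactly when both its methylation call
#' (hyper/hypo) and its expression call (up/down) are significant;
#' otherwise it stays \code{unassigned} (retained, so counts are
#' conservative: quadrant counts plus unassigned always sum to the
#' transcript universe). All four quadrants are reported even when empty —
#' an empty hypo-up quadrant is a result, not a missing value.
#'
#' @param meth a \code{merip_diff} with axis \code{methylation}.
#' @param expr a \code{merip_diff} with axis \code{expression}, over the
#'   same transcript universe.
#' @return data.frame of class \code{quadrant_table} with columns
#'   \code{transcript_id}, \code{meth_direction}, \code{expr_direction},
#'   \code{quadrant}; the named count vector (four quadrants plus
#'   \code{unassigned}) is attached as attribute \code{counts}.
#' @export
quadrant_assign <- function(meth, expr) {
  stopifnot(inherits(meth, "merip_diff"), inherits(expr, "merip_diff"))
  if (!identical(attr(meth, "axis"), "methylation"))
    stopf("meth must carry methylation calls")
  if (!identical(attr(expr, "axis"), "expression"))
    stopf("expr must carry expression calls")
  only1 <- setdiff(meth$transcript_id, expr$transcript_id)
  only2 <- setdiff(expr$transcript_id, meth$transcript_id)
  if (length(only1) || length(only2))
    stopf("tables cover different transcripts; only in methylation: %s; only in expression: %s",
          if (length(only1)) fmt_ids(only1) else "-",
          if (length(only2)) fmt_ids(only2) else "-")
  e <- expr[match(meth$transcript_id, expr$transcript_id), ]
  both <- meth$direction != "none" & e$direction != "none"
  quadrant <- rep("unassigned", nrow(meth))
  quadrant[both] <- paste(meth$direction[both], e$direction[both], sep = "_")
  out <- data.frame(transcript_id = meth$transcript_id,
                    meth_direction = meth$direction,
                    expr_direction = e$direction,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  counts <- table(factor(quadrant, levels = c(QUADRANTS, "unassigned")))
  structure(out, counts = counts,
            class = c("quadrant_table", "data.frame"))
}

#' Quadrant counts
#' @param q a \code{quadrant_table}.
#' @return named integer vector over the four quadrants and
#'   \code{unassigned}.
#' @export
quadrant_counts <- function(q) {
  stopifnot(inherits(q, "quadrant_table"))
  attr(q, "counts")
}

#' @export
print.quadrant_table <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("Methylation x expression quadrants (%d transcripts)\n",
              nrow(x)))
  for (k in names(cnt)) cat(sprintf("  %-10s %d\n", k, cnt[[k]]))
  invisible(x)
}

#' Four-quadrant plot table
#'
#' Joins the two log2 fold changes for every transcript assigned to a
#' quadrant (unassigned transcripts are excluded) and attaches the figure
#' color key: red = hyper-up, green = hyper-down, blue = hypo-down (purple
#' for the typically empty hypo-up quadrant).
#'
#' @param q a \code{quadrant_table}.
#' @param meth,expr the \code{merip_diff} tables used to build \code{q}.
#' @return data.frame with columns \code{transcript_id},
#'   \code{log2_meth_fc}, \code{log2_expr_fc}, \code{quadrant},
#'   \code{color}.
#' @export
quadrant_plot_table <- function(q, meth, expr) {
  stopifnot(inherits(q, "quadrant_table"))
  keep <- q$quadrant != "unassigned"
  ids <- q$transcript_id[keep]
  data.frame(
    transcript_id = ids,
    log2_meth_fc = meth$log2_fc[match(ids, meth$transcript_id)],
    log2_expr_fc = expr$log2_fc[match(ids, expr$transcript_id)],
    quadrant = q$quadrant[keep],
    color = unname(QUADRANT_COLORS[q$quadrant[keep]]),
    stringsAsFactors = FALSE
  )
}

#' @export
plot.quadrant_table <- function(x, meth, expr, ...) {
  pt <- quadrant_plot_table(x, meth, expr)
  plot(pt$log2_meth_fc, pt$log2_expr_fc, col = pt$color, pch = 16,
       cex = 0.5, xlab = "log2 methylation FC", ylab = "log2 expression FC",
       main = "Methylation x expression association", ...)
  abline(h = 0, v = 0, lty = 3)
  legend("topleft", legend = names(QUADRANT_COLORS),
         col = QUADRANT_COLORS, pch = 16, cex = 0.8)
  invisible(x)
}
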
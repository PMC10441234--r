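# Agglomerative hierarchical clustering of samples / transcripts for
# heatmap rendering, with Newick serialization of the dendrograms.

#' Hierarchical clustering of one matrix axis
#'
#' Agglomerative clustering (via \code{stats::hclust}) of the transcripts
#' (rows) or samples (columns) of a log2 quantity matrix under the given
#' distance metric and linkage. Euclidean distance with complete linkage is
#' the default; both are configurable. For monotone linkages
#' (complete/average/single) merge heights are nondecreasing.
#'
#' @param mat transcripts-by-samples numeric matrix.
#' @param axis \code{"transcripts"} (cluster rows) or \code{"samples"}.
#' @param metric distance metric, passed to \code{stats::dist}.
#' @param linkage agglomeration method, passed to \code{stats::hclust}.
#' @return An object of class \code{merip_dendro}: merge sequence, merge
#'   heights, leaf order, labels, metric and linkage, plus the underlying
#'   \code{hclust} object.
#' @export
hierarchical_cluster <- function(mat, axis = c("transcripts", "samples"),
                                 metric = "euclidean",
                                 linkage = "complete") {
  axis <- match.arg(axis)
  if (!is.matrix(mat) || !is.numeric(mat)) stopf("mat must be a numeric matrix")
  x <- if (axis == "samples") t(mat) else mat
  if (nrow(x) < 2) stopf("need at least 2 %s to cluster", axis)
  if (any(!is.finite(x))) stopf("non-finite values in clustering input")
  h <- hclust(dist(x, method = metric), method = linkage)
  structure(list(merge = h$merge, height = h$height, order = h$order,
                 labels = h$labels, metric = metric, linkage = linkage,
                 axis = axis, hclust = h),
            class = "merip_dendro")
}

#' Leaf order of a dendrogram
#' @param d a \code{merip_dendro}.
#' @return labels in dendrogram leaf order.
#' @export
leaf_order <- function(d) {
  stopifnot(inherits(d, "merip_dendro"))
  d$labels[d$order]
}

#' Cut a dendrogram into k groups
#' @param d a \code{merip_dendro}.
#' @param k number of clusters.
#' @return named integer cluster memberships.
#' @export
cut_groups <- function(d, k) {
  stopifnot(inherits(d, "merip_dendro"))
  cutree(d$hclust, k = k)
}

#' Serialize a dendrogram as Newick
#'
#' Branch lengths encode the merge heights.
#'
#' @param d a \code{merip_dendro}.
#' @return single Newick string.
#' @export
as_newick <- function(d) {
  stopifnot(inherits(d, "merip_dendro"))
  ape::write.tree(ape::as.phylo(d$hclust))
}

#' @export
print.merip_dendro <- function(x, ...) {
  cat(sprintf("Dendrogram over %d %s (%s distance, %s linkage)\n",
              length(x$labels), x$axis, x$metric, x$linkage))
  invisible(x)
}

# z-score rows; numerically constant rows become all zeros rather than NaN
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Heatmap-ready matrix with dendrograms
#'
#' Selects the \code{top_n} transcripts (by ascending p-value when a
#' \code{merip_diff} is supplied, otherwise the first rows), z-scores each
#' row (constant rows map to zero), clusters both axes of the z-scored
#' matrix and returns it in dendrogram leaf order.
#'
#' @param mat transcripts-by-samples log2 matrix.
#' @param diff optional \code{merip_diff} supplying the p-value ranking.
#' @param top_n number of transcripts to keep.
#' @param metric,linkage clustering parameters, see
#'   [hierarchical_cluster()].
#' @return An object of class \code{merip_heatmap}: the ordered z-score
#'   matrix plus \code{row_dendro} and \code{col_dendro}.
#' @export
heatmap_matrix <- function(mat, diff = NULL, top_n = min(100L, nrow(mat)),
                           metric = "euclidean", linkage = "complete") {
  if (!is_count(top_n) || top_n < 1) stopf("top_n must be a positive count")
  if (top_n > nrow(mat)) stopf("top_n exceeds the transcript count")
  ids <- if (!is.null(diff)) {
    stopifnot(inherits(diff, "merip_diff"))
    ranked <- diff$transcript_id[order(diff$p_value)]
    intersect(ranked, rownames(mat))[seq_len(top_n)]
  } else {
    rownames(mat)[seq_len(top_n)]
  }
  z <- zscore_rows(mat[ids, , drop = FALSE])
  rd <- if (length(ids) >= 2)
    hierarchical_cluster(z, "transcripts", metric, linkage) else NULL
  cd <- hierarchical_cluster(z, "samples", metric, linkage)
  ord <- z[if (is.null(rd)) ids else leaf_order(rd), leaf_order(cd),
           drop = FALSE]
  structure(list(matrix = ord, row_dendro = rd, col_dendro = cd),
            class = "merip_heatmap")
}

#' @export
print.merip_heatmap <- function(x, ...) {
  cat(sprintf("Heatmap matrix: %d transcripts x %d samples (row z-scores)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
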
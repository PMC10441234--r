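# Gene-set over-representation by Fisher's exact test over GMT files,
# with -log10(p) enrichment scores.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated
#' \code{set_id<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate genes
#' within a line are removed with a warning; a line with fewer than three
#' fields is a format error reported with its line number. An empty file is
#' a valid empty collection.
#'
#' @param path GMT file path.
#' @return A named list of class \code{gene_sets}; each element is a list
#'   with \code{set_id}, \code{description} and \code{genes}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stopf("GMT line %d has %d field(s); need set_id, description and at least one gene",
            i, length(f))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warnf("GMT line %d (%s): duplicate genes removed", i, f[1])
      genes <- unique(genes)
    }
    if (!length(genes)) stopf("GMT line %d (%s) has no genes", i, f[1])
    list(set_id = f[1], description = f[2], genes = genes)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "set_id")
  structure(sets, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("%d gene set(s)\n", length(x)))
  for (s in utils::head(x, 10))
    cat(sprintf("  %s (%d genes): %s\n", s$set_id, length(s$genes),
                s$description))
  invisible(x)
}

#' Over-representation of gene sets in a query list
#'
#' For each set, counts the overlap k between the query and the set's
#' members (both intersected with the universe) and computes the one-sided
#' hypergeometric upper-tail probability
#' \deqn{p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' — Fisher's exact test for over-representation — where n is the query
#' size, K the set size and N the universe size. \code{alternative =
#' "two.sided"} switches to the two-sided Fisher test. Sets with no members
#' in the universe are skipped with a warning. Records are ordered by
#' ascending p; BH-adjusted q-values are reported alongside but the
#' \code{significant} flag uses the raw p at \code{alpha}.
#'
#' @param query character vector of gene symbols (must be a subset of
#'   \code{universe}).
#' @param sets a \code{gene_sets} collection (or plain list of character
#'   vectors).
#' @param universe background gene symbols — by convention all mRNA gene
#'   symbols present on the array, not the genome.
#' @param alternative \code{"over"} (one-sided over-representation) or
#'   \code{"two.sided"}.
#' @param alpha significance level for the flag.
#' @return data.frame of class \code{merip_enrichment} with columns
#'   \code{set_id}, \code{description}, \code{k}, \code{K}, \code{n},
#'   \code{N}, \code{p_value}, \code{q_bh}, \code{enrichment_score},
#'   \code{significant}.
#' @export
fisher_enrichment <- function(query, sets, universe,
                              alternative = c("over", "two.sided"),
                              alpha = 0.05) {
  alternative <- match.arg(alternative)
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  bad <- setdiff(query, universe)
  if (length(bad))
    stopf("query genes missing from the universe: %s", fmt_ids(bad))
  if (!length(sets)) {
    out <- data.frame(set_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), q_bh = numeric(),
                      enrichment_score = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("merip_enrichment", "data.frame")))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    genes <- if (is.list(s)) s$genes else s
    set_id <- if (is.list(s)) s$set_id else names(sets)[i] %||% sprintf("set%d", i)
    desc <- if (is.list(s)) s$description else ""
    members <- intersect(unique(genes), universe)
    K <- length(members)
    if (K == 0) {
      warnf("gene set %s has no members in the universe; skipped", set_id)
      return(NULL)
    }
    k <- length(intersect(query, members))
    p <- if (alternative == "over") {
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2)
      fisher.test(tab, alternative = "two.sided")$p.value
    }
    data.frame(set_id = set_id, description = desc, k = k, K = K,
               n = n, N = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(fisher_enrichment(query, list(), universe, alternative, alpha))
  out <- out[order(out$p_value, out$set_id), ]
  rownames(out) <- NULL
  out$q_bh <- p.adjust(out$p_value, method = "BH")
  out$enrichment_score <- enrichment_score(out$p_value)
  out$significant <- out$p_value < alpha
  structure(out, alternative = alternative, alpha = alpha,
            class = c("merip_enrichment", "data.frame"))
}

#' Enrichment score: -log10 of the p-value
#'
#' @param p_value p-values in (0, 1].
#' @return nonnegative scores, strictly decreasing in p.
#' @examples
#' enrichment_score(0.001)  # 3
#' @export
enrichment_score <- function(p_value) {
  if (!is.numeric(p_value) || any(p_value <= 0) || any(p_value > 1))
    stopf("p-values must lie in (0, 1]")
  -log10(p_value)
}

#' @export
print.merip_enrichment <- function(x, n = 10L, ...) {
  cat(sprintf("Gene-set enrichment: %d set(s), %d significant at p < %g\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}
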
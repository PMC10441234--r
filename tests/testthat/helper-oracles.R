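# Independent oracles and small fixtures used across the suite.

tiny_design <- function(n_mrna = 20L, n_pos = 2L, n_neg = 2L) {
  default_design(n_mrna = n_mrna, n_spike_pos = n_pos, n_spike_neg = n_neg)
}

# Direct textbook Welch statistic + t CDF, independent of stats::t.test
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

# Exhaustive hypergeometric upper-tail summation
oracle_hyper_tail <- function(k, K, N, n) {
  i <- seq(max(k, 0), min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force agglomerative clustering: returns the sorted merge heights and
# the cophenetic matrix implied by successive nearest-cluster merges.
oracle_agglomerative <- function(dm, linkage = "complete") {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best_d <- Inf; bi <- NA; bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        sub <- dm[clusters[[i]], clusters[[j]], drop = FALSE]
        d <- switch(linkage, complete = max(sub), single = min(sub),
                    average = mean(sub))
        if (d < best_d) { best_d <- d; bi <- i; bj <- j }
      }
    }
    for (a in clusters[[bi]]) for (b in clusters[[bj]])
      coph[a, b] <- coph[b, a] <- best_d
    heights <- c(heights, best_d)
    clusters[[bj]] <- c(clusters[[bj]], clusters[[bi]])
    clusters[[bi]] <- NULL
  }
  list(heights = sort(heights), coph = coph)
}

# Nested-loop quadrant intersection, independent of quadrant_assign
oracle_quadrants <- function(meth_dir, expr_dir) {
  stopifnot(length(meth_dir) == length(expr_dir))
  out <- c(hyper_up = 0L, hyper_down = 0L, hypo_up = 0L, hypo_down = 0L,
           unassigned = 0L)
  for (i in seq_along(meth_dir)) {
    if (meth_dir[i] == "none" || expr_dir[i] == "none") {
      out["unassigned"] <- out["unassigned"] + 1L
    } else {
      key <- paste(meth_dir[i], expr_dir[i], sep = "_")
      out[key] <- out[key] + 1L
    }
  }
  out
}

# Small raw channel matrix with explicit values over a tiny design
raw_matrix <- function(values, design, channel, samples = NULL) {
  samples <- samples %||% sprintf("chol_%d", seq_len(ncol(values)))
  rownames(values) <- design$probes$probe_id[seq_len(nrow(values))]
  colnames(values) <- samples
  intensity_matrix(values, channel = channel, scale = "raw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
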
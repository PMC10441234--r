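test_that("identical items merge first at height zero", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 6, 7))
  d <- hierarchical_cluster(m, "transcripts")
  expect_equal(d$height[1], 0)
  expect_setequal(d$labels[-d$merge[1, ]], c("a", "b"))
})

test_that("small instances match the brute-force agglomerative oracle", {
  set.seed(5)
  for (linkage in c("complete", "average", "single")) {
    for (trial in 1:5) {
      n <- sample(4:6, 1)
      m <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(sprintf("t%d", 1:n), NULL))
      dend <- hierarchical_cluster(m, "transcripts", linkage = linkage)
      dm <- as.matrix(dist(m))
      oracle <- oracle_agglomerative(dm, linkage)
      expect_equal(sort(dend$height), oracle$heights, tolerance = 1e-12)
      coph <- as.matrix(stats::cophenetic(dend$hclust))
      expect_equal(unname(coph[rownames(m), rownames(m)]),
                   unname(oracle$coph), tolerance = 1e-12)
    }
  }
})

test_that("clustering is invariant to input row order up to relabeling", {
  set.seed(6)
  m <- matrix(rnorm(6 * 5), 6, 5, dimnames = list(sprintf("t%d", 1:6), NULL))
  d1 <- hierarchical_cluster(m, "transcripts")
  perm <- sample(6)
  d2 <- hierarchical_cluster(m[perm, ], "transcripts")
  c1 <- as.matrix(stats::cophenetic(d1$hclust))
  c2 <- as.matrix(stats::cophenetic(d2$hclust))
  ids <- rownames(m)
  expect_equal(c1[ids, ids], c2[ids, ids], tolerance = 1e-12)
})

test_that("complete-linkage merge heights are nondecreasing", {
  set.seed(8)
  for (trial in 1:5) {
    m <- matrix(rnorm(40), 8, 5, dimnames = list(sprintf("t%d", 1:8), NULL))
    d <- hierarchical_cluster(m, "transcripts", linkage = "complete")
    expect_true(all(diff(d$height) >= -1e-12))
  }
  expect_error(hierarchical_cluster(matrix(1, 1, 3,
                                           dimnames = list("a", NULL))),
               "at least 2")
})

test_that("dendrograms serialize to Newick with all leaves", {
  m <- matrix(rnorm(20), 5, 4, dimnames = list(sprintf("t%d", 1:5), NULL))
  d <- hierarchical_cluster(m, "transcripts")
  nwk <- as_newick(d)
  expect_match(nwk, "^\\(")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(m))
  expect_setequal(leaf_order(d), rownames(m))
})

test_that("heatmap rows are z-scored, ranked by p and dendrogram-ordered", {
  d <- tiny_design(n_mrna = 40)
  sim <- simulate_experiment(d, sim_config(n_hyper = 8, seed = 29))
  q <- quantify(sim)
  diff <- call_differential(q$m6a_quantity)
  hm <- heatmap_matrix(q$m6a_quantity, diff, top_n = 10)
  expect_equal(dim(hm$matrix), c(10, 10))
  expect_equal(unname(rowMeans(hm$matrix)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(hm$matrix, 1, sd)), rep(1, 10), tolerance = 1e-9)
  # rows are the smallest p-values
  topp <- diff$transcript_id[order(diff$p_value)][1:10]
  expect_setequal(rownames(hm$matrix), topp)
  expect_equal(rownames(hm$matrix), leaf_order(hm$row_dendro))
  expect_equal(colnames(hm$matrix), leaf_order(hm$col_dendro))
  expect_error(heatmap_matrix(q$m6a_quantity, diff, top_n = 0), "positive")
  # constant rows z-score to zero
  cm <- matrix(c(1, 1, 1, 1, 2, 1, 4, 3), 2, 4, byrow = TRUE,
               dimnames = list(c("k1", "k2"), sprintf("s%d", 1:4)))
  hm2 <- heatmap_matrix(cm, top_n = 2)
  expect_equal(unname(hm2$matrix["k1", ]), rep(0, 4))
})

test_that("sample dendrograms separate the two groups on planted data", {
  d <- tiny_design(n_mrna = 200)
  split_ok <- 0L
  for (seed in 1:20) {
    sim <- simulate_experiment(d, sim_config(n_hyper = 20, n_hypo = 20,
                                             seed = 1000 + seed))
    q <- quantify(sim)
    dend <- hierarchical_cluster(q$m6a_quantity, "samples")
    k2 <- cut_groups(dend, 2)
    grp <- sample_groups(sim$ip_raw)[names(k2)]
    if (length(unique(tapply(k2, grp, function(v) paste(sort(unique(v)),
                                                        collapse = "")))) == 2 &&
        all(tapply(k2, grp, function(v) length(unique(v))) == 1))
      split_ok <- split_ok + 1L
  }
  expect_gte(split_ok, 19L)
})
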
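test_that("spike-in normalization matches the log2 subtraction formula", {
  d <- tiny_design(n_mrna = 3, n_pos = 2, n_neg = 2)
  # rows: 3 mRNA, 2 spike_pos, 2 spike_neg; both spikes at 1024
  vals <- matrix(c(1024, 2048, 512, 1024, 1024, 7, 7,
                   1024, 4096, 256, 1024, 1024, 7, 7), ncol = 2)
  raw <- raw_matrix(vals, d, "IP", c("chol_1", "chol_2"))
  norm <- normalize_channel(raw, d)
  expect_equal(unclass(norm)[1:3, 1], c(0, 1, -1), ignore_attr = TRUE)
  expect_equal(unclass(norm)[1:3, 2], c(0, 2, -2), ignore_attr = TRUE)
  # spike rows retained
  expect_equal(nrow(norm), nrow(raw))
  expect_equal(attr(norm, "scale"), "normalized")
})

test_that("normalization is invariant to per-sample rescaling", {
  d <- tiny_design(n_mrna = 25)
  sim <- simulate_experiment(d, sim_config(n_hyper = 4, seed = 21))
  base <- normalize_channel(sim$ip_raw, d)
  set.seed(99)
  for (trial in 1:20) {
    fac <- runif(ncol(sim$ip_raw), 0.1, 10)
    scaled <- intensity_matrix(sweep(unclass(sim$ip_raw), 2, fac, `*`),
                               "IP", "raw", sample_groups(sim$ip_raw))
    expect_equal(unclass(normalize_channel(scaled, d)), unclass(base),
                 tolerance = 1e-9)
  }
})

test_that("normalization rejects bad inputs", {
  d <- tiny_design(n_mrna = 3)
  vals <- matrix(1024, 7, 2)
  raw <- raw_matrix(vals, d, "IP", c("chol_1", "skin_1"))
  expect_error(normalize_channel(normalize_channel(raw, d), d),
               "already normalized")
  neg <- unclass(raw); neg[1, 1] <- -5
  expect_error(intensity_matrix(neg, "IP", "raw"), "nonnegative")
  # matrix without any spike rows for the channel
  sub <- unclass(raw)[1:3, , drop = FALSE]
  raw_sub <- intensity_matrix(sub, "IP", "raw")
  expect_error(normalize_channel(raw_sub, d), "spike-in")
})

test_that("m6A percentage depends only on ip - sup and maps to [0, 100]", {
  d <- tiny_design(n_mrna = 4, n_pos = 1, n_neg = 1)
  mk <- function(values, channel) {
    m <- matrix(values, ncol = 1)
    raw_matrix(2^m, d, channel, "chol_1")
  }
  # with single spikes at 2^0, normalized value = log2(raw)
  ip <- normalize_channel(mk(c(5, 5 + log2(3), 5, 0, 0, 0), "IP"), d)
  sup <- normalize_channel(mk(c(5, 5, 5 - 4, 0, 0, 0), "Sup"), d)
  pct <- m6a_percentage(ip, sup, d)
  expect_equal(pct[1, 1], 50)
  expect_equal(pct[2, 1], 75)
  expect_gt(pct[3, 1], 50)  # monotone in the difference
  expect_true(all(pct >= 0 & pct <= 100))
})

test_that("expression level is the log2 of the channel sum", {
  d <- tiny_design(n_mrna = 2, n_pos = 1, n_neg = 1)
  mk <- function(values, channel)
    raw_matrix(matrix(values, ncol = 1), d, channel, "chol_1")
  ip <- normalize_channel(mk(c(1, 2^10, 1, 1), "IP"), d)
  sup <- normalize_channel(mk(c(1, 1, 1, 1), "Sup"), d)
  e <- expression_level(ip, sup, d)
  expect_equal(e[1, 1], 1)          # log2(2^0 + 2^0)
  expect_equal(e[2, 1], 10, tolerance = 1e-3)  # dominated by one addend
  q <- m6a_quantity(ip, d)
  expect_true(all(e >= q - 1e-12))
})

test_that("m6A quantity excludes spikes and preserves samples", {
  d <- tiny_design(n_mrna = 10)
  sim <- simulate_experiment(d, sim_config(seed = 2))
  qn <- m6a_quantity(normalize_channel(sim$ip_raw, d), d)
  expect_equal(nrow(qn), 10)
  expect_equal(ncol(qn), ncol(sim$ip_raw))
  expect_false(any(grepl("^SPK", rownames(qn))))
})

test_that("noise-free quantification recovers the planted fraction", {
  d <- tiny_design(n_mrna = 20)
  sim <- simulate_experiment(d, sim_config(n_hyper = 5, n_hypo = 5,
                                           noise_sd = 0, seed = 8))
  q <- quantify(sim)
  chol <- sample_groups(sim$ip_raw) == "chol"
  expect_equal(unname(q$m6a_pct[, chol]),
               matrix(sim$truth$meth_fraction_group2 * 100, 20, sum(chol)),
               tolerance = 1e-6)
  expect_equal(unname(q$m6a_pct[, !chol]),
               matrix(sim$truth$meth_fraction_group1 * 100, 20, sum(!chol)),
               tolerance = 1e-6)
})

test_that("multiple probes per transcript are averaged on the linear scale", {
  base <- tiny_design(n_mrna = 2, n_pos = 1, n_neg = 1)
  probes <- base$probes
  probes$transcript_id[2] <- probes$transcript_id[1]  # two probes, one transcript
  d <- array_design(probes)
  vals <- matrix(c(2^4, 2^6, 2^0, 2^0), ncol = 1)
  ip <- normalize_channel(raw_matrix(vals, d, "IP", "chol_1"), d)
  qn <- m6a_quantity(ip, d)
  expect_equal(nrow(qn), 1)
  expect_equal(qn[1, 1], log2((2^4 + 2^6) / 2))
})
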
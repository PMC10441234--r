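test_that("simulation is deterministic under a fixed seed", {
  d <- tiny_design(n_mrna = 40)
  cfg <- sim_config(n_hyper = 5, n_hypo = 5, n_up = 4, n_down = 4, seed = 9)
  s1 <- simulate_experiment(d, cfg)
  s2 <- simulate_experiment(d, cfg)
  expect_identical(unclass(s1$ip_raw), unclass(s2$ip_raw))
  expect_identical(unclass(s1$sup_raw), unclass(s2$sup_raw))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(d, sim_config(n_hyper = 5, n_hypo = 5,
                                          n_up = 4, n_down = 4, seed = 10))
  expect_false(identical(unclass(s1$ip_raw), unclass(s3$ip_raw)))
})

test_that("simulation does not disturb the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_experiment(tiny_design(), sim_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(true_meth_fc = 0), "positive ratio")
  expect_error(sim_config(meth_fraction_baseline = 1), "0, 1")
  expect_error(sim_config(n_per_group = 1), "at least 2")
  expect_error(sim_config(scale_range = c(2, 1)), "scale_range")
  d <- tiny_design(n_mrna = 10)
  expect_error(simulate_experiment(d, sim_config(n_hyper = 6, n_hypo = 6)),
               "exceeds")
})

test_that("noise-free simulation is exact: channel sums, fractions, ratios", {
  d <- tiny_design(n_mrna = 30)
  cfg <- sim_config(n_hyper = 5, n_hypo = 5, noise_sd = 0, seed = 3)
  sim <- simulate_experiment(d, cfg)
  tr <- d$probes$probe_class == "mRNA"
  # IP + Sup reconstructs total abundance; unplanted transcripts sit at 2^10
  total <- unclass(sim$ip_raw)[tr, ] + unclass(sim$sup_raw)[tr, ]
  none <- sim$truth$meth_label == "none"
  expect_equal(unname(total[none, ]),
               matrix(2^10, sum(none), ncol(total)), tolerance = 1e-9)
  # planted methylation raises total in the case group by (1 - f0 + f0*k)
  hyper <- sim$truth$meth_label == "hyper"
  chol <- sample_groups(sim$ip_raw) == "chol"
  expect_equal(unname(total[hyper, chol]),
               matrix(2^10 * 2.5, sum(hyper), sum(chol)), tolerance = 1e-9)
  # realized fractions match the truth table
  f <- unclass(sim$ip_raw)[tr, ] / total
  expect_equal(unname(f[hyper, chol]),
               matrix(sim$truth$meth_fraction_group2[hyper], sum(hyper),
                      sum(chol)), tolerance = 1e-12)
  expect_equal(unname(f[, !chol]),
               matrix(sim$truth$meth_fraction_group1, sum(tr), sum(!chol)),
               tolerance = 1e-12)
})

test_that("truth labels are consistent with the planted ratios", {
  d <- tiny_design(n_mrna = 50)
  cfg <- sim_config(n_hyper = 10, n_hypo = 10, n_up = 5, n_down = 5,
                    seed = 4)
  tr <- simulate_experiment(d, cfg)$truth
  expect_equal(sum(tr$meth_label == "hyper"), 10)
  expect_equal(sum(tr$meth_label == "hypo"), 10)
  expect_true(all((tr$meth_label == "hyper") ==
                    (tr$meth_effect >= cfg$true_meth_fc)))
  expect_true(all((tr$meth_label == "hypo") ==
                    (tr$meth_effect <= 1 / cfg$true_meth_fc)))
  # effect blocks are disjoint when counts allow
  expect_true(all(tr$expr_label[tr$meth_label != "none"] == "none"))
})

test_that("simulated qPCR recovers fractions and carries controls", {
  d <- tiny_design(n_mrna = 20)
  cfg <- sim_config(n_hyper = 3, noise_sd = 0, qpcr_ct_sd = 0,
                    qpcr_input_fraction = 1, seed = 6)
  sim <- simulate_experiment(d, cfg)
  ids <- sim$truth$transcript_id[c(1, 10)]
  tab <- simulate_qpcr(sim, ids, cfg, n_per_group = 4)
  # controls present with the full replicate block in every sample
  for (ctl in c("CTA850", "CTA650")) {
    per_sample <- table(tab$sample_id[tab$target_id == ctl & tab$role == "IP"])
    expect_true(all(per_sample == 3))
    expect_equal(length(per_sample), 8)
  }
  # zero noise, input fraction 1: percent input equals the methylated
  # fraction x 100 exactly
  row_ip <- tab$target_id == ids[2] & tab$role == "IP" &
    tab$sample_id == "skin_1" & tab$replicate == 1
  row_in <- tab$target_id == ids[2] & tab$role == "input" &
    tab$sample_id == "skin_1" & tab$replicate == 1
  expect_equal(percent_input(tab$ct[row_ip], tab$ct[row_in],
                             input_fraction = 1),
               50, tolerance = 1e-9)
  expect_error(simulate_qpcr(sim, "ENST_NOT_THERE", cfg),
               "unknown transcript")
})

test_that("simulated qPCR group difference recovers the planted direction", {
  d <- tiny_design(n_mrna = 20)
  hits <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(n_hyper = 1, seed = seed)
    sim <- simulate_experiment(d, cfg)
    id <- sim$truth$transcript_id[1]
    tab <- simulate_qpcr(sim, id, cfg)
    norm <- control_normalize(tab)
    cmp <- group_compare(norm, id)
    if (cmp$direction == "up") hits <- hits + 1L
  }
  expect_gte(hits, 6L)  # majority sign agreement
})
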
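test_that("percent input follows the dilution-corrected formula", {
  expect_equal(percent_input(20, 20, input_fraction = 1.0), 100)
  expect_equal(percent_input(20, 20, input_fraction = 0.1), 10)
  # one extra IP cycle halves the percent input
  expect_equal(percent_input(21, 20, input_fraction = 1.0), 50)
  # invariance to a shared Ct shift
  expect_equal(percent_input(24.3, 22.1, 0.1),
               percent_input(24.3 + 5, 22.1 + 5, 0.1))
  expect_error(percent_input(20, 20, input_fraction = 0), "0, 1")
  expect_error(percent_input(-1, 20), "positive")
})

test_that("star codes are a pure threshold function of p", {
  expect_equal(star_code(c(0.2, 0.04, 0.009, 0.0005, 0.00005)),
               c("ns", "*", "**", "***", "****"))
  set.seed(3)
  p <- runif(200, 0, 1)
  s <- star_code(p)
  expect_equal(s == "****", p < 1e-4)
  expect_equal(s == "***", p >= 1e-4 & p < 1e-3)
  expect_equal(s == "**", p >= 1e-3 & p < 1e-2)
  expect_equal(s == "ns", p >= 0.05)
})

make_ct_table <- function(targets, samples, groups, ct_fun,
                          input_fraction = 0.1) {
  grid <- expand.grid(replicate = 1:3, role = c("IP", "input"),
                      target_id = c(targets, "CTA850", "CTA650"),
                      sample_id = samples, stringsAsFactors = FALSE)
  grid$group <- groups[grid$sample_id]
  grid$ct <- mapply(ct_fun, grid$target_id, grid$role, grid$sample_id)
  structure(grid[c("sample_id", "group", "target_id", "role", "replicate",
                   "ct")],
            input_fraction = input_fraction,
            class = c("qpcr_table", "data.frame"))
}

test_that("control normalization divides by the positive control", {
  samples <- c("chol_1", "chol_2", "skin_1", "skin_2")
  groups <- setNames(c("chol", "chol", "skin", "skin"), samples)
  # every target amplifies identically to CTA850 -> relative enrichment 1;
  # CTA650 sits far later (low background)
  ct_fun <- function(target, role, sample) {
    if (role == "input") return(20)
    if (target == "CTA650") return(30)
    20 + log2(1 / 0.1)  # same Ct for T1 and CTA850
  }
  tab <- make_ct_table("T1", samples, groups, ct_fun, input_fraction = 0.1)
  norm <- control_normalize(tab)
  expect_equal(norm$rel_enrichment, rep(1, 4))
  expect_true(all(norm$qc_pass))
  expect_equal(nrow(norm), 4)  # controls are not reported as targets
  # missing control in one sample is a validation error naming it
  broken <- tab[!(tab$sample_id == "skin_2" & tab$target_id == "CTA850"), ]
  expect_error(control_normalize(broken), "skin_2")
})

test_that("replicates combine as the mean of percent input", {
  samples <- c("chol_1", "chol_2", "skin_1", "skin_2")
  groups <- setNames(c("chol", "chol", "skin", "skin"), samples)
  rep_ct <- c(20, 21, 22)
  i <- 0
  ct_fun <- function(target, role, sample) {
    if (role == "input") return(25)
    if (target %in% c("CTA850", "CTA650")) return(25)
    i <<- i %% 3 + 1
    rep_ct[i]
  }
  tab <- make_ct_table("T1", samples, groups, ct_fun, input_fraction = 1)
  norm <- control_normalize(tab)
  expected <- mean(percent_input(rep_ct, 25, input_fraction = 1))
  expect_equal(norm$pct_input[norm$target_id == "T1"], rep(expected, 4))
})

test_that("samples failing the spike-in gate are flagged and excluded", {
  samples <- c("chol_1", "chol_2", "chol_3", "skin_1", "skin_2", "skin_3")
  groups <- setNames(rep(c("chol", "skin"), each = 3), samples)
  ct_fun <- function(target, role, sample) {
    if (role == "input") return(20)
    if (target == "CTA850") return(if (sample == "chol_1") 27 else 20)
    if (target == "CTA650") return(27)  # pos/neg ratio 1 for chol_1 -> fail
    if (startsWith(sample, "chol")) 21 else 23
  }
  tab <- make_ct_table("T1", samples, groups, ct_fun)
  norm <- control_normalize(tab)
  expect_equal(sum(!norm$qc_pass), 1)
  cmp <- group_compare(norm, "T1")
  expect_equal(cmp$n_group2, 2)  # flagged chol_1 dropped
  expect_equal(cmp$direction, "up")
  cmp_all <- group_compare(norm, "T1", exclude_flagged = FALSE)
  expect_equal(cmp_all$n_group2, 3)
})

test_that("identical groups give p = 1 and no stars", {
  samples <- sprintf("%s_%d", rep(c("chol", "skin"), each = 3), 1:3)
  groups <- setNames(rep(c("chol", "skin"), each = 3), samples)
  ct_fun <- function(target, role, sample) {
    if (role == "input") return(20)
    if (target == "CTA650") return(30)
    22
  }
  tab <- make_ct_table("T1", samples, groups, ct_fun)
  cmp <- group_compare(control_normalize(tab), "T1")
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$stars, "ns")
  expect_equal(cmp$direction, "none")
  expect_error(group_compare(control_normalize(tab), "T9"), "T9")
})
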
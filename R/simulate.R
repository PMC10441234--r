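# Synthetic two-color MeRIP array experiments with planted truth.
#
# Generative model, per transcript t and sample s:
#   baseline copies      B = 2^(baseline_log2 + expr effect + N(0, noise_sd))
#   methylated component M = B * f0 * k        (k = planted methylation effect)
#   unmethylated part    U = B * (1 - f0)
# so the methylated fraction f = f0*k / (1 - f0 + f0*k) is the odds-ratio-k
# adjustment of the baseline fraction f0, and the noise-free IP ratio between
# groups equals k exactly. Channel intensities get independent log2-Gaussian
# measurement noise and a per-sample per-channel scale factor (dye/labeling
# efficiency); spike-in probes sit at a fixed level in their own channel and
# at background in the other.

#' Simulation configuration
#'
#' Defaults mirror the study design the simulator emulates: two groups
#' (cholesteatoma vs. post-auricular skin) of 5 arrays, planted methylation
#' effects of 4-fold (hyper) and 1/4 (hypo) on the methylated component,
#' 4-fold expression effects, log2-additive Gaussian noise with sd 0.25, a
#' baseline of 2^10 fluorescence units and a baseline methylated fraction of
#' 0.5. \code{scale_range} gives the log-uniform range of per-sample
#' per-channel scale factors (default \code{c(1, 1)}, i.e. none) used to
#' exercise the scale invariance of spike-in normalization.
#'
#' @param n_per_group arrays per group.
#' @param n_hyper,n_hypo number of transcripts with planted methylation
#'   effects (applied in the cholesteatoma group).
#' @param n_up,n_down number of transcripts with planted expression effects.
#' @param true_meth_fc methylation effect for hyper transcripts (hypo
#'   transcripts use the reciprocal).
#' @param true_expr_fc expression effect for up transcripts (down use the
#'   reciprocal).
#' @param noise_sd standard deviation of log2-additive Gaussian noise (one
#'   independent draw for abundance and one per channel).
#' @param baseline_log2 mean log2 baseline abundance.
#' @param meth_fraction_baseline baseline methylated fraction f0, in (0,1).
#' @param spike_level_log2 log2 intensity of spike-in probes in their own
#'   channel.
#' @param scale_range length-2 positive range for log-uniform per-sample
#'   channel scale factors.
#' @param seed integer seed; identical configs and seeds give bit-identical
#'   output.
#' @param qpcr_input_fraction fraction of fragmented RNA reserved as input in
#'   the simulated MeRIP-qPCR.
#' @param qpcr_ct_sd Ct measurement noise (cycles).
#' @param qpcr_ct_base Ct of one unit of template.
#' @param qpcr_pos_fraction,qpcr_neg_fraction effective IP recovery of the
#'   methylated (CTA850-like) and unmethylated (CTA650-like) qPCR controls.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_per_group = 5L,
                       n_hyper = 0L, n_hypo = 0L, n_up = 0L, n_down = 0L,
                       true_meth_fc = 4, true_expr_fc = 4,
                       noise_sd = 0.25, baseline_log2 = 10,
                       meth_fraction_baseline = 0.5,
                       spike_level_log2 = 10,
                       scale_range = c(1, 1), seed = 1L,
                       qpcr_input_fraction = 0.1, qpcr_ct_sd = 0.2,
                       qpcr_ct_base = 30,
                       qpcr_pos_fraction = 0.9, qpcr_neg_fraction = 0.01) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_hyper = as.integer(n_hyper), n_hypo = as.integer(n_hypo),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              true_meth_fc = true_meth_fc, true_expr_fc = true_expr_fc,
              noise_sd = noise_sd, baseline_log2 = baseline_log2,
              meth_fraction_baseline = meth_fraction_baseline,
              spike_level_log2 = spike_level_log2,
              scale_range = scale_range, seed = as.integer(seed),
              qpcr_input_fraction = qpcr_input_fraction,
              qpcr_ct_sd = qpcr_ct_sd, qpcr_ct_base = qpcr_ct_base,
              qpcr_pos_fraction = qpcr_pos_fraction,
              qpcr_neg_fraction = qpcr_neg_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_group < 2) stopf("n_per_group must be at least 2")
  for (fld in c("n_hyper", "n_hypo", "n_up", "n_down"))
    if (!is_count(cfg[[fld]])) stopf("%s must be a nonnegative count", fld)
  if (!is_scalar_num(cfg$noise_sd) || cfg$noise_sd < 0)
    stopf("noise_sd must be >= 0")
  for (fld in c("true_meth_fc", "true_expr_fc"))
    if (!is_scalar_num(cfg[[fld]]) || cfg[[fld]] <= 0)
      stopf("%s must be a positive ratio", fld)
  f0 <- cfg$meth_fraction_baseline
  if (!is_scalar_num(f0) || f0 <= 0 || f0 >= 1)
    stopf("meth_fraction_baseline must lie in (0, 1)")
  sr <- cfg$scale_range
  if (!is.numeric(sr) || length(sr) != 2L || any(sr <= 0) || sr[1] > sr[2])
    stopf("scale_range must be an ascending positive length-2 range")
  if (!is_scalar_num(cfg$qpcr_input_fraction) ||
      cfg$qpcr_input_fraction <= 0 || cfg$qpcr_input_fraction > 1)
    stopf("qpcr_input_fraction must lie in (0, 1]")
  invisible(cfg)
}

plant_labels <- function(n, cfg) {
  if (cfg$n_hyper + cfg$n_hypo > n)
    stopf("n_hyper + n_hypo exceeds the number of transcripts (%d)", n)
  if (cfg$n_up + cfg$n_down > n)
    stopf("n_up + n_down exceeds the number of transcripts (%d)", n)
  meth <- rep("none", n)
  meth[seq_len(cfg$n_hyper)] <- "hyper"
  meth[cfg$n_hyper + seq_len(cfg$n_hypo)] <- "hypo"
  # expression effects planted from the tail so the two effect blocks stay
  # disjoint whenever the counts allow it
  expr <- rep("none", n)
  tail_idx <- n + 1L - seq_len(cfg$n_up + cfg$n_down)
  expr[tail_idx[seq_len(cfg$n_up)]] <- "up"
  expr[tail_idx[cfg$n_up + seq_len(cfg$n_down)]] <- "down"
  list(meth = meth, expr = expr)
}

#' Simulate a two-color MeRIP array experiment
#'
#' Generates raw IP and Sup channel matrices over all probes of a design,
#' with planted methylation and expression effects in the cholesteatoma
#' group and a truth table recording the planted labels and the realized
#' (noise-free expected) between-group ratios. Positive spike-in probes
#' carry signal only in the IP channel, negative spike-ins only in the Sup
#' channel; the opposite channel sits at background (raw intensity 1).
#'
#' @param design an \code{array_design}; its mRNA/lncRNA probes define the
#'   simulated transcripts (effects are planted among mRNA probes only).
#' @param cfg a [sim_config()].
#' @return An object of class \code{merip_sim}: list with raw
#'   \code{intensity_matrix} elements \code{ip_raw} and \code{sup_raw}, a
#'   \code{truth} data.frame, the \code{design} and the \code{config}.
#' @examples
#' sim <- simulate_experiment(default_design(n_mrna = 50),
#'                            sim_config(n_hyper = 5, seed = 7))
#' head(sim$truth)
#' @export
simulate_experiment <- function(design, cfg = sim_config()) {
  stopifnot(inherits(design, "array_design"))
  validate_sim_config(cfg)
  pr <- design$probes
  t_rows <- which(pr$probe_class %in% c("mRNA", "lncRNA"))
  nt <- length(t_rows)
  if (nt < 1) stopf("design has no transcript probes")
  npg <- cfg$n_per_group
  ns <- 2L * npg
  samples <- c(sprintf("chol_%d", seq_len(npg)),
               sprintf("skin_%d", seq_len(npg)))
  groups <- setNames(rep(c("chol", "skin"), each = npg), samples)
  is_chol <- groups == "chol"

  # effects are planted among mRNA transcripts only
  mrna_pos <- which(pr$probe_class[t_rows] == "mRNA")
  lab <- plant_labels(length(mrna_pos), cfg)
  meth_label <- rep("none", nt); meth_label[mrna_pos] <- lab$meth
  expr_label <- rep("none", nt); expr_label[mrna_pos] <- lab$expr
  k_meth <- unname(c(hyper = cfg$true_meth_fc, hypo = 1 / cfg$true_meth_fc,
                     none = 1)[meth_label])
  k_expr <- unname(c(up = cfg$true_expr_fc, down = 1 / cfg$true_expr_fc,
                     none = 1)[expr_label])

  n_pos <- sum(pr$probe_class == "spike_pos")
  n_neg <- sum(pr$probe_class == "spike_neg")

  draws <- with_seed(cfg$seed, {
    list(eA   = matrix(rnorm(nt * ns, 0, cfg$noise_sd), nt, ns),
         eIP  = matrix(rnorm(nt * ns, 0, cfg$noise_sd), nt, ns),
         eSup = matrix(rnorm(nt * ns, 0, cfg$noise_sd), nt, ns),
         ePos = matrix(rnorm(n_pos * ns, 0, cfg$noise_sd), n_pos, ns),
         eNeg = matrix(rnorm(n_neg * ns, 0, cfg$noise_sd), n_neg, ns),
         scale_ip  = 2^runif(ns, log2(cfg$scale_range[1]),
                             log2(cfg$scale_range[2])),
         scale_sup = 2^runif(ns, log2(cfg$scale_range[1]),
                             log2(cfg$scale_range[2])))
  })

  f0 <- cfg$meth_fraction_baseline
  kmat <- matrix(1, nt, ns)
  kmat[, is_chol] <- k_meth
  expr_eff <- matrix(0, nt, ns)
  expr_eff[, is_chol] <- log2(k_expr)

  B <- 2^(cfg$baseline_log2 + expr_eff + draws$eA)
  total <- B * (1 - f0 + f0 * kmat)
  f <- pmin(pmax((f0 * kmat) / (1 - f0 + f0 * kmat), 0.01), 0.99)
  ip_t <- total * f * 2^draws$eIP
  sup_t <- total * (1 - f) * 2^draws$eSup

  # spike-ins sit at background (raw 16, well above the log floor) in the
  # channel where they are not recovered
  np <- nrow(pr)
  ip_raw <- matrix(16, np, ns, dimnames = list(pr$probe_id, samples))
  sup_raw <- matrix(16, np, ns, dimnames = list(pr$probe_id, samples))
  ip_raw[t_rows, ] <- ip_t
  sup_raw[t_rows, ] <- sup_t
  ip_raw[pr$probe_class == "spike_pos", ] <-
    2^(cfg$spike_level_log2 + draws$ePos)
  sup_raw[pr$probe_class == "spike_neg", ] <-
    2^(cfg$spike_level_log2 + draws$eNeg)
  ip_raw <- sweep(ip_raw, 2, draws$scale_ip, `*`)
  sup_raw <- sweep(sup_raw, 2, draws$scale_sup, `*`)

  # realized (noise-free expected) group ratios, cholesteatoma / skin
  f1 <- min(max(f0, 0.01), 0.99)
  f2 <- pmin(pmax((f0 * k_meth) / (1 - f0 + f0 * k_meth), 0.01), 0.99)
  true_meth_ratio <- k_expr * (1 - f0 + f0 * k_meth) * f2 / f1
  true_expr_ratio <- k_expr * (1 - f0 + f0 * k_meth)

  truth <- data.frame(
    transcript_id = pr$transcript_id[t_rows],
    meth_label = meth_label, expr_label = expr_label,
    meth_effect = k_meth, expr_effect = k_expr,
    true_meth_ratio = true_meth_ratio,
    true_expr_ratio = true_expr_ratio,
    meth_fraction_group1 = f1, meth_fraction_group2 = f2,
    stringsAsFactors = FALSE
  )

  structure(list(
    ip_raw = intensity_matrix(ip_raw, "IP", "raw", groups),
    sup_raw = intensity_matrix(sup_raw, "Sup", "raw", groups),
    truth = truth, design = design, config = cfg
  ), class = "merip_sim")
}

#' @export
print.merip_sim <- function(x, ...) {
  cat(sprintf("Simulated MeRIP array experiment: %d probes x %d samples\n",
              nrow(x$ip_raw), ncol(x$ip_raw)))
  cat(sprintf("  planted: %d hyper, %d hypo, %d up, %d down (seed %d)\n",
              x$config$n_hyper, x$config$n_hypo, x$config$n_up,
              x$config$n_down, x$config$seed))
  invisible(x)
}

#' Simulate a MeRIP-qPCR validation experiment
#'
#' Emits a long-format Ct table (IP and input roles, three replicates by
#' default) for selected transcripts plus the CTA850-like positive and
#' CTA650-like negative controls in every sample. Template amounts follow
#' the truth table: the input reaction sees \code{input_fraction} of the
#' total abundance and the IP reaction sees the methylated fraction, so the
#' expected percent-input equals the transcript's methylated fraction x 100.
#'
#' @param truth a \code{merip_sim} or its \code{truth} data.frame.
#' @param transcripts transcript ids to assay (must exist in the truth).
#' @param cfg a [sim_config()]; qPCR-specific fields and the seed are used.
#' @param n_per_group samples per group in the validation cohort (default 10).
#' @param n_replicates technical replicates per reaction.
#' @return data.frame of class \code{qpcr_table}: \code{sample_id},
#'   \code{group}, \code{target_id}, \code{role}, \code{replicate},
#'   \code{ct}; the input fraction is carried as attribute
#'   \code{input_fraction}.
#' @export
simulate_qpcr <- function(truth, transcripts, cfg = sim_config(),
                          n_per_group = 10L, n_replicates = 3L) {
  if (inherits(truth, "merip_sim")) truth <- truth$truth
  validate_sim_config(cfg)
  if (!is_count(n_per_group) || n_per_group < 2)
    stopf("n_per_group must be at least 2")
  miss <- setdiff(transcripts, truth$transcript_id)
  if (length(miss)) stopf("unknown transcript id(s): %s", fmt_ids(miss))
  rows <- match(transcripts, truth$transcript_id)

  samples <- c(sprintf("chol_%d", seq_len(n_per_group)),
               sprintf("skin_%d", seq_len(n_per_group)))
  group <- rep(c("chol", "skin"), each = n_per_group)

  targets <- c(transcripts, "CTA850", "CTA650")
  # methylated fraction per target per group
  frac <- rbind(
    cbind(truth$meth_fraction_group2[rows], truth$meth_fraction_group1[rows]),
    c(cfg$qpcr_pos_fraction, cfg$qpcr_pos_fraction),
    c(cfg$qpcr_neg_fraction, cfg$qpcr_neg_fraction)
  )
  # total template abundance per target per group (controls spiked equally)
  abun <- rbind(
    cbind(2^cfg$baseline_log2 * truth$true_expr_ratio[rows],
          rep(2^cfg$baseline_log2, length(rows))),
    c(2^cfg$baseline_log2, 2^cfg$baseline_log2),
    c(2^cfg$baseline_log2, 2^cfg$baseline_log2)
  )
  colnames(frac) <- colnames(abun) <- c("chol", "skin")

  grid <- expand.grid(replicate = seq_len(n_replicates),
                      role = c("IP", "input"),
                      target_id = targets,
                      sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- rep(group, each = length(targets) * 2L * n_replicates)
  ti <- match(grid$target_id, targets)
  conc <- ifelse(grid$role == "IP",
                 abun[cbind(ti, match(grid$group, colnames(abun)))] *
                   frac[cbind(ti, match(grid$group, colnames(frac)))],
                 abun[cbind(ti, match(grid$group, colnames(abun)))] *
                   cfg$qpcr_input_fraction)
  ct <- with_seed(cfg$seed,
                  cfg$qpcr_ct_base - log2(conc) +
                    rnorm(nrow(grid), 0, cfg$qpcr_ct_sd))
  out <- data.frame(sample_id = grid$sample_id, group = grid$group,
                    target_id = grid$target_id, role = grid$role,
                    replicate = grid$replicate, ct = ct,
                    stringsAsFactors = FALSE)
  structure(out, input_fraction = cfg$qpcr_input_fraction,
            class = c("qpcr_table", "data.frame"))
}
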
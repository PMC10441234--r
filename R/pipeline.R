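# End-to-end orchestration: normalize -> quantify -> qc -> differential
# (methylation, expression) -> quadrants -> clustering -> enrichment ->
# optional qPCR, with all stage tables written as TSV, summaries as JSON
# and dendrograms as Newick.

#' Pipeline run configuration
#'
#' Collects input paths, thresholds and options for [run_pipeline()].
#' Thresholds must satisfy \code{fc_hi > 1 > fc_lo > 0} and
#' \code{alpha} in (0, 1).
#'
#' @param design,ip_raw,sup_raw input file paths (design TSV and the two raw
#'   channel TSVs).
#' @param out_dir output directory (created if absent).
#' @param gmt optional GMT file for enrichment.
#' @param qpcr optional MeRIP-qPCR Ct table TSV.
#' @param fc_hi,fc_lo,alpha calling thresholds.
#' @param test \code{"welch"} or \code{"student"}.
#' @param metric,linkage clustering options.
#' @param enrich_alternative \code{"over"} or \code{"two.sided"}.
#' @param input_fraction qPCR input fraction.
#' @param top_n_heatmap transcripts per heatmap.
#' @param strict_qc use the disjunctive labeling gate.
#' @param seed integer seed echoed into the report.
#' @return A validated \code{merip_run_config} list.
#' @export
merip_config <- function(design, ip_raw, sup_raw, out_dir,
                         gmt = NULL, qpcr = NULL,
                         fc_hi = 3, fc_lo = 1 / 3, alpha = 0.05,
                         test = "welch", metric = "euclidean",
                         linkage = "complete",
                         enrich_alternative = "over",
                         input_fraction = 0.1, top_n_heatmap = 100L,
                         strict_qc = FALSE, seed = 1L) {
  check_thresholds(fc_hi, fc_lo, alpha)
  structure(list(design = design, ip_raw = ip_raw, sup_raw = sup_raw,
                 out_dir = out_dir, gmt = gmt, qpcr = qpcr,
                 fc_hi = fc_hi, fc_lo = fc_lo, alpha = alpha, test = test,
                 metric = metric, linkage = linkage,
                 enrich_alternative = enrich_alternative,
                 input_fraction = input_fraction,
                 top_n_heatmap = as.integer(top_n_heatmap),
                 strict_qc = strict_qc, seed = as.integer(seed)),
            class = "merip_run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage %s: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes the stage
#' tables (TSV), dendrograms (Newick), a QC block, a JSON summary with the
#' per-direction and per-quadrant counts, and a plain-text log. Any stage
#' failure aborts with an error message naming the stage. Runs are
#' deterministic: the same inputs and configuration produce byte-identical
#' summaries.
#'
#' @param cfg a [merip_config()].
#' @param verbose emit stage progress to stderr.
#' @return An object of class \code{merip_run} (invisibly): all stage
#'   results plus the summary list and the output manifest.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "merip_run_config"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("meripchip %s",
                         as.character(utils::packageVersion("meripchip"))),
                 sprintf("config: fc_hi=%g fc_lo=%g alpha=%g test=%s seed=%d",
                         cfg$fc_hi, cfg$fc_lo, cfg$alpha, cfg$test, cfg$seed))
  note <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  manifest <- character()
  emit <- function(path) manifest <<- c(manifest, path)

  note("stage design")
  design <- run_stage("design", read_design(cfg$design))
  note("stage input")
  ip_raw <- run_stage("input", read_intensity_tsv(cfg$ip_raw))
  sup_raw <- run_stage("input", read_intensity_tsv(cfg$sup_raw))

  note("stage normalize")
  quant <- run_stage("normalize",
                     quantify(ip_raw, sup_raw, design))
  emit(write_intensity_tsv(quant$ip_norm, out("ip_normalized.tsv")))
  emit(write_intensity_tsv(quant$sup_norm, out("sup_normalized.tsv")))

  note("stage qc")
  qc <- run_stage("qc", {
    pos <- design_probe_ids(design, "spike_pos")
    neg <- design_probe_ids(design, "spike_neg")
    # spike-in enrichment proxy: mean raw IP signal of positive vs negative
    # spike-ins across samples
    list(spikein = merip_spikein_qc(
      mean(unclass(ip_raw)[pos, , drop = FALSE]),
      mean(unclass(ip_raw)[neg, , drop = FALSE])))
  })
  qc_block <- qc_summary(qc)
  writeLines(qc_block, out("qc_summary.txt"))
  emit(out("qc_summary.txt"))

  note("stage differential")
  meth <- run_stage("differential-methylation",
                    call_differential(quant$m6a_quantity,
                                      axis = "methylation",
                                      fc_hi = cfg$fc_hi, fc_lo = cfg$fc_lo,
                                      alpha = cfg$alpha, test = cfg$test,
                                      design = design))
  expr <- run_stage("differential-expression",
                    call_differential(quant$expression,
                                      axis = "expression",
                                      fc_hi = cfg$fc_hi, fc_lo = cfg$fc_lo,
                                      alpha = cfg$alpha, test = cfg$test,
                                      design = design))
  emit(write_tsv(as.data.frame(meth), out("diff_methylation.tsv")))
  emit(write_tsv(as.data.frame(expr), out("diff_expression.tsv")))
  emit(write_tsv(volcano_table(meth), out("volcano_methylation.tsv")))
  emit(write_tsv(volcano_table(expr), out("volcano_expression.tsv")))

  note("stage quadrant")
  quad <- run_stage("quadrant", quadrant_assign(meth, expr))
  emit(write_tsv(as.data.frame(quad), out("quadrants.tsv")))
  emit(write_tsv(quadrant_plot_table(quad, meth, expr),
                 out("quadrant_plot.tsv")))

  note("stage clustering")
  heat <- run_stage("clustering", {
    top <- min(cfg$top_n_heatmap, nrow(quant$m6a_quantity))
    list(meth = heatmap_matrix(quant$m6a_quantity, meth, top,
                               cfg$metric, cfg$linkage),
         expr = heatmap_matrix(quant$expression, expr, top,
                               cfg$metric, cfg$linkage))
  })
  for (ax in names(heat)) {
    hm <- heat[[ax]]
    df <- data.frame(transcript_id = rownames(hm$matrix), hm$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    emit(write_tsv(df, out(sprintf("heatmap_%s.tsv", ax))))
    writeLines(as_newick(hm$col_dendro),
               out(sprintf("dendrogram_samples_%s.nwk", ax)))
    emit(out(sprintf("dendrogram_samples_%s.nwk", ax)))
  }

  enr <- NULL
  if (!is.null(cfg$gmt)) {
    note("stage enrichment")
    enr <- run_stage("enrichment", {
      sets <- read_gmt(cfg$gmt)
      pr <- design$probes
      universe <- unique(pr$gene_symbol[pr$probe_class == "mRNA"])
      sym <- function(dirs) unique(stats::na.omit(
        meth$gene_symbol[meth$direction %in% dirs]))
      list(hyper = fisher_enrichment(intersect(sym("hyper"), universe),
                                     sets, universe,
                                     cfg$enrich_alternative, cfg$alpha),
           hypo = fisher_enrichment(intersect(sym("hypo"), universe),
                                    sets, universe,
                                    cfg$enrich_alternative, cfg$alpha))
    })
    emit(write_tsv(as.data.frame(enr$hyper), out("enrichment_hyper.tsv")))
    emit(write_tsv(as.data.frame(enr$hypo), out("enrichment_hypo.tsv")))
  }

  qpcr_res <- NULL
  if (!is.null(cfg$qpcr)) {
    note("stage qpcr")
    qpcr_res <- run_stage("qpcr", {
      tab <- read.delim(cfg$qpcr, stringsAsFactors = FALSE)
      norm <- control_normalize(tab, input_fraction = cfg$input_fraction)
      targets <- unique(norm$target_id)
      cmp <- lapply(targets, function(t) group_compare(norm, t))
      data.frame(target_id = targets,
                 mean_group1 = vapply(cmp, `[[`, numeric(1), "mean_group1"),
                 mean_group2 = vapply(cmp, `[[`, numeric(1), "mean_group2"),
                 direction = vapply(cmp, `[[`, character(1), "direction"),
                 p_value = vapply(cmp, `[[`, numeric(1), "p_value"),
                 stars = vapply(cmp, `[[`, character(1), "stars"),
                 stringsAsFactors = FALSE)
    })
    emit(write_tsv(qpcr_res, out("qpcr_comparison.tsv")))
  }

  qcount <- quadrant_counts(quad)
  mcount <- table(factor(meth$direction, levels = direction_levels("methylation")))
  ecount <- table(factor(expr$direction, levels = direction_levels("expression")))
  summary_list <- list(
    n_transcripts = nrow(meth),
    n_samples = ncol(quant$m6a_quantity),
    n_hyper = unname(mcount[["hyper"]]), n_hypo = unname(mcount[["hypo"]]),
    n_up = unname(ecount[["up"]]), n_down = unname(ecount[["down"]]),
    hyper_up = unname(qcount[["hyper_up"]]),
    hyper_down = unname(qcount[["hyper_down"]]),
    hypo_up = unname(qcount[["hypo_up"]]),
    hypo_down = unname(qcount[["hypo_down"]]),
    unassigned = unname(qcount[["unassigned"]]),
    seed = cfg$seed
  )
  jsonlite::write_json(summary_list, out("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  emit(out("summary.json"))

  note(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(log_lines, out("run.log"))

  res <- structure(list(config = cfg, design = design, quant = quant,
                        qc = qc, meth = meth, expr = expr, quadrants = quad,
                        heatmaps = heat, enrichment = enr, qpcr = qpcr_res,
                        summary = summary_list, manifest = manifest),
                   class = "merip_run")
  invisible(res)
}

#' @export
print.merip_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("MeRIP array pipeline run: %d transcripts, %d samples\n",
              s$n_transcripts, s$n_samples))
  cat(sprintf("  methylation: %d hyper, %d hypo | expression: %d up, %d down\n",
              s$n_hyper, s$n_hypo, s$n_up, s$n_down))
  cat(sprintf("  quadrants: hyper_up=%d hyper_down=%d hypo_up=%d hypo_down=%d\n",
              s$hyper_up, s$hyper_down, s$hypo_up, s$hypo_down))
  invisible(x)
}

#' Write a simulated experiment as a fixture directory
#'
#' Serializes a design, both raw channel TSVs, the truth table, a manifest
#' (seed and configuration echo) and, when \code{qpcr_transcripts} is
#' given, a simulated Ct table — everything [run_pipeline()] needs.
#'
#' @param out_dir target directory.
#' @param design an \code{array_design}.
#' @param cfg a [sim_config()].
#' @param qpcr_transcripts optional transcript ids for a simulated qPCR
#'   table.
#' @return named list of file paths (invisibly).
#' @export
simulate_to_dir <- function(out_dir, design = default_design(),
                            cfg = sim_config(), qpcr_transcripts = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(design, cfg)
  paths <- list(design = file.path(out_dir, "design.tsv"),
                ip_raw = file.path(out_dir, "ip_raw.tsv"),
                sup_raw = file.path(out_dir, "sup_raw.tsv"),
                truth = file.path(out_dir, "truth.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_design(design, paths$design)
  write_intensity_tsv(sim$ip_raw, paths$ip_raw)
  write_intensity_tsv(sim$sup_raw, paths$sup_raw)
  write_tsv(sim$truth, paths$truth)
  if (!is.null(qpcr_transcripts)) {
    paths$qpcr <- file.path(out_dir, "qpcr_ct.tsv")
    write_tsv(simulate_qpcr(sim, qpcr_transcripts, cfg), paths$qpcr)
  }
  jsonlite::write_json(unclass(cfg), paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
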
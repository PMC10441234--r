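# Spike-in anchored normalization and the three per-transcript quantities:
#   m6A quantity  = spike-in normalized log2 IP intensity
#   m6A percentage = 100 * IP / (IP + Sup) on the linear normalized scale
#   expression     = log2(IP + Sup) on the linear normalized scale

#' Spike-in normalization of one channel
#'
#' Per sample, every probe's raw intensity is log2-transformed (after
#' flooring at \code{floor} to avoid -Inf on zero intensities) and the mean
#' log2 intensity of that channel's spike-in probes is subtracted:
#' \deqn{x_{norm}(p,s) = \log_2 raw(p,s) - mean_{spike} \log_2 raw(spike,s)}
#' By default the IP channel is anchored on the methylated (\code{spike_pos})
#' spike-ins — which are the ones recovered by the antibody — and the Sup
#' channel on the unmethylated (\code{spike_neg}) spike-ins; set
#' \code{spikes = "all"} to anchor both channels on all spike-ins. The
#' subtraction cancels any per-sample multiplicative factor (dye or labeling
#' efficiency), which is the point of spike-in anchoring.
#'
#' @param raw a raw \code{intensity_matrix}.
#' @param design the \code{array_design} supplying spike-in probe ids.
#' @param spikes \code{"matched"} (channel-specific spike class) or
#'   \code{"all"}.
#' @param floor minimum raw intensity before the log transform.
#' @return A normalized \code{intensity_matrix} (spike-in rows retained).
#' @export
normalize_channel <- function(raw, design, spikes = c("matched", "all"),
                              floor = 1) {
  stopifnot(inherits(raw, "intensity_matrix"), inherits(design, "array_design"))
  spikes <- match.arg(spikes)
  if (im_scale(raw) != "raw") stopf("input is already normalized")
  if (any(raw < 0)) stopf("negative raw intensity")
  if (!is_scalar_num(floor) || floor <= 0) stopf("floor must be positive")
  extra <- setdiff(rownames(raw), design$probes$probe_id)
  if (length(extra))
    stopf("probes absent from the design: %s", fmt_ids(extra))
  cls <- switch(spikes,
                matched = if (im_channel(raw) == "IP") "spike_pos" else "spike_neg",
                all = c("spike_pos", "spike_neg"))
  sp <- intersect(design_probe_ids(design, cls), rownames(raw))
  if (!length(sp))
    stopf("no usable spike-in probes (%s) for channel %s",
          paste(cls, collapse = "/"), im_channel(raw))
  lg <- log2(pmax(unclass(raw), floor))
  ref <- colMeans(lg[sp, , drop = FALSE])
  intensity_matrix(sweep(lg, 2, ref), channel = im_channel(raw),
                   scale = "normalized", groups = sample_groups(raw))
}

# Collapse normalized probe-level values to transcript level for the given
# probe classes. Multiple probes per transcript are averaged on the linear
# scale before re-logging.
transcript_matrix <- function(norm, design, classes = "mRNA") {
  pr <- design$probes
  keep <- pr$probe_class %in% classes & pr$probe_id %in% rownames(norm)
  ids <- pr$probe_id[keep]
  tid <- pr$transcript_id[keep]
  lin <- 2^unclass(norm)[ids, , drop = FALSE]
  agg <- rowsum(lin, group = tid, reorder = FALSE)
  counts <- as.vector(table(factor(tid, levels = rownames(agg))))
  out <- log2(agg / counts)
  attr(out, "groups") <- sample_groups(norm)
  out
}

check_normalized <- function(x, channel) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (im_scale(x) != "normalized") stopf("expected a normalized matrix")
  if (!is.null(channel) && im_channel(x) != channel)
    stopf("expected the %s channel, got %s", channel, im_channel(x))
  invisible(x)
}

check_aligned <- function(ip, sup) {
  if (!identical(rownames(ip), rownames(sup)) ||
      !identical(colnames(ip), colnames(sup)))
    stopf("IP and Sup matrices are not aligned on the same transcripts/samples")
  invisible(NULL)
}

#' m6A quantity: normalized log2 IP intensity per transcript
#'
#' The per-transcript methylation-amount statistic is, by definition, the
#' spike-in normalized log2 IP (Cy5) intensity. Spike-in and lncRNA probes
#' are excluded; transcripts targeted by several probes are averaged on the
#' linear scale.
#'
#' @param ip_norm normalized IP \code{intensity_matrix}.
#' @param design the \code{array_design}.
#' @return transcripts-by-samples matrix of log2 values with a \code{groups}
#'   attribute.
#' @export
m6a_quantity <- function(ip_norm, design) {
  check_normalized(ip_norm, "IP")
  transcript_matrix(ip_norm, design)
}

#' m6A percentage per transcript and sample
#'
#' Fraction of a transcript's molecules carrying m6A, estimated from the
#' partition of material between the IP and Sup channels on the linear
#' normalized scale:
#' \deqn{pct = 100 \cdot 2^{ip} / (2^{ip} + 2^{sup})}
#' This is symmetric in the two channels, depends only on the difference
#' \code{ip - sup}, and is strictly increasing in it.
#'
#' @param ip_norm,sup_norm normalized IP and Sup matrices.
#' @param design the \code{array_design}.
#' @return matrix of percentages in [0, 100].
#' @export
m6a_percentage <- function(ip_norm, sup_norm, design) {
  check_normalized(ip_norm, "IP")
  check_normalized(sup_norm, "Sup")
  ip <- transcript_matrix(ip_norm, design)
  sup <- transcript_matrix(sup_norm, design)
  check_aligned(ip, sup)
  out <- 100 / (1 + 2^(unclass(sup) - unclass(ip)))
  attr(out, "groups") <- sample_groups(ip_norm)
  out
}

#' Expression level: log2 of the total normalized intensity
#'
#' Total transcript abundance recombines the methylated (IP) and
#' unmethylated (Sup) fractions on the linear scale:
#' \deqn{expr = \log_2(2^{ip} + 2^{sup})}
#' so \code{expr >= max(ip, sup)} always.
#'
#' @inheritParams m6a_percentage
#' @return matrix of log2 expression values.
#' @export
expression_level <- function(ip_norm, sup_norm, design) {
  check_normalized(ip_norm, "IP")
  check_normalized(sup_norm, "Sup")
  ip <- transcript_matrix(ip_norm, design)
  sup <- transcript_matrix(sup_norm, design)
  check_aligned(ip, sup)
  out <- log2(2^unclass(ip) + 2^unclass(sup))
  attr(out, "groups") <- sample_groups(ip_norm)
  out
}

#' Normalize both channels and compute all per-transcript quantities
#'
#' Convenience wrapper running [normalize_channel()] on the IP and Sup
#' matrices and returning m6A quantity, m6A percentage and expression level
#' together.
#'
#' @param ip_raw,sup_raw raw channel matrices, or a \code{merip_sim} in
#'   place of \code{ip_raw}.
#' @param design the \code{array_design} (taken from the simulation if one
#'   is given).
#' @param spikes,floor passed to [normalize_channel()].
#' @return An object of class \code{merip_quant}: list with matrices
#'   \code{m6a_quantity}, \code{m6a_pct}, \code{expression}, the normalized
#'   channel matrices and the group labels.
#' @export
quantify <- function(ip_raw, sup_raw = NULL, design = NULL,
                     spikes = c("matched", "all"), floor = 1) {
  if (inherits(ip_raw, "merip_sim")) {
    sim <- ip_raw
    ip_raw <- sim$ip_raw; sup_raw <- sim$sup_raw
    design <- design %||% sim$design
  }
  spikes <- match.arg(spikes)
  ipn <- normalize_channel(ip_raw, design, spikes = spikes, floor = floor)
  supn <- normalize_channel(sup_raw, design, spikes = spikes, floor = floor)
  structure(list(
    m6a_quantity = m6a_quantity(ipn, design),
    m6a_pct = m6a_percentage(ipn, supn, design),
    expression = expression_level(ipn, supn, design),
    ip_norm = ipn, sup_norm = supn,
    groups = sample_groups(ipn)
  ), class = "merip_quant")
}

#' @export
print.merip_quant <- function(x, ...) {
  cat(sprintf("MeRIP quantification: %d transcripts x %d samples\n",
              nrow(x$m6a_quantity), ncol(x$m6a_quantity)))
  cat(sprintf("  mean m6A percentage: %.1f%%\n", mean(x$m6a_pct)))
  invisible(x)
}
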
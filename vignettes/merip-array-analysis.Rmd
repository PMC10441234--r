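---
title: "Methods: two-color m6A epitranscriptomic microarray analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-color m6A epitranscriptomic microarray analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripchip)
```

## The assay and its model

A MeRIP two-color array splits each RNA sample with an anti-m6A antibody
into an immunoprecipitated fraction (IP, Cy5-labeled: the molecules
carrying m6A) and a supernatant (Sup, Cy3-labeled: the unmodified
molecules), both hybridized to the same array. For a transcript with total
abundance $A$ and methylated fraction $f$, the two channels measure,
up to a per-sample scale factor $c$ and multiplicative noise,

$$IP \approx c_{IP}\, A f, \qquad Sup \approx c_{Sup}\, A (1 - f).$$

Exogenous spike-in RNAs of known modification status — a methylated
positive control recovered in the IP and an unmethylated negative control
recovered in the Sup — sit at a fixed input amount, so dividing by their
observed intensity (equivalently, subtracting their mean log2 intensity)
cancels $c$:

$$x_{norm}(p,s) = \log_2 raw(p,s) - \overline{\log_2 raw(spike,s)}.$$

`normalize_channel()` implements exactly this subtraction. The published
formula for this assay writes the normalization only for the IP channel
against its (Cy5) spike-ins; we normalize the Sup channel analogously
against the negative spike-ins, which are the ones recovered in that
fraction. That is an interpretation, and `spikes = "all"` switches both
channels to the pooled spike set. A raw-intensity floor of 1 fluorescence
unit (configurable) precedes the log so zero intensities do not produce
$-\infty$; the scale-invariance property therefore holds for signals above
the floor, which is why the simulator keeps background at 16 raw units.

Three per-transcript quantities follow. The **m6A quantity** is defined as
the normalized log2 IP intensity itself — it measures the methylated
*amount*, so it responds to expression changes as well as to fraction
changes; this coupling is intrinsic to the assay definition, not an
artifact, and it shapes the quadrant results below. The **m6A percentage**
is not given a formula in the assay's public description; we use
$100 \cdot 2^{ip}/(2^{ip} + 2^{sup})$, the only scale-free symmetric
combination of the two stated inputs that maps onto $[0, 100]$ and inverts
the generative model above ($= 100f$ in expectation). The **expression
level** recombines the two fractions in linear space,
$\log_2(2^{ip} + 2^{sup})$, matching "total normalized intensity"; it
always bounds each channel from above.

## Differential calling

Calls use the fold change of geometric means,
$FC = 2^{\bar{x}_2 - \bar{x}_1}$ (case/control), with inclusive
fold-change bounds $FC \ge 3$ or $FC \le 1/3$ and a strict raw-p bound
$p < 0.05$. The two-sample test is Welch's unequal-variance t-test: the
assay description reports p-values without naming a test, group variances
are not guaranteed equal, and Welch's test is the safe default at $n = 5$
per group; Student's pooled test is available via `test = "student"`, and
moderated (empirical-Bayes) tests are deliberately out of scope. No
multiple-testing correction is applied to the calls — the published
filtering rule uses raw p — but `adjust = TRUE` reports Benjamini–Hochberg
q-values alongside. Degenerate zero-variance transcripts get $p = 1$ when
the group means agree (no evidence) and $p = 0$ when they differ (the
noise-free simulation limit); volcano tables cap $-\log_{10} p$ at 320.
Methylation fold changes are computed on the m6A quantity, not the
percentage, consistent with the quantity being the stated
methylation-amount statistic (the caller accepts any matrix, so percentage
fold changes are one argument away).

## Quadrant association, clustering, enrichment, qPCR

Transcripts significant on both axes are cross-classified into hyper-up,
hyper-down, hypo-up and hypo-down; everything else stays `unassigned`
rather than being dropped, so quadrant counts plus unassigned always equal
the transcript universe — a conservation law the tests exercise. Empty
quadrants are reported as explicit zeros because the absence of a hypo-up
intersection is a finding, not missing data.

Clustering wraps `stats::hclust` (Euclidean distance, complete linkage by
default; both configurable — the published analysis names only "R
software"). Heatmap rows are the top-N transcripts by p-value, z-scored
per row with constant rows mapping to zero, and both axes are ordered by
their dendrogram leaves; dendrograms serialize to Newick with merge
heights as branch lengths.

Gene-set enrichment is the one-sided hypergeometric upper tail (Fisher's
exact test for over-representation) with score $-\log_{10} p$ and a raw-p
significance flag at 0.05; the background universe defaults to the gene
symbols present on the array rather than the genome, which is the correct
conditioning for array data and is configurable. Reproducing genome-scale
GO/KEGG term counts is out of scope — users supply their own GMT files;
two toy GMTs over the synthetic symbol space ship with the package for
hermetic testing.

MeRIP-qPCR validation uses the standard dilution-corrected percent input,
$\%input = 100 \cdot E^{(Ct_{input} - \log_E(1/if)) - Ct_{IP}}$ with
amplification efficiency $E = 2$ and input fraction $if = 0.1$ by default
(both are stated assumptions — the assay description says only "normalized
to the input"; no standard curves are reported). Replicates combine as the
mean of percent-input values, because percent input, not Ct, is the
quantity compared downstream. Per-sample relative enrichment divides by
the positive control's percent input; samples whose positive/negative
control ratio falls below 5 (a configurable stand-in — no numeric
efficiency threshold is published) are flagged and excluded from group
comparisons.

## The synthetic-data generator

Raw array data for this assay are rarely deposited, so the simulator is a
first-class module: it is the ground truth against which every stage is
validated. Its defaults are the study conditions the package emulates:
two groups of 5 arrays, 35,175 mRNA probes in the default manifest (8
positive and 8 negative spike-in probes — the true spike-in species count
of the commercial kit is unpublished, so 8+8 is a configurable stand-in),
baseline abundance $2^{10}$, baseline methylated fraction $f_0 = 0.5$,
4-fold planted effects, and log2-additive Gaussian noise with sd 0.25 per
draw. The noise level is a stand-in too — no dispersion estimates for real
arrays of this type are published — and it was fixed once, before the
recovery suite was evaluated, at a value typical of microarray log-scale
error models.

A planted methylation effect $k$ multiplies the *methylated component*:
$M = A f_0 k$, $U = A (1 - f_0)$. This is exactly an odds-ratio-$k$ change
of the methylated fraction, and it makes the noise-free IP ratio equal $k$
— so the planted effect is recoverable on the scale the caller actually
tests. Total abundance then rises by $(1 - f_0 + f_0 k)$ (2.5-fold at
$k = 4$): planting more methylated copies necessarily adds RNA. The truth
table records both realized ratios, and the fraction is clamped to
$[0.01, 0.99]$. An alternative — holding total abundance fixed and moving
only the fraction — caps the achievable IP ratio at $1/f_0$ and would make
3-fold calling thresholds unreachable from $f_0 = 0.5$; we rejected it for
that reason. Planted expression effects scale both channels, so they also
move the IP signal: the simulator reproduces the real assay's
methylation-expression coupling, which is why simulated experiments show
hyper-up and hypo-down quadrants but an empty hypo-up quadrant.

Noise draws come from a single seeded stream in fixed matrix order, with
the caller's RNG state saved and restored; identical configurations and
seeds give bit-identical output. What the simulator does **not** model:
probe-level cross-hybridization, spatial artifacts, probe affinity
differences, heavy-tailed or intensity-dependent noise, and batch
structure. Passing recovery tests therefore demonstrate correctness of
the pipeline's arithmetic and calling logic under a well-behaved error
model, not performance on real arrays.

The simulated qPCR emits Ct values per replicate as
$Ct = Ct_{base} - \log_2(conc) + \varepsilon$, with the IP reaction seeing
$A f$ and the input reaction seeing $A \cdot if$, so percent input recovers
$100 f$ exactly at zero noise; control targets use effective IP recoveries
of 0.9 (positive) and 0.01 (negative).

## Numerical and design choices

* Problem sizes in the test and acceptance suites — 1,000 transcripts, 100
  planted per direction, 20 seeds — were chosen as the smallest sizes at
  which the binomial noise on a sensitivity of ~0.95 stays well clear of
  the 0.90 acceptance bound.
* The published hybridization gate is worded as a conjunction ("yield
  below X *and* specific activity below Y stops hybridization"); it is
  implemented literally, with `strict = TRUE` switching to the more
  conservative disjunction since the wording is plausibly an artifact.
  Threshold comparisons are strict-below, so values exactly on a boundary
  proceed.
* Fold-change thresholds are inclusive ($\ge$, $\le$), the p threshold
  strict ($<$), matching the stated filtering rule; ties in clustering are
  broken deterministically by `hclust`'s cluster-index order.
* Transcripts targeted by multiple probes are averaged on the linear
  intensity scale before quantification.
* The five published validation transcripts (CD27, CSMD1, USP44, TIAL1,
  MUC12) are injected verbatim into the default manifest at fixed slots,
  and their published fold changes and p-values ship as a plain-text
  fixture for the worked classification example. Two of those fold
  changes (0.001, 0.002) are more extreme than a 10-sample array
  comparison typically yields, suggesting undocumented scaling in the
  upstream vendor pipeline; the package takes the printed values at face
  value as classifier inputs only.

## Known limitations

The pipeline starts from raw probe-intensity tables: image analysis and
feature extraction are upstream of it. lncRNA probes are representable in
the manifest but the default design and analyses target mRNA probes only.
No background subtraction, within-array loess or quantile normalization is
applied — the spike-in subtraction is the entire normalization, as
specified for this assay. Paired designs and variance-moderated tests are
not supported.
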
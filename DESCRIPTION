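Package: meripchip
Title: Two-Color m6A Epitranscriptomic Microarray Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of two-color MeRIP (methylated RNA immunoprecipitation)
    m6A epitranscriptomic microarrays. Provides spike-in anchored
    normalization of the IP (Cy5) and supernatant (Cy3) channels, per
    transcript m6A quantity, m6A percentage and expression level,
    laboratory QC gates (RNA purity, labeling specific activity, MeRIP
    spike-in enrichment), differential methylation and expression calling
    by fold-change and p-value thresholds, four-quadrant
    methylation-expression association, hierarchical clustering for
    heatmaps, Fisher's exact gene-set enrichment over GMT files, and
    MeRIP-qPCR percent-input validation analysis. Ships a synthetic
    two-color array simulator with planted truth so the whole pipeline is
    testable without proprietary array data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
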
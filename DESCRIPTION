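Package: crmarray
Title: Common-Reference Two-Color Microarray Screening with Probe-Set
    Consistency Calls and Directed Venn Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-color microarray experiments in
    which every sample is hybridized against a pooled common reference.
    Provides within-array MA transformation and LOWESS dye-bias
    correction, reconstruction of treatment-versus-treatment log-ratios
    from treatment-versus-reference ratios, per-probe one-way ANOVA with
    Fisher's LSD pairwise contrasts, significance and fold-change
    calling, collapse of multi-probe probe sets into cluster-level calls
    with divergence and single-probe exclusion rules, direction-aware
    Venn partitioning of gene sets across a two-by-two factorial design
    in two life-cycle stages, e-value filtering of annotation tables,
    and keyword-based functional category counting. Includes a synthetic
    data generator that emulates the factorial common-reference design
    with planted effects, probe anomalies, spike-in controls, and
    intensity-dependent dye bias, so the whole pipeline is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
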
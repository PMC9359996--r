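Package: mitoscope
Title: Spatiotemporal Co-Expression, Gene-Set Enrichment and Mitochondrial
    Bioenergetics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking a chromatin regulator's expression to
    nuclear-encoded mitochondrial gene regulation and mitochondrial
    bioenergetics. Implements curation and spatiotemporal stratification of a
    developmental brain expression matrix, per-stratum Spearman co-expression
    profiles against a driver gene, distribution-shift tests (Mann-Whitney U
    with exact small-sample enumeration) and kernel-density mode estimation,
    2x2 gene-set enrichment (chi-square or Fisher by Cochran's rule) with
    Bonferroni control across spatiotemporal intervals, log2-fold-change shift
    and correlation-based clustering analyses of perturbation experiments,
    dual-luciferase reporter comparisons, qPCR standard-curve quantification
    with primer-efficiency QC, reference-gene stability selection, relative
    mitochondrial DNA content, Seahorse-style Mito Stress Test parameter
    derivation with mtDNA-content adjustment, and random-intercept mixed-model
    genotype contrasts. A seeded synthetic-data module generates every input
    format with planted, recoverable effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
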
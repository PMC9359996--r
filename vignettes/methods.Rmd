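---
title: "Methods: from co-expression strata to mixed-model bioenergetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from co-expression strata to mixed-model bioenergetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscope)
```

`mitoscope` chains four analyses that are usually scattered across ad-hoc
scripts: spatiotemporal co-expression of a driver gene against a gene set,
2×2 gene-set enrichment with multiplicity control, qPCR quantification, and
Mito Stress Test bioenergetics with mixed-model genotype contrasts. This
vignette explains the statistical models, the defaults and why they were
chosen, what the synthetic-data module emulates, and the package's known
limitations.

## Curation and spatiotemporal strata

`filter_genes()` retains genes that are (optionally) on a protein-coding
list, have no missing values, and have an overall coefficient of variation
sd/mean ≥ `cv_min` (default 0.1). The CV uses the sample standard deviation
(n − 1 denominator) on the expression scale as provided; whether to compute
it before or after log transformation is a genuinely open choice, and we use
the raw provided scale because rank-based downstream statistics are
insensitive to monotone transforms, so the filter is the only place the scale
matters. Filters are applied in the order protein-coding → missing-data →
CV; the order affects only the per-rule counts in the attached report, never
the resulting gene set, and the operation is idempotent.

`assign_strata()` maps age labels ("10 pcw", "6 mos", "3 yrs") and region
labels onto eight temporal and four regional groups (shipped as a YAML
scheme), giving 32 intervals plus the synthetic overall stratum `pall`. Bin
boundaries are inclusive as printed; ages falling in the gaps between bins
(e.g. "14 pcw", "20 yrs") are rejected with an error rather than silently
assigned, because no defensible nearest-bin rule exists for a grouping that
was defined by enumeration.

## Co-expression profiles and shift tests

`spearman_profile()` computes, per stratum, the Pearson correlation of
mid-ranks (average ranks for ties) between each gene and the driver. A
stratum needs at least 3 samples; smaller strata yield a missing `r`
(flagged, never a silent zero or a dropped row) so that downstream universes
shrink visibly. Co-factor analyses (e.g. KMT5B, DNMT1, KAT5, KAT7 instead of
BRD1) are the same code path with a different driver symbol.

`shift_test()` is a two-sided Mann–Whitney *U* test. For combined samples of
at most 20 values it enumerates all C(n₁+n₂, n₁) label assignments of the
observed values — exact under ties — and reports the fraction of assignments
whose |U − n₁n₂/2| is at least the observed one. Larger samples use the
normal approximation with tie correction and no continuity correction.
Sidedness is not stated by common reporting conventions for this test family,
so the package is uniformly two-sided. The implementation is hand-rolled
because exact enumeration under ties is required for the oracle-equivalence
guarantees; `stats::wilcox.test` (which cannot do exact p with ties) serves
as an independent cross-check on tie-free data in the test suite.

`estimate_mode()` evaluates a Gaussian KDE with Silverman's rule-of-thumb
bandwidth on a fixed grid (default [−1, 1], step 0.001) and returns the
arg-max grid point, first point winning ties — fully deterministic. Mode
values of a KDE depend on bandwidth and grid conventions, so published mode
values can only be matched approximately; the package's claim is recovery of
*planted* modes, which the tests verify to ±0.05.

## Enrichment

`enrichment_2x2()` builds [[k, n−k], [K−k, N−n−K+k]] and applies Pearson's χ²
without continuity correction, switching to Fisher's exact test when any
expected cell is below 5 (Cochran's rule — a standard operationalization of
"depending on group size"). The continuity correction is deliberately off:
on target-overlap tables of realistic size it shifts the third decimal of p
(0.002 vs 0.003 on the documented example) and the uncorrected statistic is
the one whose printed values the tests reproduce. Degenerate subsets (n = 0
or n = N) are flagged `not_applicable` rather than tested.

`interval_scan()` tests both directions (r > `hi`, r < `lo`; strict
inequalities, defaults ±0.5) in every stratum. The universe is
stratum-specific — the genes with non-missing r there — which is what makes
per-interval set fractions meaningful. Bonferroni uses m = 33 (the stratum
count) applied within each direction; both m and the direction/total family
convention are exposed as knobs because the family convention is a genuine
modelling choice. The package's family-wise error guarantee is therefore
*per correction family*: under the global null, each direction's family
shows FWER ≤ 0.05 (verified by simulation in the test suite); the union over
both directions is bounded by the sum, as with any per-family Bonferroni.

## Perturbation analyses

`scale_and_cluster()` reproduces the standard heatmap preprocessing: genes
as columns, each centered and scaled to unit sample variance, clustered with
distance 1 − Pearson r. The linkage is average (UPGMA) — unspecified in
common figure legends, exposed as a flag — and genes are sorted
alphabetically before clustering so leaf order is deterministic under tied
distances. Zero-variance genes cannot be scaled and are dropped with a
warning. `direction_concordance()` counts genes whose fold-change sign in
*every* non-reference condition strictly opposes the reference sign; zeros
count as non-opposite, the strictest defensible reading. The measure is
invariant to positive rescaling of any condition. `reporter_compare()`
normalizes firefly by renilla luminescence per well and compares groups with
the equal-variance Student *t* (not Welch), matching the named test of the
assay convention; a pooled variance of exactly zero is resolved as t = 0,
p = 1 for equal means.

## qPCR

`standard_curve_fit()` regresses Ct on log₁₀(concentration); E = 10^(−1/slope)
with the acceptance window 1.8 < E < 2.1, and r² computed from residuals
(exactly 1 for noise-free series). Non-monotone series still return a fit but
fail the separate `monotone`/`qc_pass` flags. `quantify_relative()` inverts
the curve; the noise-free round trip reproduces each dilution to 1e−9.

`stability_select()` replaces external reference-selection software with an
in-package variance-decomposition score: Ct is mapped to log₁₀ quantity as
−Ct·log₁₀(2) (efficiency 2 unless a fitted log-efficiency is supplied), and
each candidate scores sqrt(mean squared inter-group bias + mean intra-group
variance). Lower is more stable; a constant candidate scores exactly 0. The
best pair minimizes the same score on the pair average, mirroring the
accepted-practice "most stable combination of two". Per-sample centering
across candidates (which absorbs loading differences) is available via
`center = TRUE` but is off by default: centering mixes every candidate's
noise into every score, which makes the ranking of a near-constant candidate
stochastic when one panel member is very noisy. The score is validated
against exhaustive all-pairs minimization, not against any external tool's
output bit-for-bit.

`mtdna_content()` implements content = 2·2^(nuclear Ct − mitochondrial Ct),
computed separately per nuclear reference and then averaged per sample —
reporting both resolves the tension between "mean signal was used as
reference" and "calculated separately" phrasings; the factor 2 encodes the
two nuclear alleles per diploid genome, so ΔCt = 0 gives content 2. The
quantity is invariant to any common Ct offset within a sample.

## Bioenergetics

Parameters use the last timepoint of each measurement interval (T3, T4, T9).
Basal respiration (T3 − T9) and non-mitochondrial consumption (T9) are
computed on both injection schemes — both have rotenone/antimycin A as the
second injection — while ATP-linked, proton leak and coupling need
oligomycin wells and maximal/spare need FCCP wells. Whether basal values
should be pooled across schemes or kept per scheme is not standardized;
the package keeps them per well and leaves pooling to the model stage.
Trace QC excludes wells whose post-rotenone/antimycin OCR exceeds baseline
(OCR(T9) > OCR(T3)); equality is retained but flagged degenerate (basal 0,
ratio parameters undefined). The exclusion rule is a package decision —
instrument vendors do not publish one.

`adjust_by_mtdna()` divides OCR at timepoints 1–6 by the group's mtDNA
content relative to control, leaving timepoints 7–9 (a non-mitochondrial
parameter) and ECAR untouched. Adjusted basal therefore mixes an adjusted T3
with an unadjusted T9; this is the stated rule's direct consequence and it
changes ratio parameters such as coupling, which is why both adjusted and
unadjusted parameter sets are emitted rather than silently merged.

`genotype_model()` fits log₁₀(value) ~ genotype + (1 | plate) by REML with
Satterthwaite degrees of freedom (`lmerTest`), control as the reference
level — the standard inference machinery for repeated plate designs. A
single-plate design falls back to OLS, which the tests pin to the closed
form at 1e−10. Nonpositive parameter values cannot be log-transformed and
are dropped with a count. Simulation shows the 2·SE interval covers a
planted β in ≈95–97% of seeds with 3 plates; with only 2 plates REML
coverage dips toward ~91%, a known cost of estimating a variance component
from two levels.

## The synthetic-data module

The generators define the study conditions the tests run under:

* `simulate_brainspan()` — 8 stages × 8 region labels × 3 donors (192
  samples; ≥ 3 per stratum is enforced). The driver's latent log2 expression
  is a monotone stage trend (range 3) plus unit donor noise; set genes are
  negative-affine transforms with noise calibrated through the
  bivariate-normal identity ρ_Pearson = 2·sin(π·ρ_Spearman/6) so the
  *global* Spearman correlation targets `rho_planted` (default −0.6).
  Because the stage trend adds driver variance between strata, within-stratum
  correlations are attenuated (≈ −0.48 at a −0.6 target) — anticorrelation
  is present in every stratum, just slightly weaker than globally.
  Expression is 2^latent (positive; ranks unchanged). Five constant genes
  and two genes with missing values exercise the filters.
* `simulate_l2fc()` — background N(0, σ = 0.2, a typical log2 microarray
  replicate noise); set genes carry a −`l2fc_shift` (default 0.5) effect in
  all three conditions, except that a planted fraction (default 0.52, the
  observed opposite-direction share for nMT genes) flips the effect sign in
  the KD condition. The flip is applied to KD — the knockdown opposing the
  two overexpression conditions — because no assignment can keep a −shift
  location in *all* conditions while half the genes oppose; at flip
  fractions near 0.5 the KD column's set distribution centers near zero by
  construction.
* `simulate_seahorse()` — mean OCR profile 100/40 (oligomycin) or 100/150
  (FCCP)/10 pmol O₂/min, genotype βs applied on log₁₀ OCR at all
  timepoints, plate intercepts N(0, 0.05), residual 0.03 log₁₀ units;
  defaults mirror the effect scale of a knockout reducing basal respiration
  by −0.14 log₁₀ units. Non-positive or mis-ordered draws are resampled
  (not truncated) so the log-normal genotype model stays exact.
* `simulate_qpcr()` — four 1:5 serial dilutions obeying
  Ct = a − log(conc)/log(E); five reference candidates including one
  zero-variance and one group-biased gene; mtDNA ΔCt planted per group
  (default: content ratio 1.87 for the L-overexpression group, matching the
  observed mtDNA increase scale).
* `simulate_reporter()` — planted activity multipliers on a subset of
  nuclear-receptor pathways (PPAR strongest), log-normal well noise.

What the generators do *not* emulate: real RPKM distributions and
heteroscedasticity, probe-level microarray structure, instrument drift
within a plate run, donor-level correlation between regions of the same
brain, or amplification inhibitors in qPCR. Passing tests therefore
demonstrate the statistical machinery recovers planted structure under
idealized Gaussian noise — not that any specific biological dataset will
reproduce published values.

## Numerical conventions and problem sizes

All tolerance-bearing choices are fixed: KDE grid step 0.001; exact
Mann–Whitney enumeration up to combined n = 20; Cochran threshold 5 for the
Fisher switch; Bonferroni m = 33 per direction; QC window 1.8 < E < 2.1;
trace QC by T3/T9 ordering. Test-suite simulations use 2,000 null shift
tests and 1,000 null interval scans (800 genes × 33 strata), 10-seed
recovery loops for modes and concordance, and 50-seed recovery for the mixed
model — sizes chosen so Monte-Carlo standard errors are small relative to
the asserted bands while the whole suite stays in the minutes range on one
core.

## Known limitations

* Published KDE mode values are convention-dependent and only reproduced
  approximately by design.
* The Bonferroni family (per direction vs total) is a knob, not a solved
  question; FWER guarantees attach to the chosen family.
* The stability score ranks candidates on an interpretable variance
  decomposition but is not a bit-level reimplementation of any external
  tool.
* With two plates, REML coverage of genotype contrasts is below nominal;
  three or more repeated experiments are recommended.
* GO-term and transcription-factor enrichment against external web services
  is out of scope; the generic 2×2 machinery is the in-package analog.
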
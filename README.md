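# mitoscope

`mitoscope` is an R package for asking whether a chromatin regulator
(prototypically the psychiatric-risk bromodomain protein BRD1) transcriptionally
controls nuclear-encoded mitochondrial (nMT) genes, and whether perturbing it
shifts mitochondrial bioenergetics. It is aimed at molecular neuroscientists
and bioinformaticians who have (a) a developmental brain expression matrix,
(b) gene sets such as MitoCarta-style nMT lists or ChIP-derived target lists,
(c) log2-fold-change tables from knockdown/overexpression experiments,
(d) qPCR Ct tables, and (e) Seahorse-style extracellular-flux plate exports —
and who want one tested toolchain from raw tables to mixed-model effect sizes.

## What it computes

**Spatiotemporal co-expression and enrichment.** After curation (unique gene
symbols, no missing data, overall coefficient of variation ≥ 0.1), samples are
binned into 32 spatiotemporal intervals — eight temporal groups p1–p8 (8–13 pcw,
16–26 pcw, 35–37 pcw, 4–10 months, 1–4 yr, 8–13 yr, 15–19 yr, 21–40 yr) crossed
with four regional groups r1–r4 — plus the overall stratum `pall`. For each
gene *g* and stratum *s* the package computes Spearman's
ρ(*g*, driver | *s*), tests the nMT set's correlation distribution against the
background with a two-sided Mann–Whitney *U* test (exact enumeration for small
samples, tie-corrected normal approximation otherwise), and locates
distribution modes by fixed-grid Gaussian-kernel density estimation. Genes with
ρ > 0.5 or ρ < −0.5 form the highly correlated subsets; enrichment of a gene
set *S* in a subset of size *n* from a universe of size *N* is tested on the
2×2 table [[k, n−k], [K−k, N−n−K+k]] with Pearson's χ² (no continuity
correction) or Fisher's exact test when any expected cell < 5, Bonferroni
corrected over the *m* = 33 strata within each direction.

**Perturbation profiles.** Gene-set shift tests on L2FC tables, unit-variance
scaling + average-linkage clustering on 1 − Pearson correlation distances,
the fraction of genes with strictly opposite fold-change signs between
conditions, and equal-variance *t* comparisons of firefly/renilla reporter
activities.

**qPCR.** Standard curves Ct = a + b·log₁₀(conc) with efficiency
E = 10^(−1/b) and the MIQE-style acceptance window 1.8 < E < 2.1;
reference-gene selection by a variance-decomposition stability score (best
pair minimizes the score of the pair average); relative mitochondrial DNA
content = 2·2^(nuclear Ct − mitochondrial Ct).

**Bioenergetics.** Mito Stress Test parameters from 9-timepoint OCR traces
(T3 baseline, T4 post oligomycin/FCCP, T9 post rotenone/antimycin A): basal =
T3 − T9, ATP-linked = T3 − T4, proton leak = T4 − T9, coupling =
ATP-linked/basal, maximal = T4 − T9 (FCCP), spare capacity % =
100·maximal/basal, non-mitochondrial = T9, OCR/ECAR at baseline; optional
division of timepoints 1–6 by group-relative mtDNA content; and genotype
contrasts from `log10(value) ~ genotype + (1 | plate)` fitted by REML with
Satterthwaite degrees of freedom (single-plate designs fall back to OLS).

**Synthetic data.** Every input format can be generated with planted,
seed-reproducible effects (`sim_config()`, `simulate_*()`), so the whole
pipeline is testable without any external download.

## Worked example

```r
library(mitoscope)

cfg <- sim_config(seed = 1)                 # planted rho = -0.6, beta_KO = -0.14
bs  <- simulate_brainspan(cfg)
m   <- filter_genes(bs$expr)                # CV >= 0.1, no missing values
a   <- assign_strata(bs$metadata)           # 32 intervals + pall
pr  <- spearman_profile(m, bs$driver, a)
sp  <- split_profile(pr, bs$gene_set)
shift_test(sp$r_set, sp$r_background)
#> Mann-Whitney shift test
#>   U = 0.0, two-sided p = 6.77e-64 (n_set = 100, n_background = 1892)
#>   mode_set = -0.614, mode_all = 0.010, delta_mode = -0.624
#>   median_set = -0.615, median_all = 0.001
```

The planted anticorrelation (target mode −0.6) is recovered at −0.614, against
a background centered on zero, with the set/background separation driving the
Mann–Whitney *p*. Downstream, the same simulated study yields the genotype
effect on basal respiration:

```r
plate  <- simulate_seahorse(cfg)
params <- well_parameters(plate)
genotype_model(params_long(params, "basal"), parameter = "basal")
#> Genotype contrasts on log10(basal) [mixed model, plate random intercept; reference: control]
#>   genotype    beta     se  df        p
#> 1       KO -0.1354 0.0067 186 7.99e-49
#> 2        L  0.1431 0.0067 186 5.83e-52
#> 3        S  0.0127 0.0067 186 6.02e-02
```

i.e. the planted −0.14 log₁₀ knockout effect is recovered within 2 standard
errors, the L overexpression effect likewise, and the null S effect is not
significant. `run_pipeline(list(out_dir = "out", seed = 1, simulate = TRUE))`
executes every stage end-to-end and writes a manifest of outputs.

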
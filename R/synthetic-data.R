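#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators.
#' Identical configurations produce bit-identical outputs (all generators
#' seed the RNG from `seed`).
#'
#' @param seed integer RNG seed.
#' @param n_genes total genes in the expression / L2FC tables.
#' @param n_set size of the planted gene set (<= n_genes).
#' @param rho_planted target Spearman correlation of set genes with the
#'   driver gene, in [-1, 1].
#' @param n_donors_per_stage donors per temporal stage (>= 2 so every
#'   stratum holds >= 3 samples).
#' @param l2fc_shift planted negative shift of set-gene log2 fold changes.
#' @param sigma_noise Gaussian noise sd on L2FC values.
#' @param opposite_fraction fraction of set genes whose knockdown-condition
#'   fold change opposes the overexpression conditions (default 0.52).
#' @param plate_effect_sd sd of the additive per-plate intercept on log10
#'   OCR.
#' @param genotype_betas named log10 OCR effects per non-control genotype.
#' @param n_plates number of simulated flux plates.
#' @param wells_per_group wells per genotype per injection scheme per plate.
#' @param ocr_noise_sd residual sd on log10 OCR.
#' @param efficiency_true true qPCR amplification efficiency, in (1, 2.2).
#' @param ct_noise Gaussian noise sd on Ct values (0 for noise-free series).
#' @param delta_ct_mtdna named per-group planted nuclear-minus-mitochondrial
#'   delta Ct (content = 2 * 2^delta).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_set = 100L,
                       rho_planted = -0.6,
                       n_donors_per_stage = 3L,
                       l2fc_shift = 0.5,
                       sigma_noise = 0.2,
                       opposite_fraction = 0.52,
                       plate_effect_sd = 0.05,
                       genotype_betas = c(KO = -0.14, L = 0.14, S = 0),
                       n_plates = 3L,
                       wells_per_group = 8L,
                       ocr_noise_sd = 0.03,
                       efficiency_true = 2,
                       ct_noise = 0.1,
                       delta_ct_mtdna = c(control = 0, KO = 0, L = 0.903, S = 0)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_set = as.integer(n_set), rho_planted = rho_planted,
              n_donors_per_stage = as.integer(n_donors_per_stage),
              l2fc_shift = l2fc_shift, sigma_noise = sigma_noise,
              opposite_fraction = opposite_fraction,
              plate_effect_sd = plate_effect_sd,
              genotype_betas = genotype_betas,
              n_plates = as.integer(n_plates),
              wells_per_group = as.integer(wells_per_group),
              ocr_noise_sd = ocr_noise_sd,
              efficiency_true = efficiency_true, ct_noise = ct_noise,
              delta_ct_mtdna = delta_ct_mtdna)
  stopifnot(cfg$n_set <= cfg$n_genes, cfg$n_genes > 0,
            cfg$sigma_noise > 0, cfg$plate_effect_sd >= 0,
            cfg$rho_planted >= -1, cfg$rho_planted <= 1,
            cfg$opposite_fraction >= 0, cfg$opposite_fraction <= 1,
            cfg$efficiency_true > 1, cfg$efficiency_true < 2.2,
            cfg$ct_noise >= 0, cfg$ocr_noise_sd >= 0,
            cfg$n_plates >= 1, cfg$wells_per_group >= 1,
            !is.null(names(cfg$genotype_betas)),
            !is.null(names(cfg$delta_ct_mtdna)))
  structure(cfg, class = "sim_config")
}

# Age and region labels used by the developmental-transcriptome generator:
# two labels per temporal stage / two regions per regional group so every
# (p, r) stratum is populated.
sim_age_labels <- list(
  p1 = c("9 pcw", "12 pcw"),   p2 = c("17 pcw", "24 pcw"),
  p3 = c("35 pcw", "37 pcw"),  p4 = c("5 mos", "9 mos"),
  p5 = c("2 yrs", "4 yrs"),    p6 = c("9 yrs", "13 yrs"),
  p7 = c("16 yrs", "19 yrs"),  p8 = c("23 yrs", "37 yrs"))

sim_region_labels <- c(
  "primary visual cortex", "primary auditory cortex",          # r1
  "dorsolateral prefrontal cortex", "primary motor cortex",    # r2
  "hippocampus", "amygdala",                                   # r3
  "mediodorsal nucleus of the thalamus", "cerebellar cortex")  # r4

#' Simulate a developmental brain expression matrix with a planted
#' anticorrelated gene set
#'
#' Emulates a curated developmental transcriptome: samples cover all 8
#' temporal stages x 8 region labels (2 per regional group) x
#' `n_donors_per_stage` donors. The driver gene ("BRD1") follows a monotone
#' decreasing temporal trajectory plus donor-level noise on a latent log2
#' scale; set genes are negative-affine transforms of the driver plus
#' Gaussian noise calibrated (via the bivariate-normal rank-correlation
#' identity) so their expected Spearman correlation with the driver is
#' `rho_planted`; background genes are independent. Expression values are
#' 2^latent, hence positive, and Spearman correlations are unaffected by the
#' transform. The matrix additionally carries 5 constant genes (CV = 0) and
#' 2 genes with missing values, to exercise the curation filters.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (genes x samples matrix), `metadata` (sample
#'   data.frame), `gene_set` (planted set symbols), `driver` ("BRD1"),
#'   `config`.
#' @export
simulate_brainspan <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_donors_per_stage * 2 < 3)
    stop("grid cannot host >= 3 samples per stratum; increase n_donors_per_stage")
  n_extra <- 8L  # driver + 5 constant + 2 missing-value genes
  if (cfg$n_set + n_extra >= cfg$n_genes)
    stop("n_genes too small for n_set plus bookkeeping genes")
  set.seed(cfg$seed)
  stages <- paste0("p", 1:8)
  meta <- do.call(rbind, lapply(seq_along(stages), function(si) {
    do.call(rbind, lapply(seq_len(cfg$n_donors_per_stage), function(d) {
      donor <- sprintf("don_%s_%d", stages[si], d)
      age <- sim_age_labels[[si]][1 + (d - 1) %% 2]
      data.frame(donor_id = donor, age = age, region = sim_region_labels,
                 stringsAsFactors = FALSE)
    }))
  }))
  meta$sample_id <- sprintf("s%03d", seq_len(nrow(meta)))
  meta <- meta[, c("sample_id", "donor_id", "age", "region")]
  ns <- nrow(meta)
  stage_idx <- as.integer(sub("p", "", sub("_.*", "", sub("don_", "", meta$donor_id))))

  trend <- seq(1.5, -1.5, length.out = 8)[stage_idx]
  z_driver <- trend + stats::rnorm(ns)
  u <- (z_driver - mean(z_driver)) / stats::sd(z_driver)
  # Pearson rho on the latent normal scale giving the target Spearman rho.
  rho_p <- 2 * sin(pi * cfg$rho_planted / 6)
  n_bg <- cfg$n_genes - cfg$n_set - n_extra
  set_names <- sprintf("NMT%04d", seq_len(cfg$n_set))
  bg_names <- sprintf("GENE%05d", seq_len(n_bg))

  z_set <- rho_p * matrix(u, nrow = cfg$n_set, ncol = ns, byrow = TRUE) +
    sqrt(1 - rho_p^2) * matrix(stats::rnorm(cfg$n_set * ns), cfg$n_set)
  z_bg <- matrix(stats::rnorm(n_bg * ns), n_bg)
  mu <- stats::rnorm(cfg$n_set + n_bg + 1, mean = 5, sd = 1)
  latent <- rbind(z_driver, z_set, z_bg) + mu
  expr <- 2^latent
  rownames(expr) <- c("BRD1", set_names, bg_names)
  colnames(expr) <- meta$sample_id

  const <- matrix(rep(2^c(3, 4, 5, 6, 7), each = ns), nrow = 5, byrow = TRUE)
  rownames(const) <- sprintf("CONST%d", 1:5)
  miss <- 2^(matrix(stats::rnorm(2 * ns), 2) + 5)
  for (i in 1:2) miss[i, sample.int(ns, 3)] <- NA
  rownames(miss) <- c("MISS1", "MISS2")
  colnames(const) <- colnames(miss) <- meta$sample_id
  expr <- rbind(expr, const, miss)

  list(expr = expr, metadata = meta, gene_set = set_names, driver = "BRD1",
       config = cfg)
}

#' Simulate a log2-fold-change table with a planted shifted gene set
#'
#' Three conditions (KD, S, L). Background genes are N(0, sigma_noise) in
#' every condition. Set genes carry a planted effect of magnitude
#' `l2fc_shift`: negative in all conditions, except that a planted fraction
#' (`opposite_fraction`) of set genes flips the sign of the effect in the KD
#' condition, so their fold changes oppose the S/L conditions.
#'
#' @param cfg a [sim_config()].
#' @return list with `l2fc` (genes x conditions matrix), `gene_set`,
#'   `opposite_genes` (the planted opposite-direction subset), `config`.
#' @export
simulate_l2fc <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  conds <- c("KD", "S", "L")
  n_bg <- cfg$n_genes - cfg$n_set
  set_names <- sprintf("NMT%04d", seq_len(cfg$n_set))
  bg_names <- sprintf("GENE%05d", seq_len(n_bg))
  m <- matrix(stats::rnorm(cfg$n_genes * 3, sd = cfg$sigma_noise),
              nrow = cfg$n_genes, dimnames = list(c(set_names, bg_names), conds))
  opp <- stats::runif(cfg$n_set) < cfg$opposite_fraction
  eff <- matrix(-cfg$l2fc_shift, nrow = cfg$n_set, ncol = 3)
  eff[opp, 1] <- cfg$l2fc_shift  # KD opposes S/L for these genes
  m[seq_len(cfg$n_set), ] <- m[seq_len(cfg$n_set), ] + eff
  list(l2fc = m, gene_set = set_names, opposite_genes = set_names[opp],
       config = cfg)
}

#' Simulate extracellular-flux plates with planted genotype effects
#'
#' Generates `n_plates` plates, each with `wells_per_group` wells per
#' genotype (control plus the names of `genotype_betas`) per injection
#' scheme (oligomycin, FCCP). Each well has 9 OCR/ECAR timepoints; log10
#' OCR = log10 of a scheme-specific mean profile (baseline ~100, oligomycin
#' drop to ~40 / FCCP rise to ~150, rotenone/antimycin A floor ~10 pmol
#' O2/min) + the genotype's beta + an additive per-plate intercept
#' ~N(0, plate_effect_sd) + N(0, ocr_noise_sd) residual. Draws violating
#' positivity or the baseline-above-floor ordering are resampled.
#'
#' @param cfg a [sim_config()].
#' @return long-format plate data.frame (see [read_seahorse_plates()]) with
#'   attribute `plate_effects`.
#' @export
simulate_seahorse <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$wells_per_group < 1) stop("need wells in each group")
  set.seed(cfg$seed + 2L)
  genotypes <- c("control", names(cfg$genotype_betas))
  betas <- c(control = 0, cfg$genotype_betas)
  profile <- list(
    oligomycin = c(100, 100, 100, 40, 40, 40, 10, 10, 10),
    FCCP = c(100, 100, 100, 150, 150, 150, 10, 10, 10))
  ecar_profile <- c(20, 20, 20, 24, 24, 24, 15, 15, 15)
  plate_int <- stats::rnorm(cfg$n_plates, sd = cfg$plate_effect_sd)
  rows <- list()
  for (p in seq_len(cfg$n_plates)) {
    widx <- 0L
    for (g in genotypes) for (sch in c("oligomycin", "FCCP")) {
      for (w in seq_len(cfg$wells_per_group)) {
        widx <- widx + 1L
        repeat {
          locr <- log10(profile[[sch]]) + betas[[g]] + plate_int[p] +
            stats::rnorm(9, sd = cfg$ocr_noise_sd)
          ocr <- 10^locr
          if (all(ocr > 0) && ocr[9] < ocr[3]) break
        }
        ecar <- 10^(log10(ecar_profile) + plate_int[p] +
                      stats::rnorm(9, sd = cfg$ocr_noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          plate_id = sprintf("plate%d", p), well = sprintf("W%03d", widx),
          group = g, scheme = sch, timepoint = 1:9, OCR = ocr, ECAR = ecar,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "plate_effects") <- plate_int
  out
}

#' Simulate qPCR tables: dilution series, expression Cts and mtDNA Cts
#'
#' The dilution series follows Ct = intercept - log(conc)/log(E_true) +
#' N(0, ct_noise) over four 1:5 serial dilutions (two replicates each). The
#' expression table holds a target gene plus five candidate reference genes
#' across the four genotype groups (3 samples each), among them one
#' zero-variance reference ("RPS", constant Ct) and one group-biased
#' reference ("POLR2", +1.5 cycles in the L group). The mtDNA table plants a
#' per-group nuclear-minus-mitochondrial delta Ct (`delta_ct_mtdna`) on two
#' nuclear reference amplicons (GAPDH, SLC34A2) against one mitochondrial
#' amplicon (MT-ND1), so the planted relative content is 2 * 2^delta.
#'
#' @param cfg a [sim_config()].
#' @return list with data.frames `dilution_series`, `expression`, `mtdna`
#'   (all in the [read_qpcr_table()] dialect) and `config`.
#' @export
simulate_qpcr <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  conc <- (1 / 5)^(1:4)
  reps <- 2L
  dil <- expand.grid(dilution = conc, replicate = seq_len(reps))
  dil_ct <- 20 - log(dil$dilution) / log(cfg$efficiency_true) +
    stats::rnorm(nrow(dil), sd = cfg$ct_noise)
  dilution_series <- data.frame(sample = "pool", group = "pool",
                                amplicon = "TARGET", class = "target",
                                dilution = dil$dilution,
                                replicate = dil$replicate, ct = dil_ct,
                                stringsAsFactors = FALSE)

  groups <- c("control", names(cfg$genotype_betas))
  samples <- paste0(rep(groups, each = 3), "_", 1:3)
  sample_group <- rep(groups, each = 3)
  refs <- c(GAPDH = 18, POLR2 = 22, HPRT = 24, RPS = 16, PGK1 = 20)
  rows <- list()
  for (a in names(refs)) {
    ct <- refs[[a]] + stats::rnorm(length(samples), sd = cfg$ct_noise)
    if (a == "RPS") ct <- rep(refs[[a]], length(samples))   # zero variance
    if (a == "POLR2") ct <- ct + 1.5 * (sample_group == "L") # group bias
    rows[[a]] <- data.frame(sample = samples, group = sample_group,
                            amplicon = a, class = "nuclear_ref",
                            dilution = NA_real_, replicate = 1L, ct = ct,
                            stringsAsFactors = FALSE)
  }
  target_ct <- 25 - 1.5 * (sample_group %in% c("S", "L")) +
    1.0 * (sample_group == "KO") +
    stats::rnorm(length(samples), sd = cfg$ct_noise)
  rows[["BRD1"]] <- data.frame(sample = samples, group = sample_group,
                               amplicon = "BRD1", class = "target",
                               dilution = NA_real_, replicate = 1L,
                               ct = target_ct, stringsAsFactors = FALSE)
  expression <- do.call(rbind, rows)
  rownames(expression) <- NULL

  miss <- setdiff(groups, names(cfg$delta_ct_mtdna))
  if (length(miss))
    stop("delta_ct_mtdna missing group(s): ", paste(miss, collapse = ", "))
  mito_ct <- 15 + stats::rnorm(length(samples), sd = cfg$ct_noise)
  delta <- cfg$delta_ct_mtdna[sample_group]
  mt_rows <- list(data.frame(sample = samples, group = sample_group,
                             amplicon = "MT-ND1", class = "mito",
                             dilution = NA_real_, replicate = 1L,
                             ct = mito_ct, stringsAsFactors = FALSE))
  for (a in c("GAPDH", "SLC34A2")) {
    mt_rows[[a]] <- data.frame(sample = samples, group = sample_group,
                               amplicon = a, class = "nuclear_ref",
                               dilution = NA_real_, replicate = 1L,
                               ct = mito_ct + delta +
                                 stats::rnorm(length(samples),
                                              sd = cfg$ct_noise / 2),
                               stringsAsFactors = FALSE)
  }
  mtdna <- do.call(rbind, mt_rows)
  rownames(mtdna) <- NULL
  list(dilution_series = dilution_series, expression = expression,
       mtdna = mtdna, config = cfg)
}

#' Simulate dual-luciferase reporter readings
#'
#' Ten nuclear-receptor response-element pathways plus a TATA-box negative
#' control, four wells per group (modified vs control). Renilla luminescence
#' is log-normal; firefly = renilla x pathway activity x a planted
#' modified-group multiplier (increased for PPAR/HNF4/AR, decreased for
#' GR/VDR, 1 elsewhere) x log-normal noise.
#'
#' @param cfg a [sim_config()].
#' @return data.frame in the [read_reporter_readings()] dialect, with
#'   attribute `planted_multipliers`.
#' @export
simulate_reporter <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  pathways <- c("HNF4", "LXR", "RXR", "PGR", "GR", "VDR", "RAR", "PPAR",
                "AR", "ESR", "neg")
  mult <- stats::setNames(rep(1, length(pathways)), pathways)
  mult[c("PPAR", "HNF4", "AR")] <- c(1.6, 1.3, 1.3)
  mult[c("GR", "VDR")] <- 0.75
  base_act <- stats::setNames(stats::runif(length(pathways), 0.5, 2), pathways)
  rows <- list()
  for (pw in pathways) for (g in c("modified", "control")) {
    for (w in 1:4) {
      ren <- stats::rlnorm(1, log(1e4), 0.1)
      act <- base_act[[pw]] * (if (g == "modified") mult[[pw]] else 1) *
        stats::rlnorm(1, 0, 0.15)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pw, group = g, well = sprintf("%s_%s_%d", pw, g, w),
        firefly = ren * act, renilla = ren, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "planted_multipliers") <- mult
  out
}
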
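test_that("identical configurations give bit-identical outputs", {
  cfg <- sim_config(seed = 1, n_genes = 300, n_set = 30)
  a <- simulate_brainspan(cfg); b <- simulate_brainspan(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$metadata, b$metadata)
  expect_identical(simulate_l2fc(cfg)$l2fc, simulate_l2fc(cfg)$l2fc)
  expect_identical(simulate_seahorse(cfg), simulate_seahorse(cfg))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  expect_identical(simulate_reporter(cfg), simulate_reporter(cfg))
  # a different seed changes the data
  expect_false(identical(a$expr,
                         simulate_brainspan(sim_config(seed = 2, n_genes = 300,
                                                       n_set = 30))$expr))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_set = 50, n_genes = 40))
  expect_error(sim_config(sigma_noise = 0))
  expect_error(sim_config(efficiency_true = 2.5))
  expect_error(sim_config(rho_planted = -1.5))
  expect_error(simulate_brainspan(sim_config(n_donors_per_stage = 1)),
               "3 samples per stratum")
})

test_that("planted anticorrelation is recovered by empirical Spearman", {
  means <- vapply(1:10, function(seed) {
    bs <- simulate_brainspan(sim_config(seed = seed, n_genes = 200, n_set = 50,
                                        rho_planted = -0.9))
    drv <- bs$expr[bs$driver, ]
    mean(apply(bs$expr[bs$gene_set, ], 1,
               function(g) cor(g, drv, method = "spearman")))
  }, numeric(1))
  expect_true(all(means < -0.5))
})

test_that("the expression matrix carries its advertised bookkeeping genes", {
  bs <- simulate_brainspan(sim_config(seed = 3, n_genes = 250, n_set = 20))
  cv <- apply(bs$expr, 1, function(v) sd(v) / mean(v))
  expect_equal(sum(cv == 0, na.rm = TRUE), 5)
  expect_equal(sum(apply(bs$expr, 1, anyNA)), 2)
  expect_equal(nrow(bs$expr), 250)
  expect_true(all(bs$expr >= 0, na.rm = TRUE))
  # driver trend is monotone in developmental stage
  a <- assign_strata(bs$metadata)
  stage <- as.integer(sub("p(\\d)r\\d", "\\1", a$stratum))
  rho <- cor(log2(bs$expr[bs$driver, a$sample_id]), stage, method = "spearman")
  expect_lt(rho, -0.3)
})

test_that("zero planted shift leaves set and background indistinguishable", {
  cfg <- sim_config(seed = 5, n_genes = 6000, n_set = 1500, l2fc_shift = 0)
  sim <- simulate_l2fc(cfg)
  st <- l2fc_shift(sim$l2fc, "KD", sim$gene_set)
  expect_gt(st$p.value, 0.01)
  expect_lt(abs(mean(sim$l2fc[sim$gene_set, "KD"]) -
                  mean(sim$l2fc[setdiff(rownames(sim$l2fc), sim$gene_set), "KD"])),
            0.05)
})

test_that("flux wells have exactly nine OCR and ECAR readings", {
  plate <- simulate_seahorse(sim_config(seed = 6, n_plates = 2,
                                        wells_per_group = 2))
  counts <- table(paste(plate$plate_id, plate$well))
  expect_true(all(counts == 9))
  expect_true(all(plate$OCR > 0))
  # rot/AA floor strictly below baseline in every well
  t3 <- plate$OCR[plate$timepoint == 3]
  t9 <- plate$OCR[plate$timepoint == 9]
  expect_true(all(t9 < t3))
  expect_setequal(unique(plate$scheme), c("oligomycin", "FCCP"))
})

test_that("null genotype effects are not spuriously detected", {
  covered <- 0L
  total <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, genotype_betas = c(KO = 0, L = 0, S = 0),
                      wells_per_group = 4)
    params <- suppressMessages(well_parameters(simulate_seahorse(cfg)))
    md <- suppressMessages(genotype_model(params_long(params, "basal")))
    co <- md$coefficients
    covered <- covered + sum(abs(co$beta) <= 2 * co$se)
    total <- total + nrow(co)
  }
  expect_gte(covered / total, 0.85)
})

test_that("noise-free dilution series inverts to the exact efficiency", {
  cfg <- sim_config(seed = 7, efficiency_true = 2, ct_noise = 0)
  qp <- simulate_qpcr(cfg)
  cv <- standard_curve_fit(qp$dilution_series$dilution, qp$dilution_series$ct)
  expect_equal(cv$efficiency, 2, tolerance = 1e-9)
  cfg18 <- sim_config(seed = 7, efficiency_true = 1.9, ct_noise = 0)
  qp18 <- simulate_qpcr(cfg18)
  cv18 <- standard_curve_fit(qp18$dilution_series$dilution, qp18$dilution_series$ct)
  expect_equal(cv18$efficiency, 1.9, tolerance = 1e-9)
})

test_that("planted delta-Ct of zero gives mtDNA content 2", {
  cfg <- sim_config(seed = 8, ct_noise = 0,
                    delta_ct_mtdna = c(control = 0, KO = 0, L = 0, S = 0))
  qp <- simulate_qpcr(cfg)
  res <- mtdna_content(qp$mtdna)
  expect_equal(res$per_sample$content, rep(2, nrow(res$per_sample)))
})

test_that("the zero-variance reference is ranked most stable on simulated Cts", {
  qp <- simulate_qpcr(sim_config(seed = 9))
  refs <- qp$expression[qp$expression$class == "nuclear_ref", ]
  ct <- as.matrix(xtabs(ct ~ sample + amplicon, data = refs))
  groups <- refs$group[match(rownames(ct), refs$sample)]
  sel <- stability_select(ct, groups)
  expect_identical(names(sel$stability)[1], "RPS")
})

test_that("the planted group-biased reference never enters the best pair", {
  picked <- vapply(1:10, function(seed) {
    qp <- simulate_qpcr(sim_config(seed = seed))
    refs <- qp$expression[qp$expression$class == "nuclear_ref", ]
    ct <- as.matrix(xtabs(ct ~ sample + amplicon, data = refs))
    groups <- refs$group[match(rownames(ct), refs$sample)]
    "POLR2" %in% stability_select(ct, groups)$best_pair
  }, logical(1))
  expect_false(any(picked))
})

test_that("generated tables round-trip through the package readers", {
  cfg <- sim_config(seed = 10, n_genes = 120, n_set = 15,
                    n_plates = 1, wells_per_group = 2)
  tmp <- withr::local_tempdir()
  bs <- simulate_brainspan(cfg)
  p <- write_expression_matrix(bs$expr, file.path(tmp, "e.tsv"))
  expect_equal(read_expression_matrix(p), bs$expr, tolerance = 1e-12)
  p <- write_sample_metadata(bs$metadata, file.path(tmp, "m.tsv"))
  expect_equal(read_sample_metadata(p), bs$metadata)
  p <- write_gmt(list(nMT = bs$gene_set, other = c("A", "B")),
                 file.path(tmp, "g.gmt"))
  expect_identical(read_gmt(p), list(nMT = bs$gene_set, other = c("A", "B")))
  lf <- simulate_l2fc(cfg)
  p <- write_l2fc_table(lf$l2fc, file.path(tmp, "l.tsv"))
  expect_equal(read_l2fc_table(p), lf$l2fc, tolerance = 1e-12)
  sh <- simulate_seahorse(cfg)
  p <- write_seahorse_plates(sh, file.path(tmp, "s.csv"))
  expect_equal(read_seahorse_plates(p), sh, tolerance = 1e-12,
               ignore_attr = TRUE)
  qp <- simulate_qpcr(cfg)
  p <- write_qpcr_table(qp$mtdna, file.path(tmp, "q.csv"))
  expect_equal(read_qpcr_table(p), qp$mtdna, tolerance = 1e-12)
  rp <- simulate_reporter(cfg)
  p <- write_reporter_readings(rp, file.path(tmp, "r.csv"))
  expect_equal(read_reporter_readings(p), rp, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the wide flux reader reproduces the long format", {
  sh <- simulate_seahorse(sim_config(seed = 11, n_plates = 1,
                                     wells_per_group = 1))
  tmp <- withr::local_tempfile(fileext = ".csv")
  wide <- do.call(rbind, lapply(split(sh, paste(sh$plate_id, sh$well)),
    function(d) {
      d <- d[order(d$timepoint), ]
      out <- data.frame(plate_id = d$plate_id[1], well = d$well[1],
                        group = d$group[1], scheme = d$scheme[1])
      out[paste0("OCR_", 1:9)] <- as.list(d$OCR)
      out[paste0("ECAR_", 1:9)] <- as.list(d$ECAR)
      out
    }))
  write.csv(wide, tmp, row.names = FALSE, quote = FALSE)
  long <- read_seahorse_wide(tmp)
  key <- function(d) d[order(d$plate_id, d$well, d$timepoint), ]
  expect_equal(key(long)$OCR, key(sh)$OCR, tolerance = 1e-12)
})
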
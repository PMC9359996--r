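make_well <- function(ocr, scheme = "oligomycin", well = "W1", group = "g",
                      plate = "p1", ecar = rep(50, 9)) {
  data.frame(plate_id = plate, well = well, group = group, scheme = scheme,
             timepoint = 1:9, OCR = ocr, ECAR = ecar, stringsAsFactors = FALSE)
}

trace9 <- function(t3, t4, t9) c(t3, t3, t3, t4, t4, t4, t9, t9, t9)

test_that("oligomycin-well parameters follow the T3/T4/T9 arithmetic", {
  p <- suppressMessages(well_parameters(make_well(trace9(100, 40, 10))))
  expect_equal(p$basal, 90)
  expect_equal(p$atp_linked, 60)
  expect_equal(p$proton_leak, 30)
  expect_equal(p$coupling, 60 / 90)
  expect_equal(p$non_mito, 10)
  expect_equal(p$ocr_ecar, 2)
  expect_true(is.na(p$maximal))
  expect_true(is.na(p$spare_pct))
})

test_that("FCCP-well parameters follow the T3/T4/T9 arithmetic", {
  p <- suppressMessages(well_parameters(make_well(trace9(100, 150, 10),
                                                  scheme = "FCCP")))
  expect_equal(p$maximal, 140)
  expect_equal(p$basal, 90)
  expect_equal(p$spare_pct, 100 * 140 / 90)
  expect_true(is.na(p$atp_linked))
  expect_true(is.na(p$coupling))
})

test_that("degenerate and QC-failing traces are flagged or excluded", {
  flat <- suppressMessages(well_parameters(make_well(trace9(50, 30, 50))))
  expect_equal(flat$basal, 0)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$coupling))
  rising <- make_well(trace9(50, 60, 80), well = "W2")
  both <- rbind(make_well(trace9(100, 40, 10)), rising)
  res <- suppressMessages(well_parameters(both))
  expect_equal(nrow(res), 1)
  expect_equal(attr(res, "excluded")$well, "W2")
})

test_that("parameter identities hold exactly on random valid traces", {
  set.seed(31)
  for (rep in 1:30) {
    t3 <- runif(1, 60, 150)
    t9 <- runif(1, 1, t3 - 1)
    scheme <- sample(c("oligomycin", "FCCP"), 1)
    t4 <- if (scheme == "oligomycin") runif(1, t9, t3) else runif(1, t3, 300)
    p <- suppressMessages(well_parameters(make_well(trace9(t3, t4, t9),
                                                    scheme = scheme)))
    if (scheme == "oligomycin") {
      expect_equal(p$coupling * p$basal, p$atp_linked, tolerance = 1e-12)
      expect_equal(p$basal, p$atp_linked + p$proton_leak, tolerance = 1e-12)
    } else {
      expect_equal(p$spare_pct, 100 * p$maximal / p$basal, tolerance = 1e-12)
    }
    expect_equal(p$non_mito, t9)
  }
})

test_that("mtDNA adjustment rescales timepoints 1-6 only", {
  plate <- rbind(make_well(trace9(100, 40, 10), group = "KO"),
                 make_well(trace9(100, 40, 10), group = "control", well = "W2"))
  content <- c(control = 1, KO = 2)
  adj <- adjust_by_mtdna(plate, content)
  pko <- suppressMessages(well_parameters(adj))
  ko <- pko[pko$group == "KO", ]
  expect_equal(ko$basal, 100 / 2 - 10)
  expect_equal(ko$atp_linked, 100 / 2 - 40 / 2)
  expect_equal(ko$proton_leak, 40 / 2 - 10)
  # rot/AA timepoints and ECAR bit-identical
  expect_identical(adj$OCR[adj$timepoint > 6], plate$OCR[plate$timepoint > 6])
  expect_identical(adj$ECAR, plate$ECAR)
  # unit content leaves the plate untouched
  expect_equal(adjust_by_mtdna(plate, c(control = 1, KO = 1))$OCR, plate$OCR)
  expect_error(adjust_by_mtdna(plate, c(control = 1)), "KO")
})

test_that("adjusting twice by sqrt(c) equals adjusting once by c", {
  set.seed(33)
  plate <- simulate_seahorse(sim_config(seed = 33, n_plates = 1,
                                        wells_per_group = 2))
  content <- c(control = 1, KO = 1.9, L = 0.7, S = 1.3)
  once <- adjust_by_mtdna(plate, content)
  twice <- adjust_by_mtdna(adjust_by_mtdna(plate, sqrt(content)), sqrt(content))
  expect_equal(twice$OCR, once$OCR, tolerance = 1e-12)
})

test_that("single-plate genotype model equals the OLS closed form", {
  vals <- data.frame(value = c(10, 10, 10^0.8, 10^0.8),
                     genotype = c("control", "control", "KO", "KO"),
                     plate_id = "p1", stringsAsFactors = FALSE)
  md <- suppressWarnings(genotype_model(vals))  # zero-residual toy fit
  expect_identical(md$method, "ols")
  expect_equal(md$coefficients$beta, -0.2, tolerance = 1e-10)
  # against lm directly on random data
  set.seed(35)
  v2 <- data.frame(value = 10^rnorm(40, 1, 0.1),
                   genotype = rep(c("control", "KO"), 20),
                   plate_id = "p1", stringsAsFactors = FALSE)
  md2 <- genotype_model(v2)
  ref <- lm(log10(value) ~ relevel(factor(genotype), "control"), data = v2)
  expect_equal(md2$coefficients$beta, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_error(genotype_model(v2[v2$genotype == "KO", ]), "2 genotypes")
})

test_that("mixed model recovers a planted genotype effect within 2 SE", {
  hits <- 0
  for (seed in 1:5) {
    plate <- simulate_seahorse(sim_config(seed = seed, wells_per_group = 5))
    params <- suppressMessages(well_parameters(plate))
    md <- suppressMessages(genotype_model(params_long(params, "basal")))
    co <- md$coefficients
    ko <- co[co$genotype == "KO", ]
    if (abs(ko$beta - (-0.14)) <= 2 * ko$se) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("nonpositive values are dropped with a message", {
  vals <- data.frame(value = c(10, 12, -1, 9, 11, 8),
                     genotype = rep(c("control", "KO"), each = 3),
                     plate_id = "p1", stringsAsFactors = FALSE)
  expect_message(md <- genotype_model(vals), "nonpositive")
  expect_equal(md$n_dropped, 1)
})

test_that("energy ratio summarises OCR/ECAR at baseline", {
  plate <- rbind(make_well(trace9(100, 40, 10), ecar = rep(50, 9)),
                 make_well(trace9(100, 40, 10), well = "W2", ecar = rep(50, 9)))
  er <- energy_ratio(plate)
  expect_equal(er$per_well$ratio, c(2, 2))
  expect_equal(er$per_group$mean, 2)
  expect_equal(er$per_group$sem, 0)
  doubled <- plate
  doubled$OCR <- doubled$OCR * 2
  doubled$ECAR <- doubled$ECAR * 2
  expect_equal(energy_ratio(doubled)$per_well$ratio, c(2, 2))
})
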
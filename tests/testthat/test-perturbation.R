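toy_l2fc <- function() {
  m <- matrix(c( 1.0, -0.5, -0.8,
                 0.5,  0.2, -0.1,
                -0.3,  0.4,  0.6), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("KD", "L", "S")))
  m
}

test_that("L2FC shift test flags planted negative shifts", {
  cfg <- sim_config(seed = 6, n_genes = 5000, n_set = 500, l2fc_shift = 0.5,
                    opposite_fraction = 0)
  sim <- simulate_l2fc(cfg)
  st <- l2fc_shift(sim$l2fc, "KD", sim$gene_set)
  expect_lt(st$p.value, 1e-6)
  expect_lt(st$median_set - st$median_all, 0)
  expect_error(l2fc_shift(sim$l2fc, "KD", c("absent1", "absent2")),
               "does not intersect")
  expect_error(l2fc_shift(sim$l2fc, "XX", sim$gene_set), "condition")
})

test_that("scaled columns are exactly centered and unit variance", {
  m <- matrix(rnorm(40), nrow = 4,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:10)))
  cl <- scale_and_cluster(t(m))
  expect_true(all(abs(colMeans(cl$scaled)) < 1e-12))
  expect_true(all(abs(apply(cl$scaled, 2, sd) - 1) < 1e-12))
  # hand case: column [1,2,3] -> [-1,0,1]
  m2 <- matrix(c(1, 2, 3, 5, 1, 0), nrow = 3,
               dimnames = list(c("KD", "L", "S"), c("a", "b")))
  cl2 <- scale_and_cluster(t(m2))
  expect_equal(unname(cl2$scaled[, "a"]), c(-1, 0, 1))
})

test_that("identical genes sit at distance zero and merge first", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 1, 2),
             g4 = c(-1, 4, 0))
  colnames(m) <- c("KD", "L", "S")
  cl <- scale_and_cluster(m)
  expect_equal(cl$hclust$height[1], 0)
  leaves <- cl$hclust$labels[-cl$hclust$merge[1, ]]
  expect_setequal(leaves, c("g1", "g2"))
})

test_that("zero-variance genes are dropped with a warning", {
  m <- rbind(g1 = c(1, 2, 3), flat = c(2, 2, 2), g3 = c(3, 1, 2))
  colnames(m) <- c("KD", "L", "S")
  expect_warning(cl <- scale_and_cluster(m), "flat")
  expect_false("flat" %in% colnames(cl$scaled))
})

test_that("average linkage matches a naive O(n^3) agglomeration oracle", {
  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(rnorm(5 * 6), nrow = 6,
                dimnames = list(paste0("c", 1:6), paste0("g", 1:5)))
    cl <- scale_and_cluster(t(m))
    d <- 1 - cor(cl$scaled)
    coph_pkg <- as.matrix(stats::cophenetic(cl$hclust))
    coph_orc <- oracle_average_linkage_cophenetic(d)
    dimnames(coph_orc) <- dimnames(d)
    expect_equal(coph_pkg, coph_orc[rownames(coph_pkg), colnames(coph_pkg)],
                 tolerance = 1e-10)
  }
})

test_that("direction concordance counts strict all-condition sign opposition", {
  m <- toy_l2fc()  # signs: KD [+,+,-], L [-,+,+], S [-,-,+]
  expect_equal(direction_concordance(m, "KD"), 2 / 3)
  allsame <- matrix(abs(rnorm(12)), 4,
                    dimnames = list(paste0("g", 1:4), c("KD", "L", "S")))
  expect_equal(direction_concordance(allsame, "KD"), 0)
  wz <- matrix(c(0, -1, -1, 1, -1, 0), 2, byrow = TRUE,
               dimnames = list(c("z1", "z2"), c("KD", "L", "S")))
  expect_equal(direction_concordance(wz, "KD"), 0)  # zeros never opposite
})

test_that("direction concordance is invariant to positive rescaling", {
  set.seed(17)
  m <- matrix(rnorm(300), 100,
              dimnames = list(sprintf("g%03d", 1:100), c("KD", "L", "S")))
  base <- direction_concordance(m, "KD")
  m2 <- m
  m2[, "L"] <- 7.3 * m2[, "L"]
  m2[, "KD"] <- 0.01 * m2[, "KD"]
  expect_equal(direction_concordance(m2, "KD"), base)
})

test_that("planted opposite-direction fraction is recovered", {
  cfg <- sim_config(seed = 8, n_genes = 10000, n_set = 4000,
                    opposite_fraction = 0.5, l2fc_shift = 0.5,
                    sigma_noise = 0.2)
  sim <- simulate_l2fc(cfg)
  conc <- direction_concordance(sim$l2fc[sim$gene_set, ], "KD")
  expect_equal(conc, 0.5, tolerance = 0.05)
})

test_that("reporter activities normalize by renilla and compare groups", {
  r <- data.frame(pathway = "P1", group = rep(c("modified", "control"), each = 2),
                  well = paste0("w", 1:4),
                  firefly = c(10, 20, 30, 60), renilla = c(5, 10, 10, 20),
                  stringsAsFactors = FALSE)
  res <- reporter_compare(r)
  expect_equal(res$mean_modified, 2)
  expect_equal(res$mean_control, 3)
  # identical groups: t = 0, p = 1
  r2 <- data.frame(pathway = "P1", group = rep(c("modified", "control"), each = 3),
                   well = paste0("w", 1:6),
                   firefly = rep(c(10, 20, 30), 2), renilla = rep(c(5, 5, 5), 2),
                   stringsAsFactors = FALSE)
  res2 <- reporter_compare(r2)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})

test_that("reporter p-values are invariant to common scaling within a group", {
  set.seed(19)
  r <- data.frame(pathway = "P1", group = rep(c("modified", "control"), each = 4),
                  well = paste0("w", 1:8),
                  firefly = abs(rnorm(8, 20, 3)), renilla = abs(rnorm(8, 10, 1)),
                  stringsAsFactors = FALSE)
  base <- reporter_compare(r)
  r2 <- r
  i <- r2$group == "modified"
  r2$firefly[i] <- 3 * r2$firefly[i]
  r2$renilla[i] <- 3 * r2$renilla[i]
  expect_equal(reporter_compare(r2)$p, base$p, tolerance = 1e-12)
  # halving activities by doubling renilla halves means
  r3 <- r
  r3$renilla <- 2 * r3$renilla
  expect_equal(reporter_compare(r3)$mean_modified, base$mean_modified / 2)
})

test_that("a group with fewer than two wells is flagged without a p-value", {
  r <- data.frame(pathway = "P1", group = c("modified", "control", "control"),
                  well = paste0("w", 1:3),
                  firefly = c(10, 20, 30), renilla = c(5, 10, 10),
                  stringsAsFactors = FALSE)
  res <- reporter_compare(r)
  expect_true(res$flagged)
  expect_true(is.na(res$p))
})
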
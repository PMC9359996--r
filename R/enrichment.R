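#' Threshold a correlation profile into highly correlated subsets
#'
#' Splits each stratum of a profile into highly positively (r > hi) and
#' highly negatively (r < lo) correlated gene lists, using strict
#' inequalities. Genes with missing r are excluded from both lists and from
#' that stratum's universe.
#'
#' @param profile a [spearman_profile()] result.
#' @param hi,lo correlation thresholds (hi > lo).
#' @return named list per stratum, each with character vectors `pos`, `neg`,
#'   `universe`.
#' @export
threshold_subsets <- function(profile, hi = 0.5, lo = -0.5) {
  stopifnot(hi > lo)
  strata <- unique(profile$stratum)
  out <- lapply(strata, function(s) {
    sub <- profile[profile$stratum == s & !is.na(profile$r), , drop = FALSE]
    list(pos = sub$gene[sub$r > hi],
         neg = sub$gene[sub$r < lo],
         universe = sub$gene)
  })
  names(out) <- strata
  out
}

#' 2x2 gene-set enrichment test
#'
#' Tests whether a subset of size `n` drawn from a universe of size `N`
#' contains more (or fewer) members of a gene set of size `K` than expected,
#' given `k` observed members. Builds the contingency table
#' `[[k, n-k], [K-k, N-n-K+k]]` and applies Pearson's chi-square test without
#' continuity correction, or Fisher's exact test when any expected cell is
#' below 5 (Cochran's rule). P-values are two-sided.
#'
#' @param k set genes inside the subset.
#' @param n subset size.
#' @param K set genes in the universe.
#' @param N universe size.
#' @return one-row data.frame `k, n, K, N, fraction, expected_fraction,
#'   direction, test, p`, classed `enrichment_result`.
#' @export
enrichment_2x2 <- function(k, n, K, N) {
  stopifnot(k <= n, n <= N, k <= K, K <= N, k >= 0)
  if (n == 0 || n == N) {
    out <- data.frame(k = k, n = n, K = K, N = N,
                      fraction = if (n > 0) k / n else NA_real_,
                      expected_fraction = K / N,
                      direction = "none", test = "not_applicable",
                      p = NA_real_, stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  if (any(expected < 5)) {
    test <- "fisher"
    p <- stats::fisher.test(tab)$p.value
  } else {
    test <- "chi-square"
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
  }
  frac <- k / n
  exp_frac <- K / N
  direction <- if (frac > exp_frac) "enriched"
    else if (frac < exp_frac) "depleted" else "none"
  out <- data.frame(k = k, n = n, K = K, N = N, fraction = frac,
                    expected_fraction = exp_frac, direction = direction,
                    test = test, p = p, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Bonferroni adjustment
#'
#' @param ps raw p-values.
#' @param m family size (must be at least `length(ps)`).
#' @return adjusted p-values `min(1, m * p)`, order-preserving.
#' @export
bonferroni <- function(ps, m = length(ps)) {
  if (m < length(ps)) stop("family size m must be >= number of p-values")
  pmin(1, m * ps)
}

#' Per-stratum gene-set enrichment scan
#'
#' For each stratum (the 32 spatiotemporal intervals plus `pall`) and each
#' direction (positively correlated subset r > hi; negatively correlated
#' subset r < lo), tests enrichment of `gene_set` among the subset against
#' that stratum's universe (genes with non-missing r there), with Bonferroni
#' control applied within each direction over `m` strata.
#'
#' @param profile a [spearman_profile()] result.
#' @param gene_set character vector of gene symbols.
#' @param hi,lo correlation thresholds.
#' @param m Bonferroni family size; defaults to the number of strata in the
#'   profile.
#' @param alpha significance level applied to adjusted p-values.
#' @return data.frame `stratum, direction, k, n, K, N, fraction,
#'   expected_fraction, test, p, p_adj, significant`, classed
#'   `interval_scan`.
#' @export
interval_scan <- function(profile, gene_set, hi = 0.5, lo = -0.5,
                          m = NULL, alpha = 0.05) {
  subsets <- threshold_subsets(profile, hi = hi, lo = lo)
  strata <- names(subsets)
  if (is.null(m)) m <- length(strata)
  rows <- list()
  for (s in strata) {
    uni <- subsets[[s]]$universe
    K <- sum(gene_set %in% uni)
    N <- length(uni)
    for (dir in c("pos", "neg")) {
      sub <- subsets[[s]][[dir]]
      res <- enrichment_2x2(sum(sub %in% gene_set), length(sub), K, N)
      res <- cbind(data.frame(stratum = s, direction = dir,
                              stringsAsFactors = FALSE), res)
      rows[[paste(s, dir)]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  for (dir in c("pos", "neg")) {
    i <- out$direction == dir
    out$p_adj[i] <- bonferroni(out$p[i], m = m)
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  class(out) <- c("interval_scan", "data.frame")
  out
}

#' Overlap enrichment between two gene lists
#'
#' Tests whether two gene lists overlap more than expected within a common
#' universe (e.g. a protein's chromatin targets against nuclear-encoded
#' mitochondrial genes among all protein-coding genes), by delegating to
#' [enrichment_2x2()] with k = |a intersect b|, n = |a|, K = |b|,
#' N = |universe|.
#'
#' @param list_a,list_b character vectors of gene symbols, subsets of
#'   `universe`.
#' @param universe character vector of all eligible gene symbols.
#' @return an `enrichment_result` (see [enrichment_2x2()]).
#' @export
overlap_enrichment <- function(list_a, list_b, universe) {
  out_a <- setdiff(list_a, universe)
  if (length(out_a))
    stop("list_a element(s) outside universe: ",
         paste(utils::head(out_a, 5), collapse = ", "))
  out_b <- setdiff(list_b, universe)
  if (length(out_b))
    stop("list_b element(s) outside universe: ",
         paste(utils::head(out_b, 5), collapse = ", "))
  enrichment_2x2(length(intersect(list_a, list_b)),
                 length(unique(list_a)),
                 length(unique(list_b)),
                 length(unique(universe)))
}
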
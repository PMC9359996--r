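#' Per-stratum Spearman co-expression profile against a driver gene
#'
#' For every gene other than the driver, computes the Spearman correlation of
#' its expression with the driver's expression, within each spatiotemporal
#' stratum and across the whole dataset (stratum `pall`). Spearman r is the
#' Pearson correlation of mid-ranks (ties receive average ranks). Strata with
#' fewer than 3 samples yield a missing r (never a silent 0) with the sample
#' count recorded.
#'
#' @param m numeric matrix, genes x samples.
#' @param driver gene symbol present in `rownames(m)`.
#' @param assignment a [assign_strata()] result covering the columns of `m`,
#'   or NULL for a `pall`-only profile.
#' @return long data.frame `gene, stratum, r, n`, classed
#'   `correlation_profile`.
#' @export
spearman_profile <- function(m, driver, assignment = NULL) {
  if (!driver %in% rownames(m)) stop("driver gene not in matrix: ", driver)
  others <- setdiff(rownames(m), driver)
  idx <- list(pall = seq_len(ncol(m)))
  if (!is.null(assignment)) {
    if (!all(colnames(m) %in% assignment$sample_id))
      stop("assignment does not cover all samples")
    strat <- assignment$stratum[match(colnames(m), assignment$sample_id)]
    idx <- c(idx, split(seq_len(ncol(m)), strat))
  }
  res <- lapply(names(idx), function(s) {
    cols <- idx[[s]]
    n <- length(cols)
    if (n < 3) {
      r <- rep(NA_real_, length(others))
    } else {
      y <- m[driver, cols]
      x <- t(m[others, cols, drop = FALSE])
      r <- suppressWarnings(as.vector(stats::cor(x, y, method = "spearman")))
    }
    data.frame(gene = others, stratum = s, r = r, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("correlation_profile", "data.frame")
  out
}

# Mid-rank Mann-Whitney U of x (the "set") relative to y (the background).
mw_u <- function(x, y) {
  rk <- rank(c(x, y))
  sum(rk[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Two-sided Mann-Whitney p. Exhaustive enumeration of all C(n1+n2, n1)
# labelings when the combined sample is small (handles ties exactly);
# otherwise normal approximation with tie correction, no continuity
# correction.
mw_test <- function(x, y, exact_max = 20L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- mw_u(x, y)
  mu <- n1 * n2 / 2
  if (n <= exact_max) {
    rk <- rank(c(x, y))
    combos <- utils::combn(n, n1)
    us <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    tie <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = u, p.value = p)
}

#' Distribution-shift test between a gene set and the background
#'
#' Two-sided Mann-Whitney U test (exact enumeration for small samples,
#' normal approximation with tie correction otherwise) comparing a gene set's
#' values (correlations or log2 fold changes) against background values, plus
#' kernel-density mode estimates of the two distributions and their
#' difference.
#'
#' @param values_set numeric values for the gene set (length >= 2).
#' @param values_background numeric background values, excluding set members.
#' @param mode_from,mode_to grid limits for the mode estimator; defaults suit
#'   correlation values in [-1, 1].
#' @return object of class `shift_test` with fields `U`, `p.value`,
#'   `mode_set`, `mode_all`, `delta_mode`, `median_set`, `median_all`,
#'   `n_set`, `n_background`.
#' @export
shift_test <- function(values_set, values_background,
                       mode_from = -1, mode_to = 1) {
  values_set <- values_set[!is.na(values_set)]
  values_background <- values_background[!is.na(values_background)]
  if (length(values_set) < 2) stop("need at least 2 set values")
  if (length(values_background) < 1) stop("background is empty")
  tst <- mw_test(values_set, values_background)
  mode_set <- if (length(values_set) >= 10)
    estimate_mode(values_set, mode_from, mode_to) else NA_real_
  mode_all <- if (length(values_background) >= 10)
    estimate_mode(values_background, mode_from, mode_to) else NA_real_
  structure(list(U = tst$U, p.value = tst$p.value,
                 mode_set = mode_set, mode_all = mode_all,
                 delta_mode = mode_set - mode_all,
                 median_set = stats::median(values_set),
                 median_all = stats::median(values_background),
                 n_set = length(values_set),
                 n_background = length(values_background)),
            class = "shift_test")
}

#' @export
print.shift_test <- function(x, ...) {
  cat("Mann-Whitney shift test\n")
  cat(sprintf("  U = %.1f, two-sided p = %.3g (n_set = %d, n_background = %d)\n",
              x$U, x$p.value, x$n_set, x$n_background))
  if (!is.na(x$delta_mode))
    cat(sprintf("  mode_set = %.3f, mode_all = %.3f, delta_mode = %.3f\n",
                x$mode_set, x$mode_all, x$delta_mode))
  cat(sprintf("  median_set = %.3f, median_all = %.3f\n",
              x$median_set, x$median_all))
  invisible(x)
}

#' Mode of a sample by fixed-grid kernel density estimation
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a fixed grid (default [-1, 1] with step 0.001); the mode is
#' the grid point of maximum density. Deterministic; the first grid point
#' wins exact ties.
#'
#' @param values numeric vector, length >= 10.
#' @param from,to grid limits.
#' @param n_grid number of grid points (default 2001 gives step 0.001 on
#'   [-1, 1]).
#' @return the estimated mode (a grid point).
#' @export
estimate_mode <- function(values, from = -1, to = 1, n_grid = 2001L) {
  values <- values[!is.na(values)]
  if (length(values) < 10) stop("need at least 10 values for mode estimation")
  d <- stats::density(values, bw = "nrd0", from = from, to = to, n = n_grid)
  d$x[which.max(d$y)]
}

#' Correlation values of a gene set and its background within one stratum
#'
#' Convenience splitter used by enrichment and shift analyses: returns the
#' non-missing r values of `gene_set` members and of all other genes in the
#' given stratum of a correlation profile.
#'
#' @param profile a [spearman_profile()] result.
#' @param gene_set character vector of gene symbols.
#' @param stratum stratum id (default "pall").
#' @return list with numeric vectors `r_set` and `r_background`.
#' @export
split_profile <- function(profile, gene_set, stratum = "pall") {
  sub <- profile[profile$stratum == stratum & !is.na(profile$r), , drop = FALSE]
  in_set <- sub$gene %in% gene_set
  list(r_set = sub$r[in_set], r_background = sub$r[!in_set])
}
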
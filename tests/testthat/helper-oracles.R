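# Independent brute-force oracles used across test files. These deliberately
# take different computational routes than the package implementations.

# Spearman r as Pearson on explicitly computed mid-ranks.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Mann-Whitney U by pair counting (greater = 1, tie = 1/2).
oracle_u <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exact two-sided permutation p-value for the U statistic.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- oracle_u(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    oracle_u(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration: sum of the
# probabilities of all tables at most as probable as the observed one.
oracle_fisher_p <- function(k, n, K, N) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  support <- lo:hi
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive O(n^3) average-linkage agglomeration returning the cophenetic
# distance matrix. Ties broken by first minimum in column-major scan.
oracle_average_linkage_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  cd <- d
  coph <- matrix(0, n, n)
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    best <- c(NA, NA); best_d <- Inf
    for (a in idx) for (b in idx) if (a < b && cd[a, b] < best_d) {
      best_d <- cd[a, b]; best <- c(a, b)
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      coph[a, b] <- coph[b, a] <- best_d
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    for (a in idx) if (a != i && a != j)
      cd[i, a] <- cd[a, i] <- (ni * cd[i, a] + nj * cd[j, a]) / (ni + nj)
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active[j] <- FALSE
  }
  coph
}

# Small complete metadata grid covering every temporal and regional label of
# the default scheme once per donor.
toy_metadata_grid <- function(donors_per_stage = 1) {
  ages <- c("10 pcw", "20 pcw", "36 pcw", "6 mos", "3 yrs", "11 yrs",
            "17 yrs", "30 yrs")
  regions <- c("primary visual cortex", "primary motor cortex",
               "amygdala", "cerebellar cortex")
  grid <- expand.grid(age = ages, region = regions, donor = seq_len(donors_per_stage),
                      stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("s%03d", seq_len(nrow(grid))),
             donor_id = paste0("d", grid$donor, "_", grid$age),
             age = grid$age, region = grid$region, stringsAsFactors = FALSE)
}
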
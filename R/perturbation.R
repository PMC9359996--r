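#' Gene-set shift test on a log2-fold-change table
#'
#' Compares the L2FC values of a gene set in one condition against all other
#' genes in the same condition with a two-sided Mann-Whitney U test, and
#' reports shift direction via median and mode differences.
#'
#' @param l2fc numeric matrix, genes x conditions (rownames = genes).
#' @param condition column name of the condition to test.
#' @param gene_set character vector of gene symbols.
#' @return a [shift_test()] object.
#' @export
l2fc_shift <- function(l2fc, condition, gene_set) {
  if (!condition %in% colnames(l2fc))
    stop("condition not in table: ", condition)
  in_set <- rownames(l2fc) %in% gene_set
  if (!any(in_set)) stop("gene set does not intersect the table")
  v <- l2fc[, condition]
  rng <- range(v, finite = TRUE)
  pad <- 0.05 * diff(rng)
  shift_test(v[in_set], v[!in_set],
             mode_from = rng[1] - pad, mode_to = rng[2] + pad)
}

#' Scale a gene-set L2FC table and cluster genes by correlation
#'
#' Restricts the table to a gene set, transposes to conditions x genes,
#' centers each gene to mean 0 and scales to unit sample variance, and
#' agglomeratively clusters genes with distance 1 - Pearson correlation and
#' (by default) average linkage. Genes are sorted alphabetically before
#' clustering so the leaf order is deterministic under distance ties;
#' zero-variance genes are dropped with a warning.
#'
#' @param l2fc numeric matrix, genes x conditions.
#' @param gene_set optional character vector restricting the genes (default:
#'   all genes in the table).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `scaled` (conditions x genes matrix), `hclust` (the
#'   dendrogram), `order` (gene labels in leaf order) and `dropped`
#'   (zero-variance genes), classed `l2fc_clustering`.
#' @export
scale_and_cluster <- function(l2fc, gene_set = NULL, linkage = "average") {
  if (!is.null(gene_set))
    l2fc <- l2fc[rownames(l2fc) %in% gene_set, , drop = FALSE]
  if (nrow(l2fc) < 2 || ncol(l2fc) < 2)
    stop("need at least 2 genes and 2 conditions")
  x <- t(l2fc[sort(rownames(l2fc)), , drop = FALSE])  # conditions x genes
  sdv <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sdv == 0]
  if (length(dropped)) {
    warning("dropping zero-variance gene(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sdv > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 genes with nonzero variance")
  scaled <- scale(x, center = TRUE, scale = TRUE)
  d <- stats::as.dist(1 - stats::cor(scaled))
  hc <- stats::hclust(d, method = linkage)
  structure(list(scaled = scaled, hclust = hc,
                 order = colnames(scaled)[hc$order], dropped = dropped),
            class = "l2fc_clustering")
}

#' @export
plot.l2fc_clustering <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Fraction of genes with opposite fold-change direction
#'
#' Fraction of genes whose L2FC sign in every non-reference condition is
#' strictly opposite to its sign in the reference condition. Zeros (in the
#' reference or any other condition) count as non-opposite.
#'
#' @param l2fc numeric matrix, genes x conditions.
#' @param ref_condition reference condition column name.
#' @param other_conditions other condition column names (default: all
#'   remaining columns).
#' @return fraction in [0, 1].
#' @export
direction_concordance <- function(l2fc, ref_condition,
                                  other_conditions = NULL) {
  if (is.null(other_conditions))
    other_conditions <- setdiff(colnames(l2fc), ref_condition)
  stopifnot(ref_condition %in% colnames(l2fc),
            all(other_conditions %in% colnames(l2fc)))
  s0 <- sign(l2fc[, ref_condition])
  so <- sign(l2fc[, other_conditions, drop = FALSE])
  opp <- s0 != 0 & apply(so, 1, function(s) all(s != 0) ) &
    apply(so == -s0, 1, all)
  mean(opp)
}

#' Compare dual-luciferase reporter activity between groups
#'
#' Per-well activity is firefly / renilla luminescence. For each pathway the
#' `modified` and `control` groups are compared with a two-sided
#' equal-variance (Student) t-test; group means and standard errors are
#' reported. Pathways where either group has fewer than 2 wells are flagged
#' and get no p-value.
#'
#' @param readings data.frame with columns `pathway, group, well, firefly,
#'   renilla`; `group` levels are `modified` and `control`.
#' @return data.frame per pathway: group means with SEM, t statistic,
#'   two-sided p, and a `flagged` indicator.
#' @export
reporter_compare <- function(readings) {
  stopifnot(all(c("pathway", "group", "firefly", "renilla") %in%
                  colnames(readings)))
  if (any(readings$renilla <= 0)) stop("renilla readings must be positive")
  bad <- setdiff(unique(readings$group), c("modified", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  readings$activity <- readings$firefly / readings$renilla
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  # pooled-variance Student t with explicit degenerate handling (both groups
  # constant: t = 0, p = 1 for equal means, p = 0 otherwise)
  student_t <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    dm <- mean(x) - mean(y)
    if (se == 0) {
      if (dm == 0) list(t = 0, p = 1)
      else list(t = sign(dm) * Inf, p = 0)
    } else {
      t <- dm / se
      list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
    }
  }
  rows <- lapply(split(readings, readings$pathway), function(d) {
    a_mod <- d$activity[d$group == "modified"]
    a_ctl <- d$activity[d$group == "control"]
    flagged <- length(a_mod) < 2 || length(a_ctl) < 2
    tt <- if (flagged) list(t = NA_real_, p = NA_real_)
      else student_t(a_mod, a_ctl)
    data.frame(pathway = d$pathway[1],
               mean_modified = mean(a_mod), sem_modified = sem(a_mod),
               mean_control = mean(a_ctl), sem_control = sem(a_ctl),
               t = tt$t, p = tt$p, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
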
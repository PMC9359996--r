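#' Fit a qPCR standard curve from a dilution series
#'
#' Least-squares fit of Ct against log10(relative concentration). The
#' amplification efficiency is E = 10^(-1/slope); primers are accepted when
#' 1.8 < E < 2.1 (MIQE-style QC window). A non-monotone series still returns
#' a fit but fails QC.
#'
#' @param dilution relative concentrations (> 0), at least 3 distinct values
#'   (e.g. 1:5 serial dilutions 0.2, 0.04, 0.008, 0.0016).
#' @param ct observed Ct values (same length).
#' @param amplicon optional amplicon name carried into the result.
#' @return object of class `standard_curve` with fields `slope` (cycles per
#'   log10 concentration), `intercept` (cycles at concentration 1),
#'   `efficiency`, `r_squared`, `accepted` (efficiency window), `monotone`,
#'   and `qc_pass` (accepted and monotone).
#' @export
standard_curve_fit <- function(dilution, ct, amplicon = NA_character_) {
  stopifnot(length(dilution) == length(ct), all(dilution > 0), all(ct > 0))
  if (length(unique(dilution)) < 3)
    stop("need at least 3 distinct dilutions")
  fit <- stats::lm(ct ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0)
    warning("non-negative slope: Ct should decrease with concentration")
  efficiency <- 10^(-1 / slope)
  tss <- sum((ct - mean(ct))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  mean_ct <- tapply(ct, dilution, mean)
  monotone <- !is.unsorted(rev(mean_ct[order(as.numeric(names(mean_ct)))]))
  accepted <- efficiency > 1.8 & efficiency < 2.1
  structure(list(amplicon = amplicon, slope = slope, intercept = intercept,
                 efficiency = efficiency, r_squared = r2,
                 accepted = accepted, monotone = monotone,
                 qc_pass = accepted && monotone),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve%s\n",
              if (!is.na(x$amplicon)) paste0(" (", x$amplicon, ")") else ""))
  cat(sprintf("  Ct = %.4f %+.4f * log10(conc);  E = %.4f;  r^2 = %.4f\n",
              x$intercept, x$slope, x$efficiency, x$r_squared))
  cat(sprintf("  QC (1.8 < E < 2.1, monotone): %s\n",
              if (x$qc_pass) "accepted" else "REJECTED"))
  invisible(x)
}

#' Relative abundance from a Ct value and a standard curve
#'
#' Inverts the standard curve: abundance = 10^((ct - intercept)/slope),
#' monotone decreasing in ct. Warns when the curve failed efficiency QC.
#'
#' @param ct Ct value(s).
#' @param curve a [standard_curve_fit()] result.
#' @return relative abundance(s) on the concentration scale of the series.
#' @export
quantify_relative <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$accepted)
    warning("standard curve failed QC; abundances may be unreliable")
  10^((ct - curve$intercept) / curve$slope)
}

# Stability value of one log-quantity profile: sqrt of (mean squared
# inter-group bias + mean intra-group variance), after the sample-wise
# centering applied by the caller.
stability_value <- function(q, groups) {
  gm <- tapply(q, groups, mean)
  gv <- tapply(q, groups, stats::var)
  sqrt(mean((gm - mean(q))^2) + mean(gv))
}

#' Reference-gene stability selection
#'
#' Variance-decomposition stability model for choosing reference genes, in
#' the spirit of model-based reference selection: Ct values are converted to
#' log10 quantities (assuming efficiency 2 unless another log-efficiency is
#' supplied) and each candidate is scored as
#' sqrt(mean squared inter-group bias + mean intra-group variance); lower is
#' more stable, and a constant candidate scores exactly 0. With
#' `center = TRUE` the quantities are first centered per sample across
#' candidates, absorbing sample-loading differences at the cost of mixing
#' every candidate's noise into every score (kept off by default so the
#' ranking of a zero-variance candidate is deterministic). The best pair
#' minimizes the same score applied to the pair average, and the per-sample
#' normalization factor is the mean log-quantity of the chosen pair.
#'
#' @param ct_mat numeric matrix, samples x candidate reference genes
#'   (colnames required).
#' @param groups factor/character of group membership per sample (each group
#'   needs >= 2 samples).
#' @param log_efficiency log10 of the per-cycle amplification factor used to
#'   map Ct to log-quantity (default log10(2)).
#' @param center center log-quantities per sample across candidates before
#'   scoring (default FALSE).
#' @return object of class `stability_selection` with fields `stability`
#'   (named, ascending), `best_pair`, `pair_stability` (all pairs),
#'   `norm_factor` (per sample), `excluded` (candidates with missing data).
#' @export
stability_select <- function(ct_mat, groups, log_efficiency = log10(2),
                             center = FALSE) {
  stopifnot(is.matrix(ct_mat), !is.null(colnames(ct_mat)))
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(ct_mat))
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  excluded <- colnames(ct_mat)[apply(ct_mat, 2, anyNA)]
  if (length(excluded)) {
    warning("excluding candidate(s) with missing values: ",
            paste(excluded, collapse = ", "))
    ct_mat <- ct_mat[, !colnames(ct_mat) %in% excluded, drop = FALSE]
  }
  if (ncol(ct_mat) < 3) stop("need at least 3 complete candidates")
  q <- -ct_mat * log_efficiency            # log10 quantity
  centered <- if (center) q - rowMeans(q) else q
  stab <- apply(centered, 2, stability_value, groups = groups)
  pairs <- utils::combn(colnames(ct_mat), 2)
  pair_stab <- apply(pairs, 2, function(p)
    stability_value(rowMeans(centered[, p, drop = FALSE]), groups))
  names(pair_stab) <- apply(pairs, 2, paste, collapse = "+")
  best <- pairs[, which.min(pair_stab)]
  structure(list(stability = sort(stab),
                 best_pair = best,
                 pair_stability = sort(pair_stab),
                 norm_factor = rowMeans(q[, best, drop = FALSE]),
                 excluded = excluded),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("Reference-gene stability (lower = more stable):\n")
  print(round(x$stability, 4))
  cat("Best pair:", paste(x$best_pair, collapse = " + "), "\n")
  invisible(x)
}

#' Relative mitochondrial DNA content
#'
#' Computes, per sample and per nuclear reference amplicon,
#' content = 2 * 2^(nuclear Ct - mitochondrial Ct), then averages across
#' nuclear references per sample. Equal nuclear and mitochondrial Ct gives
#' content 2 (two nuclear alleles per diploid genome). Replicate Ct values of
#' the same (sample, amplicon) are averaged first; samples without a
#' mitochondrial Ct are skipped with a warning.
#'
#' @param tab qPCR data.frame with columns `sample, amplicon, class, ct`;
#'   `class` distinguishes `mito` from `nuclear_ref` amplicons (and `group`
#'   is carried through when present).
#' @return object of class `mtdna_content`: list with `per_reference`
#'   (sample, reference, content) and `per_sample` (sample, content = mean
#'   across references).
#' @export
mtdna_content <- function(tab) {
  stopifnot(all(c("sample", "amplicon", "class", "ct") %in% colnames(tab)))
  tab <- tab[tab$class %in% c("mito", "nuclear_ref"), , drop = FALSE]
  if (!nrow(tab)) stop("no mito or nuclear_ref rows in table")
  agg <- stats::aggregate(ct ~ sample + amplicon + class, data = tab, FUN = mean)
  samples <- unique(agg$sample)
  per_ref <- list()
  skipped <- character()
  for (s in samples) {
    d <- agg[agg$sample == s, , drop = FALSE]
    mito <- d$ct[d$class == "mito"]
    nuc <- d[d$class == "nuclear_ref", , drop = FALSE]
    if (!length(mito) || !nrow(nuc)) {
      skipped <- c(skipped, s)
      next
    }
    mito_ct <- mean(mito)
    per_ref[[s]] <- data.frame(sample = s, reference = nuc$amplicon,
                               content = 2 * 2^(nuc$ct - mito_ct),
                               stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipping sample(s) without complete mito/nuclear Ct: ",
            paste(skipped, collapse = ", "))
  if (!length(per_ref)) stop("no sample with both mito and nuclear Ct")
  per_reference <- do.call(rbind, per_ref)
  rownames(per_reference) <- NULL
  per_sample <- stats::aggregate(content ~ sample, data = per_reference,
                                 FUN = mean)
  if ("group" %in% colnames(tab)) {
    grp <- unique(tab[, c("sample", "group")])
    per_sample <- merge(per_sample, grp, by = "sample", sort = FALSE)
  }
  structure(list(per_reference = per_reference, per_sample = per_sample),
            class = "mtdna_content")
}

#' @export
print.mtdna_content <- function(x, ...) {
  cat("Relative mtDNA content (2 * 2^(nuclear Ct - mito Ct)):\n")
  print(x$per_sample)
  invisible(x)
}

#' Group-level relative mtDNA content
#'
#' Mean per-sample content per group, optionally normalized so that a control
#' group equals 1 (the scale used to adjust respiration traces).
#'
#' @param content a [mtdna_content()] result whose `per_sample` table has a
#'   `group` column.
#' @param relative_to optional group name to normalize against.
#' @return named numeric vector of group contents.
#' @export
mtdna_group_content <- function(content, relative_to = NULL) {
  stopifnot(inherits(content, "mtdna_content"))
  ps <- content$per_sample
  if (!"group" %in% colnames(ps)) stop("per-sample table has no group column")
  g <- tapply(ps$content, ps$group, mean)
  if (!is.null(relative_to)) {
    if (!relative_to %in% names(g)) stop("unknown group: ", relative_to)
    g <- g / g[[relative_to]]
  }
  g
}
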
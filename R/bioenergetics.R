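#' Mito Stress Test respiration parameters per well
#'
#' Derives respiration parameters from 9-timepoint OCR/ECAR traces under the
#' two-injection scheme (oligomycin or FCCP first, rotenone/antimycin A
#' second), using the last timepoint of each interval: T3 (baseline), T4
#' (post first injection), T9 (post rotenone/antimycin A).
#'
#' All wells: basal = OCR(T3) - OCR(T9); non-mitochondrial = OCR(T9);
#' OCR/ECAR = OCR(T3)/ECAR(T3). Oligomycin wells: ATP-linked = OCR(T3) -
#' OCR(T4); proton leak = OCR(T4) - OCR(T9); coupling efficiency =
#' ATP-linked / basal. FCCP wells: maximal = OCR(T4) - OCR(T9); spare
#' capacity (%) = 100 * maximal / basal. Parameters requiring the other
#' scheme's injection are NA. Wells failing trace QC (OCR(T9) > OCR(T3))
#' are excluded and listed in the `excluded` attribute; a zero basal
#' (OCR(T9) = OCR(T3)) is retained but leaves ratio parameters NA and sets
#' the `degenerate` flag.
#'
#' @param plate long-format plate data.frame (see [read_seahorse_plates()]).
#' @return data.frame per well with the parameters above, classed
#'   `bioenergetics_params`, with attribute `excluded`.
#' @export
well_parameters <- function(plate) {
  validate_seahorse(plate)
  key <- paste(plate$plate_id, plate$well, sep = "::")
  rows <- lapply(split(plate, key), function(d) {
    d <- d[order(d$timepoint), ]
    ocr <- d$OCR; ecar <- d$ECAR
    t3 <- ocr[3]; t4 <- ocr[4]; t9 <- ocr[9]
    basal <- t3 - t9
    out <- data.frame(plate_id = d$plate_id[1], well = d$well[1],
                      group = d$group[1], scheme = d$scheme[1],
                      basal = basal, atp_linked = NA_real_,
                      proton_leak = NA_real_, coupling = NA_real_,
                      maximal = NA_real_, spare_pct = NA_real_,
                      non_mito = t9,
                      ocr_ecar = if (ecar[3] > 0) t3 / ecar[3] else NA_real_,
                      qc_pass = t9 <= t3, degenerate = basal == 0,
                      stringsAsFactors = FALSE)
    if (d$scheme[1] == "oligomycin") {
      out$atp_linked <- t3 - t4
      out$proton_leak <- t4 - t9
      out$coupling <- if (basal != 0) (t3 - t4) / basal else NA_real_
    } else {
      out$maximal <- t4 - t9
      out$spare_pct <- if (basal != 0) 100 * (t4 - t9) / basal else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  excluded <- out[!out$qc_pass, c("plate_id", "well"), drop = FALSE]
  if (nrow(excluded))
    message(nrow(excluded), " well(s) excluded by trace QC (OCR(T9) > OCR(T3))")
  out <- out[out$qc_pass, , drop = FALSE]
  attr(out, "excluded") <- excluded
  class(out) <- c("bioenergetics_params", "data.frame")
  out
}

#' Adjust OCR traces by relative mtDNA content
#'
#' Divides the OCR values of timepoints 1-6 by each group's relative mtDNA
#' content (normalized so the control group equals 1), leaving the
#' post-rotenone/antimycin-A timepoints 7-9 (non-mitochondrial oxygen
#' consumption) and all ECAR values untouched. Parameters are then
#' recomputed with [well_parameters()] on the adjusted plate; note that
#' ratio parameters mix adjusted (T3, T4) and unadjusted (T9) terms by
#' construction.
#'
#' @param plate long-format plate data.frame.
#' @param content named numeric vector of relative mtDNA content per group
#'   (e.g. from [mtdna_group_content()]).
#' @param control group used as the unit reference (default "control").
#' @return adjusted plate data.frame with attribute
#'   `mtdna_adjustment` = the applied per-group divisors.
#' @export
adjust_by_mtdna <- function(plate, content, control = "control") {
  validate_seahorse(plate)
  groups <- unique(plate$group)
  miss <- setdiff(groups, names(content))
  if (length(miss))
    stop("missing mtDNA content for group(s): ", paste(miss, collapse = ", "))
  if (any(content <= 0)) stop("mtDNA content must be positive")
  if (!control %in% names(content)) stop("unknown control group: ", control)
  rel <- content / content[[control]]
  adj <- plate
  i <- adj$timepoint <= 6
  adj$OCR[i] <- adj$OCR[i] / rel[adj$group[i]]
  attr(adj, "mtdna_adjustment") <- rel[groups]
  adj
}

#' Genotype contrasts on a bioenergetics parameter
#'
#' Fits log10(value) ~ genotype + (1 | plate) by REML with Satterthwaite
#' degrees of freedom for the genotype t-statistics, the control genotype
#' being the reference level (beta = 0). With a single plate, falls back to
#' ordinary least squares. Nonpositive values cannot be log-transformed and
#' are dropped with a message.
#'
#' @param values data.frame with columns `value`, `genotype`, `plate_id`
#'   (see [params_long()]).
#' @param control reference genotype (default "control").
#' @param parameter optional parameter name carried into the result.
#' @return object of class `flux_model`: `coefficients` data.frame
#'   (genotype, beta, se, df, p), `method` ("lmm" or "ols"), `fit`,
#'   `n_dropped`.
#' @export
genotype_model <- function(values, control = "control", parameter = NA_character_) {
  stopifnot(all(c("value", "genotype", "plate_id") %in% colnames(values)))
  values <- values[!is.na(values$value), , drop = FALSE]
  n_dropped <- sum(values$value <= 0)
  if (n_dropped) {
    message("dropping ", n_dropped, " nonpositive value(s)")
    values <- values[values$value > 0, , drop = FALSE]
  }
  if (length(unique(values$genotype)) < 2)
    stop("need at least 2 genotypes")
  if (!control %in% values$genotype)
    stop("control genotype absent: ", control)
  values$genotype <- stats::relevel(factor(values$genotype), ref = control)
  values$logv <- log10(values$value)
  if (length(unique(values$plate_id)) >= 2) {
    fit <- lmerTest::lmer(logv ~ genotype + (1 | plate_id), data = values)
    cf <- stats::coef(summary(fit))  # Satterthwaite df
    method <- "lmm"
  } else {
    fit <- stats::lm(logv ~ genotype, data = values)
    cf <- stats::coef(summary(fit))
    cf <- cbind(cf[, 1:2, drop = FALSE], df = fit$df.residual,
                cf[, 3:4, drop = FALSE])
    method <- "ols"
  }
  rows <- grepl("^genotype", rownames(cf))
  coefs <- data.frame(genotype = sub("^genotype", "", rownames(cf)[rows]),
                      beta = cf[rows, 1], se = cf[rows, 2],
                      df = cf[rows, "df"], p = cf[rows, ncol(cf)],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(parameter = parameter, coefficients = coefs,
                 method = method, control = control, fit = fit,
                 n_dropped = n_dropped),
            class = "flux_model")
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf("Genotype contrasts on log10(%s) [%s; reference: %s]\n",
              if (is.na(x$parameter)) "value" else x$parameter,
              if (x$method == "lmm") "mixed model, plate random intercept"
              else "OLS, single plate", x$control))
  df <- x$coefficients
  df$beta <- round(df$beta, 4); df$se <- round(df$se, 4)
  df$df <- round(df$df, 1); df$p <- signif(df$p, 3)
  print(df)
  invisible(x)
}

#' @export
coef.flux_model <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$genotype)
}

#' @export
summary.flux_model <- function(object, ...) object$coefficients

#' Reshape one parameter of a params table for modelling
#'
#' @param params a [well_parameters()] result.
#' @param parameter column name of the parameter (e.g. "basal", "maximal").
#' @return data.frame `value, genotype, plate_id` with NA rows removed.
#' @export
params_long <- function(params, parameter) {
  stopifnot(parameter %in% colnames(params))
  out <- data.frame(value = params[[parameter]], genotype = params$group,
                    plate_id = params$plate_id, stringsAsFactors = FALSE)
  out[!is.na(out$value), , drop = FALSE]
}

#' Baseline OCR/ECAR energy ratio
#'
#' Per-well ratio OCR(T3)/ECAR(T3) and group summaries (mean, SEM); wells
#' with zero baseline ECAR are flagged and excluded from summaries.
#'
#' @param plate long-format plate data.frame.
#' @return list with `per_well` (plate_id, well, group, ratio, flagged) and
#'   `per_group` (group, mean, sem, n).
#' @export
energy_ratio <- function(plate) {
  validate_seahorse(plate)
  key <- paste(plate$plate_id, plate$well, sep = "::")
  rows <- lapply(split(plate, key), function(d) {
    d <- d[order(d$timepoint), ]
    data.frame(plate_id = d$plate_id[1], well = d$well[1], group = d$group[1],
               ratio = if (d$ECAR[3] > 0) d$OCR[3] / d$ECAR[3] else NA_real_,
               flagged = d$ECAR[3] <= 0, stringsAsFactors = FALSE)
  })
  per_well <- do.call(rbind, rows)
  rownames(per_well) <- NULL
  ok <- per_well[!per_well$flagged, , drop = FALSE]
  per_group <- do.call(rbind, lapply(split(ok, ok$group), function(d)
    data.frame(group = d$group[1], mean = mean(d$ratio),
               sem = stats::sd(d$ratio) / sqrt(nrow(d)), n = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(per_group) <- NULL
  list(per_well = per_well, per_group = per_group)
}
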
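#' Run the analysis pipeline from a single configuration
#'
#' Orchestrates the stages end-to-end and writes every output as TSV/CSV
#' under `out_dir`, together with a manifest of written files and their MD5
#' hashes. The configuration is a list (or path to a YAML file) with fields:
#'
#' \describe{
#'   \item{out_dir}{output directory (created if absent).}
#'   \item{seed}{integer seed; required when `simulate` is TRUE.}
#'   \item{simulate}{TRUE to generate all inputs with the synthetic-data
#'     module (optionally a list of [sim_config()] overrides); otherwise
#'     file paths must be supplied in `inputs`.}
#'   \item{inputs}{list of paths: `expression`, `metadata`, `gene_sets`
#'     (GMT), `l2fc`, `seahorse`, `qpcr_dilution`, `qpcr_expression`,
#'     `qpcr_mtdna`, `reporter` — only those needed by requested stages.}
#'   \item{driver}{driver gene symbol (default "BRD1").}
#'   \item{gene_set}{name of the gene set in the GMT to test (default:
#'     first set).}
#'   \item{cv_min, hi, lo, bonferroni_m}{analysis thresholds (defaults 0.1,
#'     0.5, -0.5, 33).}
#'   \item{stages}{character vector among `curate`, `coexpr`, `enrich`,
#'     `shift`, `cluster`, `reporter`, `qpcr`, `flux` (default: all).}
#' }
#'
#' Stage dependencies are checked up front (`coexpr` needs `curate`,
#' `enrich` needs `coexpr`, `flux` uses `qpcr` output for the mtDNA
#' adjustment) and a missing prerequisite is an error naming the stage.
#'
#' @param config list or path to a YAML file.
#' @return invisibly, the manifest data.frame (file, md5, stage); also
#'   written to `manifest.tsv` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || !length(config))
    stop("config must be a non-empty list or YAML file")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("curate", "coexpr", "enrich", "shift", "cluster",
                  "reporter", "qpcr", "flux")
  stages <- if (is.null(config$stages)) all_stages
    else match.arg(config$stages, all_stages, several.ok = TRUE)
  deps <- list(coexpr = "curate", enrich = "coexpr", cluster = NULL,
               shift = NULL, flux = NULL)
  for (s in intersect(names(deps), stages)) {
    need <- setdiff(deps[[s]], stages)
    if (length(need))
      stop("stage '", s, "' requires stage '", need, "' to run first")
  }
  simulate <- isTRUE(config$simulate) || is.list(config$simulate)
  if (!simulate && is.null(config$inputs))
    stop("config must set simulate: true or provide inputs")
  driver <- if (is.null(config$driver)) "BRD1" else config$driver
  cv_min <- if (is.null(config$cv_min)) 0.1 else config$cv_min
  hi <- if (is.null(config$hi)) 0.5 else config$hi
  lo <- if (is.null(config$lo)) -0.5 else config$lo
  bonf_m <- if (is.null(config$bonferroni_m)) 33L else config$bonferroni_m

  manifest <- data.frame(file = character(), md5 = character(),
                         stage = character(), stringsAsFactors = FALSE)
  emit <- function(path, stage) {
    manifest[nrow(manifest) + 1L, ] <<-
      list(basename(path), unname(tools::md5sum(path)), stage)
    path
  }
  t0 <- function(stage) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))
    proc.time()[["elapsed"]]
  }

  if (simulate) {
    if (is.null(config$seed)) stop("config$seed is required when simulating")
    args <- if (is.list(config$simulate)) config$simulate else list()
    args$seed <- config$seed
    cfg <- do.call(sim_config, args)
    el <- t0("simulate")
    bs <- simulate_brainspan(cfg)
    lf <- simulate_l2fc(cfg)
    sh <- simulate_seahorse(cfg)
    qp <- simulate_qpcr(cfg)
    rp <- simulate_reporter(cfg)
    emit(write_expression_matrix(bs$expr, file.path(out_dir, "expression.tsv")),
         "simulate")
    emit(write_sample_metadata(bs$metadata, file.path(out_dir, "metadata.tsv")),
         "simulate")
    emit(write_gmt(list(nMT = bs$gene_set), file.path(out_dir, "genesets.gmt")),
         "simulate")
    emit(write_l2fc_table(lf$l2fc, file.path(out_dir, "l2fc.tsv")), "simulate")
    emit(write_seahorse_plates(sh, file.path(out_dir, "seahorse.csv")),
         "simulate")
    emit(write_qpcr_table(qp$dilution_series,
                          file.path(out_dir, "qpcr_dilution.csv")), "simulate")
    emit(write_qpcr_table(qp$expression,
                          file.path(out_dir, "qpcr_expression.csv")), "simulate")
    emit(write_qpcr_table(qp$mtdna, file.path(out_dir, "qpcr_mtdna.csv")),
         "simulate")
    emit(write_reporter_readings(rp, file.path(out_dir, "reporter.csv")),
         "simulate")
    inputs <- list(expression = file.path(out_dir, "expression.tsv"),
                   metadata = file.path(out_dir, "metadata.tsv"),
                   gene_sets = file.path(out_dir, "genesets.gmt"),
                   l2fc = file.path(out_dir, "l2fc.tsv"),
                   seahorse = file.path(out_dir, "seahorse.csv"),
                   qpcr_dilution = file.path(out_dir, "qpcr_dilution.csv"),
                   qpcr_expression = file.path(out_dir, "qpcr_expression.csv"),
                   qpcr_mtdna = file.path(out_dir, "qpcr_mtdna.csv"),
                   reporter = file.path(out_dir, "reporter.csv"))
  } else {
    inputs <- config$inputs
    for (nm in names(inputs))
      if (!file.exists(inputs[[nm]]))
        stop("input file for '", nm, "' does not exist: ", inputs[[nm]])
  }

  need_input <- function(nm, stage) {
    if (is.null(inputs[[nm]]))
      stop("stage '", stage, "' needs input '", nm, "'")
    inputs[[nm]]
  }
  gene_sets <- if (!is.null(inputs$gene_sets)) read_gmt(inputs$gene_sets) else NULL
  pick_set <- function(stage) {
    if (is.null(gene_sets)) stop("stage '", stage, "' needs input 'gene_sets'")
    nm <- if (is.null(config$gene_set)) names(gene_sets)[1] else config$gene_set
    if (!nm %in% names(gene_sets)) stop("gene set not in GMT: ", nm)
    gene_sets[[nm]]
  }

  curated <- NULL
  assignment <- NULL
  if ("curate" %in% stages) {
    t0("curate")
    m <- read_expression_matrix(need_input("expression", "curate"))
    meta <- read_sample_metadata(need_input("metadata", "curate"))
    curated <- filter_genes(m, cv_min = cv_min)
    assignment <- assign_strata(meta)
    report <- attr(curated, "filter_report")
    utils::write.table(
      data.frame(rule = names(report), genes = as.integer(report)),
      emit_path <- file.path(out_dir, "filter_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    emit(emit_path, "curate")
    utils::write.table(assignment, sa <- file.path(out_dir, "strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(sa, "curate")
  }

  profile <- NULL
  if ("coexpr" %in% stages) {
    t0("coexpr")
    profile <- spearman_profile(curated, driver, assignment)
    emit(write_correlation_profile(profile, file.path(out_dir, "profile.tsv")),
         "coexpr")
    sp <- split_profile(profile, pick_set("coexpr"))
    st <- shift_test(sp$r_set, sp$r_background)
    utils::write.table(
      data.frame(U = st$U, p = st$p.value, mode_set = st$mode_set,
                 mode_all = st$mode_all, delta_mode = st$delta_mode),
      sf <- file.path(out_dir, "coexpr_shift.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    emit(sf, "coexpr")
  }

  if ("enrich" %in% stages) {
    t0("enrich")
    scan <- interval_scan(profile, pick_set("enrich"), hi = hi, lo = lo,
                          m = bonf_m)
    utils::write.table(scan, ef <- file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(ef, "enrich")
  }

  if ("shift" %in% stages) {
    t0("shift")
    l2fc <- read_l2fc_table(need_input("l2fc", "shift"))
    gs <- pick_set("shift")
    rows <- do.call(rbind, lapply(colnames(l2fc), function(cond) {
      st <- l2fc_shift(l2fc, cond, gs)
      data.frame(condition = cond, U = st$U, p = st$p.value,
                 median_set = st$median_set, median_all = st$median_all,
                 delta_mode = st$delta_mode, stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, sf <- file.path(out_dir, "l2fc_shift.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(sf, "shift")
  }

  if ("cluster" %in% stages) {
    t0("cluster")
    l2fc <- read_l2fc_table(need_input("l2fc", "cluster"))
    cl <- scale_and_cluster(l2fc, pick_set("cluster"))
    utils::write.table(
      data.frame(gene = cl$order, leaf_position = seq_along(cl$order)),
      cf <- file.path(out_dir, "cluster_order.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    emit(cf, "cluster")
  }

  if ("reporter" %in% stages) {
    t0("reporter")
    rr <- reporter_compare(read_reporter_readings(need_input("reporter",
                                                             "reporter")))
    utils::write.table(rr, rf <- file.path(out_dir, "reporter_compare.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(rf, "reporter")
  }

  mtdna_groups <- NULL
  if ("qpcr" %in% stages) {
    t0("qpcr")
    dil <- read_qpcr_table(need_input("qpcr_dilution", "qpcr"))
    curve <- standard_curve_fit(dil$dilution, dil$ct,
                                amplicon = dil$amplicon[1])
    utils::write.table(
      data.frame(amplicon = curve$amplicon, slope = curve$slope,
                 intercept = curve$intercept, efficiency = curve$efficiency,
                 r_squared = curve$r_squared, accepted = curve$accepted),
      qf <- file.path(out_dir, "standard_curve.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    emit(qf, "qpcr")
    ex <- read_qpcr_table(need_input("qpcr_expression", "qpcr"))
    refs <- ex[ex$class == "nuclear_ref", ]
    ct_mat <- as.matrix(stats::xtabs(ct ~ sample + amplicon, data = refs))
    groups <- refs$group[match(rownames(ct_mat), refs$sample)]
    sel <- stability_select(ct_mat, groups)
    utils::write.table(
      data.frame(candidate = names(sel$stability),
                 stability = unname(sel$stability),
                 in_best_pair = names(sel$stability) %in% sel$best_pair),
      sf <- file.path(out_dir, "reference_stability.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    emit(sf, "qpcr")
    mt <- mtdna_content(read_qpcr_table(need_input("qpcr_mtdna", "qpcr")))
    utils::write.table(mt$per_sample, mf <- file.path(out_dir, "mtdna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(mf, "qpcr")
    if ("group" %in% colnames(mt$per_sample))
      mtdna_groups <- mtdna_group_content(mt, relative_to = "control")
  }

  if ("flux" %in% stages) {
    t0("flux")
    plate <- read_seahorse_plates(need_input("seahorse", "flux"))
    params <- suppressMessages(well_parameters(plate))
    utils::write.table(params, pf <- file.path(out_dir, "flux_params.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(pf, "flux")
    if (!is.null(mtdna_groups) &&
        all(unique(plate$group) %in% names(mtdna_groups))) {
      adj <- adjust_by_mtdna(plate, mtdna_groups)
      params_adj <- suppressMessages(well_parameters(adj))
      utils::write.table(params_adj,
                         af <- file.path(out_dir, "flux_params_adjusted.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(af, "flux")
    } else {
      params_adj <- NULL
    }
    use <- if (is.null(params_adj)) params else params_adj
    fit_rows <- list()
    for (par in c("basal", "atp_linked", "proton_leak", "maximal")) {
      lv <- params_long(use, par)
      if (!nrow(lv) || length(unique(lv$genotype)) < 2) next
      md <- suppressMessages(genotype_model(lv, parameter = par))
      fit_rows[[par]] <- cbind(parameter = par, md$coefficients)
    }
    if (length(fit_rows)) {
      utils::write.table(do.call(rbind, fit_rows),
                         gf <- file.path(out_dir, "flux_model.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(gf, "flux")
    }
  }

  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
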
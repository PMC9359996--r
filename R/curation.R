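#' Default spatiotemporal grouping scheme
#'
#' Loads the shipped YAML mapping of age labels to eight temporal groups
#' (p1-p8) and region labels to four regional groups (r1-r4). Together these
#' define 32 spatiotemporal intervals; downstream analyses add the synthetic
#' overall stratum `pall` for a universe of 33 strata.
#'
#' Temporal groups cover, inclusively: p1 = 8-13 pcw, p2 = 16-26 pcw,
#' p3 = 35-37 pcw, p4 = 4-10 months, p5 = 1-4 years, p6 = 8-13 years,
#' p7 = 15-19 years, p8 = 21-40 years. Ages in the gaps between bins are
#' deliberately rejected rather than silently binned.
#'
#' @param path optional path to an alternative YAML scheme.
#' @return list with elements `temporal` (data.frame group/unit/min/max) and
#'   `regional` (named character vector, region label -> group).
#' @export
spatiotemporal_scheme <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "spatiotemporal_scheme.yaml",
                        package = "mitoscope", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  temporal <- do.call(rbind, lapply(raw$temporal, as.data.frame))
  regional <- unlist(lapply(names(raw$regional), function(g) {
    stats::setNames(rep(g, length(raw$regional[[g]])), raw$regional[[g]])
  }))
  if (length(unique(temporal$group)) != 8L)
    stop("scheme must define exactly 8 temporal groups")
  if (length(unique(regional)) != 4L)
    stop("scheme must define exactly 4 regional groups")
  structure(list(temporal = temporal, regional = regional),
            class = "spatiotemporal_scheme")
}

# Parse "<number> pcw|mos|yrs" into value + unit; errors on anything else.
parse_age_label <- function(age) {
  m <- regmatches(age, regexec("^\\s*([0-9]+(?:\\.[0-9]+)?)\\s*(pcw|mos|yrs)\\s*$", age))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("unparseable age label(s): ", paste(unique(age[bad]), collapse = ", "))
  data.frame(value = as.numeric(vapply(m, `[`, character(1), 2L)),
             unit = vapply(m, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

temporal_group <- function(age, scheme) {
  parsed <- parse_age_label(age)
  out <- character(length(age))
  for (i in seq_along(age)) {
    hit <- scheme$temporal$unit == parsed$unit[i] &
      scheme$temporal$min <= parsed$value[i] &
      scheme$temporal$max >= parsed$value[i]
    if (sum(hit) != 1L)
      stop("age label not covered by any temporal group: '", age[i], "'")
    out[i] <- scheme$temporal$group[hit]
  }
  out
}

#' Assign samples to spatiotemporal strata
#'
#' Maps each sample's age label to a temporal group and its region label to a
#' regional group, yielding one (p, r) stratum per sample. Unknown labels are
#' an error naming the offending label.
#'
#' @param metadata data.frame with columns `sample_id`, `age`, `region` (and
#'   typically `donor_id`).
#' @param scheme a [spatiotemporal_scheme()].
#' @return data.frame with columns `sample_id`, `temporal`, `regional`,
#'   `stratum` (e.g. "p3r2"), classed `stratum_assignment`.
#' @export
assign_strata <- function(metadata, scheme = spatiotemporal_scheme()) {
  stopifnot(all(c("sample_id", "age", "region") %in% colnames(metadata)))
  p <- temporal_group(metadata$age, scheme)
  unknown <- setdiff(unique(metadata$region), names(scheme$regional))
  if (length(unknown))
    stop("region label(s) not covered by the scheme: ",
         paste(unknown, collapse = ", "))
  r <- unname(scheme$regional[metadata$region])
  out <- data.frame(sample_id = metadata$sample_id, temporal = p, regional = r,
                    stratum = paste0(p, r), stringsAsFactors = FALSE)
  class(out) <- c("stratum_assignment", "data.frame")
  out
}

#' List the stratum universe of an assignment
#'
#' @param assignment a [assign_strata()] result.
#' @return character vector: "pall" followed by the nonempty (p, r) strata in
#'   sorted order.
#' @export
stratum_universe <- function(assignment) {
  c("pall", sort(unique(assignment$stratum)))
}

#' Filter an expression matrix for informative genes
#'
#' Applies, in order: restriction to a protein-coding list (when given),
#' removal of genes with any missing value, and removal of genes whose overall
#' coefficient of variation (sample sd / mean, computed across all samples on
#' the provided expression scale) is below `cv_min`. The attached
#' `filter_report` attribute counts genes removed by each rule.
#'
#' @param m numeric matrix, genes x samples, unique rownames.
#' @param cv_min minimum coefficient of variation to retain a gene.
#' @param protein_coding optional character vector of allowed gene symbols.
#' @return filtered matrix with attribute `filter_report` (named integer
#'   vector: not_protein_coding, missing_data, low_cv, retained).
#' @export
filter_genes <- function(m, cv_min = 0.1, protein_coding = NULL) {
  stopifnot(is.matrix(m), nrow(m) > 0)
  if (anyDuplicated(rownames(m))) stop("gene symbols must be unique")
  n0 <- nrow(m)
  n_pc <- 0L
  if (!is.null(protein_coding)) {
    keep <- rownames(m) %in% protein_coding
    n_pc <- sum(!keep)
    m <- m[keep, , drop = FALSE]
  }
  has_na <- apply(m, 1, anyNA)
  n_na <- sum(has_na)
  m <- m[!has_na, , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  cv <- ifelse(mu == 0, ifelse(sdv == 0, 0, Inf), sdv / mu)
  low <- cv < cv_min
  n_cv <- sum(low)
  m <- m[!low, , drop = FALSE]
  if (nrow(m) == 0) stop("empty matrix: all genes removed by filters")
  attr(m, "filter_report") <- c(not_protein_coding = n_pc,
                                missing_data = n_na,
                                low_cv = n_cv,
                                retained = nrow(m))
  stopifnot(n_pc + n_na + n_cv == n0 - nrow(m))
  m
}
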
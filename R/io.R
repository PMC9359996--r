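#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column is `gene_symbol` and whose
#' remaining columns are one sample each. Gene symbols must be unique.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows (rownames = gene symbols), samples in
#'   columns.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_symbol")
    stop("expected first column 'gene_symbol' in ", path)
  if (anyDuplicated(df$gene_symbol))
    stop("duplicate gene symbols in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_symbol
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV
#'
#' @param m numeric matrix with gene symbols as rownames.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_symbol = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `donor_id`, `age`, `region`.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "donor_id", "age", "region")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to the .gmt file.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a log2-fold-change table
#'
#' TSV with a `gene` column and one `L2FC_<condition>` column per condition.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows, conditions in columns (prefix
#'   `L2FC_` stripped from column names).
#' @export
read_l2fc_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene") stop("expected first column 'gene' in ", path)
  if (anyDuplicated(df$gene)) stop("duplicate genes in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  colnames(m) <- sub("^L2FC_", "", colnames(m))
  storage.mode(m) <- "double"
  m
}

#' @rdname read_l2fc_table
#' @param m numeric matrix of L2FC values (genes x conditions).
#' @export
write_l2fc_table <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-1] <- paste0("L2FC_", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read extracellular-flux plate data (long format)
#'
#' CSV with columns `plate_id, well, group, scheme, timepoint, OCR, ECAR`;
#' nine timepoints per well, scheme is `oligomycin` or `FCCP`.
#'
#' @param path path to the CSV file.
#' @return data.frame of per-well traces.
#' @export
read_seahorse_plates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "group", "scheme", "timepoint", "OCR", "ECAR")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("plate file missing column(s): ", paste(miss, collapse = ", "))
  validate_seahorse(df)
  df
}

#' Read a wide (instrument-export style) flux plate file
#'
#' CSV with columns `plate_id, well, group, scheme, OCR_1..OCR_9,
#' ECAR_1..ECAR_9`; converted to the long format used throughout.
#'
#' @param path path to the CSV file.
#' @return long-format data.frame as [read_seahorse_plates()].
#' @export
read_seahorse_wide <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ocr_cols <- paste0("OCR_", 1:9)
  ecar_cols <- paste0("ECAR_", 1:9)
  miss <- setdiff(c("plate_id", "well", "group", "scheme", ocr_cols, ecar_cols),
                  colnames(df))
  if (length(miss))
    stop("wide plate file missing column(s): ", paste(miss, collapse = ", "))
  long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    data.frame(plate_id = df$plate_id[i], well = df$well[i],
               group = df$group[i], scheme = df$scheme[i], timepoint = 1:9,
               OCR = as.numeric(df[i, ocr_cols]),
               ECAR = as.numeric(df[i, ecar_cols]),
               stringsAsFactors = FALSE)
  }))
  validate_seahorse(long)
  long
}

#' @rdname read_seahorse_plates
#' @param plate long-format plate data.frame.
#' @export
write_seahorse_plates <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_seahorse <- function(df) {
  key <- paste(df$plate_id, df$well)
  tp <- tapply(df$timepoint, key, function(t) identical(sort(t), 1:9))
  if (!all(unlist(tp)))
    stop("every well must have exactly timepoints 1..9")
  if (any(df$OCR < 0, na.rm = TRUE)) stop("negative OCR values")
  bad <- setdiff(unique(df$scheme), c("oligomycin", "FCCP"))
  if (length(bad)) stop("unknown injection scheme: ", paste(bad, collapse = ", "))
  invisible(df)
}

#' Read a qPCR Ct table
#'
#' CSV with columns `sample, group, amplicon, class, dilution, replicate, ct`;
#' `class` is one of target, nuclear_ref, mito; `dilution` may be empty (NA)
#' for non-standard-curve rows.
#'
#' @param path path to the CSV file.
#' @return data.frame of Ct readings.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "amplicon", "class", "dilution", "replicate", "ct")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("qPCR table missing column(s): ", paste(miss, collapse = ", "))
  df$ct <- as.numeric(df$ct)
  df$dilution <- as.numeric(df$dilution)
  if (any(df$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  if (any(df$dilution <= 0, na.rm = TRUE)) stop("dilutions must be positive")
  df
}

#' @rdname read_qpcr_table
#' @param tab qPCR data.frame.
#' @export
write_qpcr_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read dual-luciferase reporter readings
#'
#' CSV with columns `pathway, group, well, firefly, renilla`.
#'
#' @param path path to the CSV file.
#' @return data.frame of readings.
#' @export
read_reporter_readings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pathway", "group", "well", "firefly", "renilla")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("reporter file missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$renilla <= 0)) stop("renilla readings must be positive")
  df
}

#' @rdname read_reporter_readings
#' @param readings reporter data.frame.
#' @export
write_reporter_readings <- function(readings, path) {
  utils::write.csv(readings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a correlation profile (long TSV: gene, stratum, r, n)
#'
#' @param path file path.
#' @return data.frame with columns gene, stratum, r, n.
#' @export
read_correlation_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "stratum", "r", "n")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("profile missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("correlation_profile", "data.frame")
  df
}

#' @rdname read_correlation_profile
#' @param profile correlation profile data.frame.
#' @export
write_correlation_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
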
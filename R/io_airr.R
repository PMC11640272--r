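#' Read an AIRR Rearrangement TSV of single-cell TCR contigs
#'
#' Parses a tab-separated file in the AIRR Community Rearrangement dialect
#' (one row per assembled contig) into a validated contig table. Only TRA and
#' TRB loci are retained; rows carrying other loci (TRG, TRD, IGH, ...) are
#' dropped with a warning giving the count. A missing `duplicate_count`
#' column (or an NA value in it) yields `umi_count = 1`.
#'
#' @param path path to the TSV. The header must contain at least
#'   `cell_id`, `locus`, `v_call`, `j_call`, `junction_aa`, `productive`.
#' @return a `data.frame` with columns `cell_id`, `locus` (`"TRA"`/`"TRB"`),
#'   `v_call`, `j_call`, `junction_aa`, `productive` (logical),
#'   `umi_count` (integer >= 0).
#' @export
read_airr_rearrangements <- function(path) {
  if (!file.exists(path)) format_error(sprintf("AIRR file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, na.strings = c("", "NA"))
  required <- c("cell_id", "locus", "v_call", "j_call", "junction_aa", "productive")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    format_error(sprintf("%s: missing mandatory column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  productive <- parse_airr_bool(df$productive, "productive", path)
  if ("duplicate_count" %in% names(df)) {
    raw <- df$duplicate_count
    umi <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & (is.na(umi) | umi < 0 | umi != floor(umi)))
    if (length(bad) > 0) {
      format_error(sprintf(
        "%s: unparseable duplicate_count at data row %d (value '%s')",
        path, bad[1], raw[bad[1]]))
    }
    umi[is.na(umi)] <- 1
  } else {
    umi <- rep(1, nrow(df))
  }
  contigs <- data.frame(
    cell_id = df$cell_id,
    locus = df$locus,
    v_call = df$v_call,
    j_call = df$j_call,
    junction_aa = ifelse(is.na(df$junction_aa), "", df$junction_aa),
    productive = productive,
    umi_count = as.integer(umi),
    stringsAsFactors = FALSE
  )
  keep <- contigs$locus %in% c("TRA", "TRB")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d contig(s) with locus outside {TRA, TRB}", n_dropped),
            call. = FALSE)
  }
  contigs <- contigs[keep, , drop = FALSE]
  rownames(contigs) <- NULL
  validate_contigs(contigs)
  contigs
}

validate_contigs <- function(contigs) {
  stopifnot(is.data.frame(contigs))
  if (any(contigs$umi_count < 0)) format_error("umi_count must be >= 0")
  bad <- contigs$productive & (is.na(contigs$junction_aa) | !nzchar(contigs$junction_aa))
  if (any(bad)) {
    format_error(sprintf("%d productive contig(s) with empty junction_aa", sum(bad)))
  }
  invisible(contigs)
}

#' Write contigs to an AIRR Rearrangement TSV
#'
#' Inverse of [read_airr_rearrangements()]; `umi_count` is written to the
#' AIRR `duplicate_count` column and `productive` as `T`/`F`.
#'
#' @param contigs contig `data.frame` as returned by
#'   [read_airr_rearrangements()] or [simulate_repertoire()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr_rearrangements <- function(contigs, path) {
  out <- data.frame(
    cell_id = contigs$cell_id,
    locus = contigs$locus,
    v_call = contigs$v_call,
    j_call = contigs$j_call,
    junction_aa = contigs$junction_aa,
    productive = ifelse(contigs$productive, "T", "F"),
    duplicate_count = contigs$umi_count,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cells-by-genes count matrix
#'
#' Accepts either a dense CSV (header row = gene symbols, first column =
#' cell ids) or a Matrix Market triplet file accompanied by `*_cells.txt`
#' and `*_genes.txt` sidecars (one id per line, rows = cells, columns =
#' genes). Counts must be non-negative integers; duplicate cell or gene ids
#' are an error.
#'
#' @param path path to the `.csv` or `.mtx` file.
#' @return a base integer matrix with cells as rownames and genes as colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) format_error(sprintf("expression file not found: %s", path))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    cells_f <- paste0(stem, "_cells.txt")
    genes_f <- paste0(stem, "_genes.txt")
    if (!file.exists(cells_f) || !file.exists(genes_f)) {
      format_error(sprintf("missing sidecar files %s / %s", cells_f, genes_f))
    }
    rownames(m) <- readLines(cells_f)
    colnames(m) <- readLines(genes_f)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
  }
  validate_expression_matrix(m, path)
}

validate_expression_matrix <- function(m, what = "expression matrix") {
  if (anyDuplicated(rownames(m))) format_error(sprintf("%s: duplicate cell ids", what))
  if (anyDuplicated(colnames(m))) format_error(sprintf("%s: duplicate gene ids", what))
  if (length(m) > 0) {
    if (any(is.na(m))) format_error(sprintf("%s: NA counts", what))
    if (any(m < 0)) format_error(sprintf("%s: negative counts", what))
    if (any(m != floor(m))) format_error(sprintf("%s: non-integer counts", what))
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as Matrix Market triplets or dense CSV
#'
#' @param m integer matrix, cells in rows, genes in columns.
#' @param path output path; a `.mtx` suffix selects Matrix Market (with
#'   `*_cells.txt`/`*_genes.txt` sidecars), anything else dense CSV.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(rownames(m), paste0(stem, "_cells.txt"))
    writeLines(colnames(m), paste0(stem, "_genes.txt"))
  } else {
    utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  }
  invisible(path)
}

binding_score_columns <- c(
  "cdr3_alpha", "cdr3_beta", "v_alpha", "j_alpha", "v_beta", "j_beta",
  "peptide", "mhc", "t_cell_type", "score"
)

#' Read a per-clonotype binding-score CSV
#'
#' The file follows the output convention of sequence-based TCR-pMHC binding
#' predictors: one row per (clonotype, peptide, MHC) query with a `score`
#' in \[0, 1\]. Scores are never clamped; any out-of-range value raises a
#' validation error naming the row, as does a duplicated query key.
#'
#' @param path path to the CSV with columns `cdr3_alpha, cdr3_beta, v_alpha,
#'   j_alpha, v_beta, j_beta, peptide, mhc, t_cell_type, score`.
#' @return a validated `data.frame` with those ten columns.
#' @export
read_binding_scores <- function(path) {
  if (!file.exists(path)) format_error(sprintf("score file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  missing <- setdiff(binding_score_columns, names(df))
  if (length(missing) > 0) {
    format_error(sprintf("%s: missing column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  df <- df[binding_score_columns]
  df$score <- suppressWarnings(as.numeric(df$score))
  validate_binding_scores(df, path)
  df
}

validate_binding_scores <- function(df, what = "binding scores") {
  bad <- which(is.na(df$score) | df$score < 0 | df$score > 1)
  if (length(bad) > 0) {
    validation_error(sprintf(
      "%s: score outside [0, 1] at row(s) %s",
      what, paste(utils::head(bad, 5), collapse = ", ")))
  }
  keys <- do.call(paste, c(df[c("cdr3_alpha", "cdr3_beta", "v_alpha", "j_alpha",
                                "v_beta", "j_beta", "peptide", "mhc")],
                           sep = "\r"))
  if (anyDuplicated(keys)) {
    validation_error(sprintf("%s: duplicate query keys at row(s) %s",
                             what,
                             paste(utils::head(which(duplicated(keys)), 5),
                                   collapse = ", ")))
  }
  invisible(df)
}

#' Write a binding-score table to CSV
#'
#' @param scores `data.frame` in the layout of [read_binding_scores()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binding_scores <- function(scores, path) {
  utils::write.csv(scores[binding_score_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read per-cell sample-tag (donor) labels
#'
#' @param path CSV with columns `cell_id, donor`.
#' @return `data.frame` with unique `cell_id` and `donor` columns.
#' @export
read_sample_tags <- function(path) {
  if (!file.exists(path)) format_error(sprintf("sample-tag file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("cell_id", "donor") %in% names(df))) {
    format_error(sprintf("%s: expected columns cell_id, donor", path))
  }
  if (anyDuplicated(df$cell_id)) {
    format_error(sprintf("%s: duplicate cell_id in sample tags", path))
  }
  df[c("cell_id", "donor")]
}

#' Write per-cell sample-tag labels
#' @param tags `data.frame` with `cell_id`, `donor`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_tags <- function(tags, path) {
  utils::write.csv(tags[c("cell_id", "donor")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
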
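#' Describe the peptide-MHC context of a binding query
#'
#' Binding predictors score a TCR against one peptide presented by one MHC
#' allele on one T-cell lineage. The default context is the HER2/neu-derived
#' HLA-A2-restricted 9-mer KIFGSLAFL on CD8 cells.
#'
#' @param peptide amino-acid string, uppercase IUPAC; length 8-11 for MHC
#'   class I.
#' @param mhc allele string, passed through verbatim (predictor vocabularies
#'   differ; no normalization is attempted).
#' @param t_cell_type `"CD8"` or `"CD4"`.
#' @return a `peptide_context` list.
#' @export
peptide_context <- function(peptide = "KIFGSLAFL", mhc = "HLA-A*02:01",
                            t_cell_type = c("CD8", "CD4")) {
  t_cell_type <- match.arg(t_cell_type)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptide)) {
    validation_error("peptide must be uppercase IUPAC amino acids")
  }
  if (nchar(peptide) < 8 || nchar(peptide) > 11) {
    validation_error("class I peptide length must be 8-11 residues")
  }
  if (!nzchar(mhc)) validation_error("mhc must be non-empty")
  structure(list(peptide = peptide, mhc = mhc, t_cell_type = t_cell_type),
            class = "peptide_context")
}

#' Build predictor-input queries for every clonotype
#'
#' One query row per full-length clonotype, carrying the six receptor
#' components plus the peptide context, in deterministic key-sorted order.
#' Optionally written as the CSV an external TCR-pMHC predictor consumes
#' (the score-table layout minus the `score` column).
#'
#' @param table full-length clonotype table.
#' @param ctx a [peptide_context()].
#' @param path optional CSV output path.
#' @return `data.frame` of queries (9 columns).
#' @export
build_predictor_input <- function(table, ctx, path = NULL) {
  stopifnot(attr(table, "resolution") == "full_length",
            inherits(ctx, "peptide_context"))
  if (nrow(table) > 0 &&
      any(!nzchar(table$cdr3_alpha) | !nzchar(table$cdr3_beta))) {
    validation_error("clonotype with empty CDR3 cannot be queried")
  }
  q <- as.data.frame(table[full_length_key_cols])
  q <- q[c("cdr3_alpha", "cdr3_beta", "v_alpha", "j_alpha", "v_beta", "j_beta")]
  q$peptide <- rep(ctx$peptide, nrow(q))
  q$mhc <- rep(ctx$mhc, nrow(q))
  q$t_cell_type <- rep(ctx$t_cell_type, nrow(q))
  ord <- do.call(order, q[c("cdr3_alpha", "cdr3_beta", "v_alpha", "j_alpha",
                            "v_beta", "j_beta")])
  q <- q[ord, , drop = FALSE]
  rownames(q) <- NULL
  if (!is.null(path)) {
    utils::write.csv(q, path, row.names = FALSE, quote = FALSE)
  }
  q
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, in double arithmetic.
# The multiply is split into 16-bit halves so every intermediate stays
# below 2^53 and the result is exact.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor2_32(h, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  h
}

# XOR of a 32-bit value (double) with a byte
bitwXor2_32 <- function(h, b) {
  lo <- h %% 256
  h - lo + bitwXor(as.integer(lo), as.integer(b))
}

#' Deterministic stand-in score provider
#'
#' A test double for an external TCR-pMHC binding predictor: each query is
#' scored by a stable non-cryptographic digest (32-bit FNV-1a) of the
#' UTF-8 concatenation of its nine fields, divided by the digest's maximum
#' value, giving a platform-independent score in \[0, 1\]. The same query
#' always yields the same score, across sessions and machines; the scores
#' carry no biological meaning.
#'
#' @param queries query `data.frame` from [build_predictor_input()].
#' @return a binding-score `data.frame` (the queries plus a `score` column).
#' @export
stub_predictor <- function(queries) {
  fields <- c("cdr3_alpha", "cdr3_beta", "v_alpha", "j_alpha", "v_beta",
              "j_beta", "peptide", "mhc", "t_cell_type")
  concat <- do.call(paste, c(queries[fields], sep = "|"))
  out <- queries[fields]
  out$score <- vapply(concat, function(s) fnv1a32(s) / 4294967295, numeric(1),
                      USE.NAMES = FALSE)
  out
}

#' Validate a binding-score table and summarise its range
#'
#' @param scores binding-score `data.frame`.
#' @return list with `pass` (all scores in \[0, 1\]), `n`, `min`, `max`,
#'   and `offending_rows` (indices of out-of-range scores, if any).
#' @export
validate_scores <- function(scores) {
  bad <- which(is.na(scores$score) | scores$score < 0 | scores$score > 1)
  list(
    pass = length(bad) == 0,
    n = nrow(scores),
    min = if (nrow(scores) > 0) min(scores$score) else NA_real_,
    max = if (nrow(scores) > 0) max(scores$score) else NA_real_,
    offending_rows = bad
  )
}
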
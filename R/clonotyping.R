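#' Pair alpha and beta chains per cell
#'
#' Each cell is represented by at most one TRA and one TRB chain chosen from
#' its productive contigs. When a cell carries several productive contigs of
#' the same locus, the chain with the highest `umi_count` wins; ties are
#' broken by the lexicographically smallest `junction_aa` so the result is
#' deterministic. Cells with no productive chain of either locus are omitted.
#'
#' @param contigs contig `data.frame` (see [read_airr_rearrangements()]).
#' @return a `data.frame` with one row per cell: `cell_id`,
#'   `v_alpha`, `j_alpha`, `cdr3_alpha`, `v_beta`, `j_beta`, `cdr3_beta`
#'   (NA for an absent chain) and `complete` (TRUE iff both chains present).
#' @export
pair_chains <- function(contigs) {
  prod <- contigs[contigs$productive & contigs$locus %in% c("TRA", "TRB"), ,
                  drop = FALSE]
  empty <- data.frame(
    cell_id = character(), v_alpha = character(), j_alpha = character(),
    cdr3_alpha = character(), v_beta = character(), j_beta = character(),
    cdr3_beta = character(), complete = logical(), stringsAsFactors = FALSE
  )
  if (nrow(prod) == 0) return(empty)
  # order so that the first row per (cell, locus) is the chosen chain
  ord <- order(prod$cell_id, prod$locus, -prod$umi_count, prod$junction_aa)
  prod <- prod[ord, , drop = FALSE]
  first <- !duplicated(paste(prod$cell_id, prod$locus, sep = "\r"))
  n_ambiguous <- sum(!first)
  if (n_ambiguous > 0) {
    message(sprintf("resolved %d cell/locus ambiguities by highest UMI count",
                    n_ambiguous))
  }
  sel <- prod[first, , drop = FALSE]
  cells <- sort(unique(sel$cell_id))
  a <- sel[sel$locus == "TRA", , drop = FALSE]
  b <- sel[sel$locus == "TRB", , drop = FALSE]
  ai <- match(cells, a$cell_id)
  bi <- match(cells, b$cell_id)
  out <- data.frame(
    cell_id = cells,
    v_alpha = a$v_call[ai], j_alpha = a$j_call[ai], cdr3_alpha = a$junction_aa[ai],
    v_beta = b$v_call[bi], j_beta = b$j_call[bi], cdr3_beta = b$junction_aa[bi],
    stringsAsFactors = FALSE
  )
  out$complete <- !is.na(out$cdr3_alpha) & !is.na(out$cdr3_beta)
  rownames(out) <- NULL
  out
}

full_length_key_cols <- c("v_alpha", "j_alpha", "cdr3_alpha",
                          "v_beta", "j_beta", "cdr3_beta")
cdr3_pair_key_cols <- c("cdr3_alpha", "cdr3_beta")

clonotype_key_cols <- function(resolution) {
  switch(resolution,
         full_length = full_length_key_cols,
         cdr3_pair = cdr3_pair_key_cols,
         stop("resolution must be 'full_length' or 'cdr3_pair'"))
}

#' Count clonotypes at full-length or CDR3-pair resolution
#'
#' Partitions the complete cells (both chains present) into clonotypes.
#' At `full_length` resolution the key is the six-tuple (V-alpha, J-alpha,
#' CDR3-alpha, V-beta, J-beta, CDR3-beta) with allele suffixes stripped from
#' the gene calls; at `cdr3_pair` resolution only the two CDR3 amino-acid
#' sequences define identity. The full-length partition always refines the
#' CDR3-pair partition.
#'
#' @param cells paired-receptor `data.frame` from [pair_chains()].
#' @param resolution `"full_length"` (default) or `"cdr3_pair"`.
#' @return a clonotype table: `data.frame` with the key columns, `cell_count`,
#'   `binding_score` (NA until [attach_scores()]), and a `cell_ids` list
#'   column; rows sorted by key; attribute `resolution` records the key type.
#' @export
count_clonotypes <- function(cells, resolution = c("full_length", "cdr3_pair")) {
  resolution <- match.arg(resolution)
  key_cols <- clonotype_key_cols(resolution)
  complete <- cells[cells$complete, , drop = FALSE]
  if (nrow(complete) == 0) {
    warning("no complete cells: returning an empty clonotype table", call. = FALSE)
    tab <- stats::setNames(
      as.data.frame(matrix(character(), 0, length(key_cols)),
                    stringsAsFactors = FALSE), key_cols)
    tab$cell_count <- integer()
    tab$binding_score <- numeric()
    tab$cell_ids <- list()
    attr(tab, "resolution") <- resolution
    class(tab) <- c("clonotype_table", "data.frame")
    return(tab)
  }
  keyed <- complete[key_cols]
  for (col in intersect(key_cols, c("v_alpha", "j_alpha", "v_beta", "j_beta"))) {
    keyed[[col]] <- strip_allele(keyed[[col]])
  }
  key <- do.call(paste, c(keyed, sep = "\r"))
  groups <- split(seq_len(nrow(complete)), key)
  ord <- order(names(groups))
  groups <- groups[ord]
  tab <- keyed[vapply(groups, `[`, integer(1), 1), , drop = FALSE]
  tab$cell_count <- unname(vapply(groups, length, integer(1)))
  tab$binding_score <- NA_real_
  tab$cell_ids <- unname(lapply(groups, function(i) complete$cell_id[i]))
  rownames(tab) <- NULL
  attr(tab, "resolution") <- resolution
  class(tab) <- c("clonotype_table", "data.frame")
  tab
}

#' Remove clonotypes represented by a single cell
#'
#' Singleton clonotypes are uninformative for expansion-based selection and
#' are dropped before downstream analysis. The report mirrors QC output:
#' `retained_pct = 100 * n_after / n_before`, rounded half-up to one decimal
#' (NA, flagged, for an empty input table).
#'
#' @param table a clonotype table from [count_clonotypes()].
#' @return a list with `retained` (the filtered table) and `report`
#'   (`n_before`, `n_after`, `retained_pct`).
#' @export
filter_singletons <- function(table) {
  n_before <- nrow(table)
  retained <- table[table$cell_count >= 2, , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "resolution") <- attr(table, "resolution")
  class(retained) <- class(table)
  n_after <- nrow(retained)
  pct <- if (n_before == 0) {
    warning("empty clonotype table: retained_pct undefined", call. = FALSE)
    NA_real_
  } else {
    round_half_up(100 * n_after / n_before, 1)
  }
  list(retained = retained,
       report = list(n_before = n_before, n_after = n_after, retained_pct = pct))
}

#' Attach predicted binding scores to a full-length clonotype table
#'
#' Joins score rows to clonotypes on the six full-length key components
#' (allele-stripped). Clonotypes without a matching row keep an NA score and
#' are counted in a warning; two score rows matching one clonotype is an
#' error (the join must be unambiguous).
#'
#' @param table full-length clonotype table.
#' @param scores binding-score `data.frame` (see [read_binding_scores()]).
#' @return the table with `binding_score` filled where matched.
#' @export
attach_scores <- function(table, scores) {
  stopifnot(attr(table, "resolution") == "full_length")
  if (nrow(table) == 0) return(table)
  tab_key <- do.call(paste, c(table[full_length_key_cols], sep = "\r"))
  sc <- scores
  for (col in c("v_alpha", "j_alpha", "v_beta", "j_beta")) {
    sc[[col]] <- strip_allele(sc[[col]])
  }
  sc_key <- do.call(paste, c(sc[full_length_key_cols], sep = "\r"))
  hits <- lapply(tab_key, function(k) which(sc_key == k))
  n_hits <- lengths(hits)
  if (any(n_hits > 1)) {
    validation_error(sprintf(
      "ambiguous score match: %d clonotype(s) matched by more than one score row",
      sum(n_hits > 1)))
  }
  unmatched <- sum(n_hits == 0)
  if (unmatched > 0) {
    warning(sprintf("%d clonotype(s) have no binding score", unmatched),
            call. = FALSE)
  }
  table$binding_score[n_hits == 1] <- sc$score[unlist(hits[n_hits == 1])]
  table
}

#' Select the dominant clonotype
#'
#' The dominant clonotype is the most expanded one; among clonotypes tied at
#' the maximum cell count, the highest predicted binding score wins, and any
#' residual tie falls back to the lexicographically smallest key so the
#' selection is deterministic and invariant to row order. All max-count
#' clonotypes must carry a score (binding specificity is the discriminator
#' the method relies on).
#'
#' @param table a scored full-length clonotype table with at least one row.
#' @return a list: `key` (named character vector of the six components),
#'   `cell_count`, `binding_score`, `cell_ids`, and `candidates` (the
#'   max-count subtable the score decided among).
#' @export
select_dominant <- function(table) {
  stopifnot(attr(table, "resolution") == "full_length")
  if (nrow(table) == 0) format_error("cannot select a dominant clonotype from an empty table")
  max_count <- max(table$cell_count)
  cand <- table[table$cell_count == max_count, , drop = FALSE]
  if (any(is.na(cand$binding_score))) {
    format_error(sprintf(
      "%d max-count clonotype(s) lack a binding score; attach scores before selection",
      sum(is.na(cand$binding_score))))
  }
  key_str <- do.call(paste, c(cand[full_length_key_cols], sep = "\r"))
  ord <- order(-cand$binding_score, key_str)
  best <- cand[ord[1], , drop = FALSE]
  list(
    key = stats::setNames(unlist(best[1, full_length_key_cols]),
                          full_length_key_cols),
    cell_count = best$cell_count,
    binding_score = best$binding_score,
    cell_ids = best$cell_ids[[1]],
    candidates = cand
  )
}

#' Contrast CDR3-pair and full-length clonotype resolution
#'
#' Two cells can share their CDR3 alpha-beta amino-acid pair yet use
#' different V/J genes, i.e. carry different receptors. For every CDR3 pair
#' this reports how many cells express it, how many distinct full-length
#' clonotypes hide underneath, and the size of the largest one — the
#' discrepancy that shows CDR3 sequences alone under-resolve TCR identity.
#'
#' @param cells paired-receptor `data.frame` with at least one complete cell.
#' @return `data.frame` with `cdr3_alpha`, `cdr3_beta`, `pair_cell_count`,
#'   `n_full_length_clonotypes`, `max_full_length_count`, sorted by
#'   decreasing `pair_cell_count`.
#' @export
compare_resolutions <- function(cells) {
  full <- count_clonotypes(cells, "full_length")
  if (nrow(full) == 0) format_error("no complete cells to compare")
  pair_key <- paste(full$cdr3_alpha, full$cdr3_beta, sep = "\r")
  agg <- lapply(split(seq_len(nrow(full)), pair_key), function(i) {
    data.frame(
      cdr3_alpha = full$cdr3_alpha[i[1]],
      cdr3_beta = full$cdr3_beta[i[1]],
      pair_cell_count = sum(full$cell_count[i]),
      n_full_length_clonotypes = length(i),
      max_full_length_count = max(full$cell_count[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$pair_cell_count, out$cdr3_alpha, out$cdr3_beta), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a clonotype table to CSV
#'
#' @param table clonotype table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(table, path) {
  out <- as.data.frame(table[setdiff(names(table), "cell_ids")])
  out <- cbind(resolution = attr(table, "resolution"), out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a dominant clonotype as JSON and FASTA
#'
#' Writes `<stem>.json` with the key, cell count and score, and
#' `<stem>.fasta` with the CDR3 alpha/beta amino-acid sequences — the
#' hand-off to receptor-construct design.
#'
#' @param dominant result of [select_dominant()].
#' @param stem output path stem (without extension).
#' @return character vector of the two paths, invisibly.
#' @export
export_dominant <- function(dominant, stem) {
  json_path <- paste0(stem, ".json")
  fasta_path <- paste0(stem, ".fasta")
  jsonlite::write_json(
    list(key = as.list(dominant$key),
         cell_count = dominant$cell_count,
         binding_score = dominant$binding_score,
         cell_ids = dominant$cell_ids),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    ">CDR3_alpha", unname(dominant$key["cdr3_alpha"]),
    ">CDR3_beta", unname(dominant$key["cdr3_beta"])
  ), fasta_path)
  invisible(c(json_path, fasta_path))
}
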
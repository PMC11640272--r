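#' Cell-recovery percentage
#'
#' Fraction of loaded cells the platform successfully called as singlets,
#' as a percentage rounded half-up to one decimal (18000 loaded and 4989
#' called gives 27.7).
#'
#' @param n_loaded cells loaded into the cartridge (> 0).
#' @param n_called single cells called by the upstream pipeline.
#' @return percentage, one decimal.
#' @export
compute_recovery <- function(n_loaded, n_called) {
  if (n_loaded <= 0) format_error("n_loaded must be > 0")
  if (n_called > n_loaded) {
    warning("more cells called than loaded; check inputs", call. = FALSE)
  }
  round_half_up(100 * n_called / n_loaded, 1)
}

#' Run the dominant-clonotype discovery pipeline end to end
#'
#' Executes the full sequence: read (or accept in-memory) inputs, pair
#' chains, count full-length clonotypes, filter singletons, attach binding
#' scores, select the dominant clonotype, log2-CPM normalize, assemble
#' features, PCA, UMAP, HDBSCAN, phenotype clusters, and measure the
#' dominant clonotype's cluster cohesion. Any stage failure aborts with the
#' stage name. The run is deterministic for a fixed `seed`.
#'
#' @param airr contigs `data.frame` or path to an AIRR TSV.
#' @param expr count matrix or path (CSV/MTX).
#' @param tags sample-tag `data.frame` or path, optional.
#' @param scores binding-score `data.frame` or path; if NULL and
#'   `stub_scores = TRUE`, the deterministic stub scores every clonotype.
#' @param stub_scores use [stub_predictor()] instead of external scores.
#' @param ctx a [peptide_context()] (used for stub queries and reporting).
#' @param n_loaded optional number of cells loaded upstream, for the
#'   recovery percentage.
#' @param markers marker genes for features and phenotyping.
#' @param pca_k,n_neighbors,min_dist,min_cluster_size embedding parameters.
#' @param seed seed for the stochastic stages (UMAP layout).
#' @param out_dir optional directory; when given, all artifacts (clonotype
#'   tables, embedding CSV, report JSON, dominant-clonotype JSON/FASTA) are
#'   written there.
#' @return list with `qc` (the summary), `cells`, `clonotypes` (filtered,
#'   scored), `clonotypes_unfiltered`, `resolution_comparison`, `dominant`,
#'   `embedding` (pca/umap/labels), `phenotypes`, `cohesion`.
#' @export
run_pipeline <- function(airr, expr, tags = NULL, scores = NULL,
                         stub_scores = is.null(scores),
                         ctx = peptide_context(), n_loaded = NULL,
                         markers = default_markers,
                         pca_k = NULL, n_neighbors = 15L, min_dist = 0.1,
                         min_cluster_size = 5L, seed = 42L, out_dir = NULL) {
  stage <- function(name, expr_) {
    tryCatch(expr_, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  contigs <- stage("read_airr", {
    if (is.character(airr)) read_airr_rearrangements(airr) else airr
  })
  m <- stage("read_expression", {
    if (is.character(expr)) read_expression_matrix(expr)
    else validate_expression_matrix(expr)
  })
  tag_df <- if (is.character(tags)) stage("read_tags", read_sample_tags(tags)) else tags

  cells <- stage("pair_chains", pair_chains(contigs))
  full <- stage("count_clonotypes", count_clonotypes(cells, "full_length"))
  if (nrow(full) == 0) format_error("pipeline stage 'count_clonotypes' failed: no complete cells")
  filt <- stage("filter_singletons", filter_singletons(full))

  score_df <- stage("scores", {
    if (!is.null(scores)) {
      if (is.character(scores)) read_binding_scores(scores) else scores
    } else if (stub_scores) {
      stub_predictor(build_predictor_input(full, ctx))
    } else {
      format_error("no binding scores given and stub scoring disabled")
    }
  })
  scored <- stage("attach_scores", attach_scores(filt$retained, score_df))
  dominant <- stage("select_dominant", select_dominant(scored))
  comparison <- stage("compare_resolutions", compare_resolutions(cells))

  norm <- stage("normalize", normalize_log2_cpm(m))
  features <- stage("assemble_features", assemble_features(norm, scored, markers))
  if (is.null(pca_k)) pca_k <- min(8L, ncol(features))
  pca <- stage("pca", run_pca(features, pca_k))
  umap <- stage("umap", run_umap(pca$coords, seed = seed,
                                 n_neighbors = n_neighbors, min_dist = min_dist))
  labels <- stage("hdbscan", run_hdbscan(umap, min_cluster_size = min_cluster_size))
  phenotypes <- stage("phenotype", phenotype_clusters(labels, norm, markers))
  cohesion <- stage("cohesion", dominant_cohesion(labels, rownames(norm), dominant))

  qc <- list(
    n_loaded = n_loaded,
    n_called_cells = nrow(m),
    recovery_pct = if (!is.null(n_loaded)) compute_recovery(n_loaded, nrow(m)) else NULL,
    n_cells_with_tcr = nrow(cells),
    n_complete_cells = sum(cells$complete),
    n_clonotypes_before = filt$report$n_before,
    n_after_singleton_filter = filt$report$n_after,
    retained_pct = filt$report$retained_pct,
    n_clusters = length(setdiff(unique(labels), -1L)),
    n_noise_cells = sum(labels == -1L),
    dominant_key = as.list(dominant$key),
    dominant_cell_count = dominant$cell_count,
    dominant_binding_score = dominant$binding_score,
    dominant_cohesion = cohesion$fraction,
    seed = seed,
    parameters = list(markers = markers, pca_k = pca_k,
                      n_neighbors = n_neighbors, min_dist = min_dist,
                      min_cluster_size = min_cluster_size)
  )
  result <- list(qc = qc, cells = cells, clonotypes = scored,
                 clonotypes_unfiltered = full,
                 resolution_comparison = comparison, dominant = dominant,
                 embedding = list(pca = pca, umap = umap, labels = labels,
                                  seed = seed),
                 phenotypes = phenotypes, cohesion = cohesion, tags = tag_df)
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  result
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_clonotype_table(result$clonotypes,
                        file.path(out_dir, "clonotypes_filtered.csv"))
  write_clonotype_table(result$clonotypes_unfiltered,
                        file.path(out_dir, "clonotypes_full.csv"))
  utils::write.csv(result$resolution_comparison,
                   file.path(out_dir, "resolution_comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  emb <- data.frame(
    cell_id = rownames(result$embedding$umap),
    result$embedding$pca$coords,
    UMAP1 = result$embedding$umap[, 1],
    UMAP2 = result$embedding$umap[, 2],
    cluster = result$embedding$labels
  )
  utils::write.csv(emb, file.path(out_dir, "embedding.csv"), row.names = FALSE)
  utils::write.csv(result$phenotypes, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  export_dominant(result$dominant, file.path(out_dir, "dominant_clonotype"))
  write_report(result$qc, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Write the QC summary as JSON
#'
#' @param qc the `qc` element of a [run_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(qc, path) {
  jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
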
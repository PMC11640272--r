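#' Default marker panel for cluster phenotyping
#'
#' Canonical reporting order: lineage markers first (CD8, CD4), then the
#' regulatory marker FOXP3, then the cytotoxicity program (NKG7, GZMA, GZMB).
#' @export
default_markers <- c("CD8", "CD4", "FOXP3", "NKG7", "GZMA", "GZMB")

#' Log2 counts-per-million normalization
#'
#' Per cell: `cpm = counts * 1e6 / sum(counts)`, returned as `log2(cpm + 1)`.
#' Cells with zero total counts stay all-zero (counted in a warning) rather
#' than producing NaN.
#'
#' @param m cells-by-genes count matrix (non-negative integers).
#' @return numeric matrix of the same shape and dimnames.
#' @export
normalize_log2_cpm <- function(m) {
  if (nrow(m) < 1) format_error("expression matrix has no cells")
  if (any(m < 0)) format_error("negative counts")
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero cell(s) left at zero after normalization",
                    sum(zero)), call. = FALSE)
  }
  denom <- ifelse(zero, 1, totals)
  cpm <- m * (1e6 / denom)
  log2(cpm + 1)
}

#' Assemble the per-cell feature matrix for co-embedding
#'
#' The clustering space co-embeds three kinds of information: normalized
#' marker expression, clonal expansion (log2 of the cell's full-length
#' clonotype size), and the clonotype's predicted binding score. Cells
#' without a complete receptor (or without a scored clonotype) contribute 0
#' for the derived features before scaling. Every column is z-scored;
#' zero-variance columns are left at 0 after centering (with a message)
#' so degenerate inputs do not poison the embedding.
#'
#' @param norm normalized expression matrix from [normalize_log2_cpm()].
#' @param table scored full-length clonotype table (may be the filtered one).
#' @param markers marker genes to use; all must be in the panel.
#' @return numeric matrix, cells x (markers + clone_size + binding_score),
#'   rownames = cell ids.
#' @export
assemble_features <- function(norm, table, markers = default_markers) {
  missing <- setdiff(markers, colnames(norm))
  if (length(missing) > 0) {
    format_error(sprintf(
      "marker gene(s) %s not in the %d-gene panel",
      paste(missing, collapse = ", "), ncol(norm)))
  }
  cells <- rownames(norm)
  clone_size <- rep(0, length(cells))
  score <- rep(0, length(cells))
  if (nrow(table) > 0) {
    for (k in seq_len(nrow(table))) {
      idx <- match(table$cell_ids[[k]], cells)
      idx <- idx[!is.na(idx)]
      clone_size[idx] <- log2(table$cell_count[k])
      s <- table$binding_score[k]
      score[idx] <- if (is.na(s)) 0 else s
    }
  }
  n_unassigned <- sum(clone_size == 0)
  if (n_unassigned > 0) {
    message(sprintf(
      "%d cell(s) without a counted clonotype: clone_size/score set to 0",
      n_unassigned))
  }
  f <- cbind(norm[, markers, drop = FALSE],
             clone_size = clone_size, binding_score = score)
  zscore_columns(f)
}

zscore_columns <- function(f) {
  mu <- colMeans(f)
  sd <- apply(f, 2L, stats::sd)
  flat <- is.na(sd) | sd == 0
  if (any(flat)) {
    message(sprintf("zero-variance feature(s) left at 0: %s",
                    paste(colnames(f)[flat], collapse = ", ")))
    sd[flat] <- 1
  }
  scaled <- sweep(sweep(f, 2L, mu, "-"), 2L, sd, "/")
  scaled
}

#' Principal component analysis of the feature matrix
#'
#' Thin wrapper over [stats::prcomp()] (centered, unscaled — features are
#' already z-scored upstream) returning the pieces the pipeline reports.
#'
#' @param f feature matrix from [assemble_features()].
#' @param k number of components, `<= ncol(f)`.
#' @return list with `coords` (cells x k), `explained_variance_ratio`
#'   (non-increasing, sums to <= 1).
#' @export
run_pca <- function(f, k = min(8L, ncol(f))) {
  if (k > ncol(f)) format_error(sprintf("k = %d exceeds %d features", k, ncol(f)))
  p <- stats::prcomp(f, center = TRUE, scale. = FALSE)
  evr <- p$sdev^2 / sum(p$sdev^2)
  list(coords = p$x[, seq_len(k), drop = FALSE],
       explained_variance_ratio = evr[seq_len(min(k, length(evr)))])
}

#' UMAP co-embedding
#'
#' Deterministic 2-D embedding via `uwot::umap` with a fixed seed and a
#' single SGD thread (multi-threaded stochastic gradient descent is not
#' reproducible).
#'
#' @param coords input coordinates (typically PCA scores).
#' @param seed RNG seed.
#' @param n_neighbors,min_dist UMAP graph/layout parameters.
#' @return cells x 2 coordinate matrix.
#' @export
run_umap <- function(coords, seed = 42L, n_neighbors = 15L, min_dist = 0.1) {
  if (nrow(coords) < n_neighbors + 1L) {
    format_error(sprintf(
      "%d cells is too few for n_neighbors = %d; reduce n_neighbors",
      nrow(coords), n_neighbors))
  }
  set.seed(seed)
  out <- uwot::umap(as.matrix(coords), n_neighbors = n_neighbors,
                    min_dist = min_dist, n_threads = 1, n_sgd_threads = 0,
                    verbose = FALSE)
  rownames(out) <- rownames(coords)
  colnames(out) <- c("UMAP1", "UMAP2")
  out
}

#' Cluster embedded cells with HDBSCAN
#'
#' @param coords embedded coordinates (cells x 2 from [run_umap()], or any
#'   numeric matrix).
#' @param min_cluster_size smallest group reported as a cluster.
#' @return integer labels, `-1` = noise.
#' @export
run_hdbscan <- function(coords, min_cluster_size = 5L) {
  hdbscan_labels(as.matrix(coords), min_cluster_size = min_cluster_size)
}

#' Assign marker phenotypes to clusters
#'
#' For each non-noise cluster and marker, the sign is `+` iff the cluster's
#' median normalized expression strictly exceeds the global median across
#' all cells (a scale-free criterion with no tuned cutoffs); otherwise `-`.
#' The phenotype string concatenates the markers in panel order, e.g.
#' `"CD8+ CD4- FOXP3- NKG7+ GZMA+ GZMB+"` for a cytotoxic cluster.
#'
#' @param labels cluster labels (from [run_hdbscan()]); `-1` ignored.
#' @param norm normalized expression matrix (rows align with `labels`).
#' @param markers marker genes in reporting order.
#' @return `data.frame` with one row per cluster: `cluster`, `n_cells`, one
#'   sign column per marker, and `phenotype` (the concatenated string).
#' @export
phenotype_clusters <- function(labels, norm, markers = default_markers) {
  stopifnot(length(labels) == nrow(norm))
  clusters <- sort(unique(labels[labels != -1L]))
  if (length(clusters) == 0) format_error("no non-noise clusters to phenotype")
  global_med <- apply(norm[, markers, drop = FALSE], 2L, stats::median)
  rows <- lapply(clusters, function(cl) {
    sub <- norm[labels == cl, markers, drop = FALSE]
    med <- apply(sub, 2L, stats::median)
    signs <- ifelse(med > global_med, "+", "-")
    out <- data.frame(cluster = cl, n_cells = nrow(sub),
                      stringsAsFactors = FALSE)
    for (mk in markers) out[[mk]] <- unname(signs[mk])
    out$phenotype <- paste0(markers, signs, collapse = " ")
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Cluster cohesion of the dominant clonotype
#'
#' How tightly the dominant clonotype's cells co-localize in the clustering:
#' the modal (most frequent) non-noise cluster among its member cells, and
#' the fraction of members found there. If every member is noise the mode is
#' taken over the noise label and the result flagged.
#'
#' @param labels cluster labels aligned with `cell_ids`.
#' @param cell_ids cell ids aligned with `labels`.
#' @param dominant result of [select_dominant()].
#' @return list: `modal_cluster`, `n_in_modal_cluster`, `n_members`,
#'   `fraction`, `all_noise` flag.
#' @export
dominant_cohesion <- function(labels, cell_ids, dominant) {
  idx <- match(dominant$cell_ids, cell_ids)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) format_error("no dominant-clonotype member has coordinates")
  member_labels <- labels[idx]
  pool <- member_labels[member_labels != -1L]
  all_noise <- length(pool) == 0
  if (all_noise) {
    warning("all dominant-clonotype members are noise; cohesion over noise label",
            call. = FALSE)
    pool <- member_labels
  }
  counts <- table(pool)
  modal <- as.integer(names(counts)[which.max(counts)])
  n_modal <- max(counts)
  list(modal_cluster = modal,
       n_in_modal_cluster = as.integer(n_modal),
       n_members = length(member_labels),
       fraction = as.numeric(n_modal) / length(member_labels),
       all_noise = all_noise)
}
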
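#' @name gene_pools
#' @title Small V/J gene-segment name pools used by the simulator
#' @description Compact TRAV/TRAJ/TRBV/TRBJ name lists; clonotype identity in
#' this pipeline is gene-level, so a small pool is enough to exercise the
#' keying logic while keeping collision structure realistic.
#' @keywords internal
NULL

trav_pool <- paste0("TRAV", 1:12)
traj_pool <- paste0("TRAJ", c(3, 6, 9, 12, 15, 18, 21, 24, 27, 30, 33, 37))
trbv_pool <- paste0("TRBV", c(2, 4, 5, 6, 7, 9, 11, 12, 19, 20, 27, 28))
trbj_pool <- paste0("TRBJ", c("1-1", "1-2", "1-5", "2-1", "2-3", "2-7"))

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# deterministic CDR3: junction "C" + base-20 encoding of an integer + "F"
aa_code <- function(i, len = 9) {
  digits <- integer(len)
  for (k in seq_len(len)) {
    digits[k] <- i %% 20L
    i <- i %/% 20L
  }
  paste0("C", paste(aa_alphabet[digits + 1L], collapse = ""), "F")
}

random_cdr3 <- function(n, min_len = 8, max_len = 16) {
  lens <- sample(seq(min_len, max_len), n, replace = TRUE)
  vapply(lens, function(l) {
    paste0("C", paste(sample(aa_alphabet, l - 2, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

#' Specify a synthetic TCR repertoire
#'
#' Clone sizes follow a Zipf law (cells assigned to clones with probability
#' proportional to rank^-s), the standard caricature of clonal expansion:
#' a few antigen-driven clones dominate, a long tail of singletons follows.
#' An explicit size list overrides the law. With `plant_dominant = TRUE` the
#' first clone is topped up (cells moved from the smallest clones) until it
#' holds at least `dominant_factor` times the runner-up — the planted ground
#' truth recovery tests look for.
#'
#' @param n_cells total cells.
#' @param n_clones clones to draw sizes for (empty clones are dropped).
#' @param zipf_s Zipf exponent, > 0; default 1.5.
#' @param sizes optional explicit clone sizes (must sum to `n_cells`).
#' @param n_donors donors for sample-tag labels; default 3.
#' @param dropout per-cell probability of losing one chain, in \[0, 1).
#' @param plant_dominant enforce the planted-dominance margin on clone 1.
#' @param dominant_factor required size ratio over the runner-up.
#' @return a `repertoire_spec` list.
#' @export
repertoire_spec <- function(n_cells = 500, n_clones = 120, zipf_s = 1.5,
                            sizes = NULL, n_donors = 3, dropout = 0,
                            plant_dominant = TRUE, dominant_factor = 2) {
  if (!is.null(sizes) && sum(sizes) != n_cells) {
    validation_error("explicit clone sizes must sum to n_cells")
  }
  if (zipf_s <= 0) validation_error("zipf_s must be > 0")
  if (dropout < 0 || dropout >= 1) validation_error("dropout must be in [0, 1)")
  structure(list(n_cells = n_cells, n_clones = n_clones, zipf_s = zipf_s,
                 sizes = sizes, n_donors = n_donors, dropout = dropout,
                 plant_dominant = plant_dominant,
                 dominant_factor = dominant_factor),
            class = "repertoire_spec")
}

#' Simulate a paired-chain TCR repertoire
#'
#' Each clone receives a distinct (V, J, CDR3) for both chains (CDR3s are
#' random IUPAC strings framed by the conserved C...F junction residues);
#' every cell inherits its clone's chains as two productive contigs with
#' random UMI counts; chain dropout then removes the alpha or beta contig of
#' a cell with the specified probability. Deterministic given `seed`.
#'
#' @param spec a [repertoire_spec()].
#' @param seed RNG seed.
#' @return list with `contigs` (AIRR-style contig `data.frame`), `tags`
#'   (cell_id/donor), and `ground_truth` (`clones` table with key columns
#'   and `size`, plus `planted_key`).
#' @export
simulate_repertoire <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "repertoire_spec"))
  set.seed(seed)
  sizes <- spec$sizes
  if (is.null(sizes)) {
    prob <- seq_len(spec$n_clones)^(-spec$zipf_s)
    assign <- sample(spec$n_clones, spec$n_cells, replace = TRUE,
                     prob = prob / sum(prob))
    sizes <- tabulate(assign, nbins = spec$n_clones)
    if (spec$plant_dominant) sizes <- enforce_dominance(sizes, spec$dominant_factor)
  }
  keep <- sizes > 0
  sizes <- sizes[keep]
  n_clones <- length(sizes)

  keys <- draw_distinct_keys(n_clones)
  clones <- cbind(keys, data.frame(size = sizes))
  cell_ids <- sprintf("cell_%05d", seq_len(spec$n_cells))
  clone_of_cell <- rep(seq_len(n_clones), sizes)

  n <- length(cell_ids)
  contigs <- data.frame(
    cell_id = rep(cell_ids, each = 2L),
    locus = rep(c("TRA", "TRB"), times = n),
    v_call = as.vector(rbind(clones$v_alpha[clone_of_cell],
                             clones$v_beta[clone_of_cell])),
    j_call = as.vector(rbind(clones$j_alpha[clone_of_cell],
                             clones$j_beta[clone_of_cell])),
    junction_aa = as.vector(rbind(clones$cdr3_alpha[clone_of_cell],
                                  clones$cdr3_beta[clone_of_cell])),
    productive = TRUE,
    umi_count = sample(1:50, 2L * n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (spec$dropout > 0) {
    drop_cell <- stats::runif(n) < spec$dropout
    which_chain <- sample(c("TRA", "TRB"), n, replace = TRUE)
    kill <- paste(contigs$cell_id, contigs$locus) %in%
      paste(cell_ids[drop_cell], which_chain[drop_cell])
    contigs <- contigs[!kill, , drop = FALSE]
    rownames(contigs) <- NULL
  }
  tags <- data.frame(
    cell_id = cell_ids,
    donor = paste0("donor_", sample(seq_len(spec$n_donors), n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  list(
    contigs = contigs,
    tags = tags,
    ground_truth = list(
      clones = clones,
      clone_of_cell = stats::setNames(clone_of_cell, cell_ids),
      planted_key = unlist(clones[1, full_length_key_cols])
    )
  )
}

# move cells from the smallest clones into clone 1 until it is at least
# `factor` times the runner-up
enforce_dominance <- function(sizes, factor) {
  if (length(sizes) < 2) return(sizes)
  repeat {
    runner_up <- max(sizes[-1])
    need <- ceiling(factor * runner_up) - sizes[1]
    if (need <= 0) break
    donors <- which(sizes > 0)
    donors <- donors[donors != 1L]
    smallest <- donors[which.min(sizes[donors])]
    take <- min(need, sizes[smallest])
    sizes[smallest] <- sizes[smallest] - take
    sizes[1] <- sizes[1] + take
  }
  sizes
}

draw_distinct_keys <- function(n_clones, max_tries = 100L) {
  draw <- function(n) data.frame(
    v_alpha = sample(trav_pool, n, replace = TRUE),
    j_alpha = sample(traj_pool, n, replace = TRUE),
    cdr3_alpha = random_cdr3(n),
    v_beta = sample(trbv_pool, n, replace = TRUE),
    j_beta = sample(trbj_pool, n, replace = TRUE),
    cdr3_beta = random_cdr3(n),
    stringsAsFactors = FALSE
  )
  keys <- draw(n_clones)
  for (try in seq_len(max_tries)) {
    kk <- do.call(paste, c(keys, sep = "\r"))
    dup <- duplicated(kk)
    if (!any(dup)) return(keys)
    keys[dup, ] <- draw(sum(dup))
  }
  format_error("could not draw distinct clonotype keys; reduce n_clones")
}

#' Specify synthetic marker expression
#'
#' Negative-binomial counts per population profile. The default two profiles
#' mirror an antigen-expanded culture: a cytotoxic effector population
#' (CD8/NKG7/GZMA/GZMB high, CD4/FOXP3 low) against a non-cytotoxic rest.
#' Non-marker panel genes share one background profile.
#'
#' @param profiles named list: population -> named vector of marker NB means.
#' @param dispersion NB size parameter (larger = closer to Poisson).
#' @param n_genes total panel size including the markers; default 397.
#' @param background_mean NB mean for non-marker genes.
#' @return an `expression_spec` list.
#' @export
expression_spec <- function(
    profiles = list(
      cytotoxic = c(CD8 = 80, CD4 = 8, FOXP3 = 8, NKG7 = 80, GZMA = 80, GZMB = 80),
      other = c(CD8 = 8, CD4 = 60, FOXP3 = 30, NKG7 = 8, GZMA = 8, GZMB = 8)
    ),
    dispersion = 20, n_genes = 397, background_mean = 5) {
  for (p in profiles) {
    if (any(p <= 0)) validation_error("profile means must be > 0")
  }
  if (dispersion <= 0) validation_error("dispersion must be > 0")
  structure(list(profiles = profiles, dispersion = dispersion,
                 n_genes = n_genes, background_mean = background_mean),
            class = "expression_spec")
}

#' Simulate a targeted-panel count matrix
#'
#' @param cell_ids cell identifiers (row order of the output).
#' @param populations population label per cell; must name a profile.
#' @param spec an [expression_spec()].
#' @param seed RNG seed.
#' @return integer matrix, cells x `n_genes`; marker columns named per the
#'   profiles, background genes `BG001...`.
#' @export
simulate_expression <- function(cell_ids, populations, spec = expression_spec(),
                                seed = 1L) {
  stopifnot(inherits(spec, "expression_spec"),
            length(cell_ids) == length(populations))
  unknown <- setdiff(unique(populations), names(spec$profiles))
  if (length(unknown) > 0) {
    format_error(sprintf("unknown population(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  set.seed(seed)
  markers <- names(spec$profiles[[1]])
  n <- length(cell_ids)
  n_bg <- spec$n_genes - length(markers)
  m <- matrix(0L, n, spec$n_genes,
              dimnames = list(cell_ids,
                              c(markers, sprintf("BG%03d", seq_len(n_bg)))))
  for (pop in names(spec$profiles)) {
    idx <- which(populations == pop)
    if (length(idx) == 0) next
    mu <- spec$profiles[[pop]]
    for (k in seq_along(markers)) {
      m[idx, k] <- stats::rnbinom(length(idx), mu = mu[k], size = spec$dispersion)
    }
  }
  m[, length(markers) + seq_len(n_bg)] <-
    stats::rnbinom(n * n_bg, mu = spec$background_mean, size = spec$dispersion)
  storage.mode(m) <- "integer"
  m
}

#' Simulate per-clonotype binding scores with a planted winner
#'
#' Non-planted clonotypes draw Beta(a, b) scores; the planted clonotype gets
#' the maximum of those plus a margin, capped at 1, making it the strict
#' argmax (Beta draws are < 1 almost surely).
#'
#' @param table full-length clonotype table to score.
#' @param planted_key named character vector of the planted clonotype's six
#'   key components (or NULL for no planting).
#' @param ctx a [peptide_context()].
#' @param shape1,shape2 Beta parameters for background scores.
#' @param margin planted score margin over the background maximum.
#' @param seed RNG seed.
#' @return a binding-score `data.frame` (one row per clonotype).
#' @export
simulate_binding_scores <- function(table, planted_key = NULL,
                                    ctx = peptide_context(),
                                    shape1 = 2, shape2 = 5, margin = 0.05,
                                    seed = 1L) {
  set.seed(seed)
  q <- build_predictor_input(table, ctx)
  scores <- stats::rbeta(nrow(q), shape1, shape2)
  if (!is.null(planted_key) && nrow(q) > 0) {
    hit <- q$cdr3_alpha == planted_key["cdr3_alpha"] &
      q$cdr3_beta == planted_key["cdr3_beta"] &
      q$v_alpha == planted_key["v_alpha"] &
      q$j_alpha == planted_key["j_alpha"] &
      q$v_beta == planted_key["v_beta"] &
      q$j_beta == planted_key["j_beta"]
    if (!any(hit)) format_error("planted key not present in the clonotype table")
    background_max <- if (sum(!hit) > 0) max(scores[!hit]) else 0
    scores[hit] <- min(1, background_max + margin)
  }
  q$score <- scores
  q
}

#' Simulate a complete single-cell TCR + expression dataset
#'
#' Bundles repertoire, expression (cytotoxic profile planted on the dominant
#' clone's cells), binding scores (planted strict argmax), and donor tags,
#' together with the ground truth a recovery test needs. Everything is
#' deterministic given `seed`.
#'
#' @param seed RNG seed driving all four generators.
#' @param rep_spec a [repertoire_spec()].
#' @param expr_spec an [expression_spec()].
#' @param ctx a [peptide_context()].
#' @return list with `contigs`, `expression`, `tags`, `scores`,
#'   `ground_truth`.
#' @export
simulate_dataset <- function(seed = 1L, rep_spec = repertoire_spec(),
                             expr_spec = expression_spec(),
                             ctx = peptide_context()) {
  rep <- simulate_repertoire(rep_spec, seed = seed)
  cells <- pair_chains(rep$contigs)
  table <- count_clonotypes(cells, "full_length")
  planted <- rep$ground_truth$planted_key
  scores <- simulate_binding_scores(table, planted_key = planted, ctx = ctx,
                                    seed = seed + 1000L)
  cell_ids <- names(rep$ground_truth$clone_of_cell)
  populations <- ifelse(rep$ground_truth$clone_of_cell == 1L,
                        "cytotoxic", "other")
  expression <- simulate_expression(cell_ids, populations, expr_spec,
                                    seed = seed + 2000L)
  rep$ground_truth$populations <- stats::setNames(populations, cell_ids)
  list(contigs = rep$contigs, expression = expression, tags = rep$tags,
       scores = scores, ground_truth = rep$ground_truth)
}

#' Four-population marker profiles for clustering studies
#'
#' Well-separated T-cell caricatures — cytotoxic effector, regulatory
#' (CD4/FOXP3), helper (CD4), naive CD8 — used to test that the embedding
#' and density clustering recover planted population structure. Off-profile
#' markers sit at a baseline mean of 8 rather than near zero: at targeted-
#' panel depth, expressed genes rarely drop to exact zeros, and a baseline
#' keeps the log2-CPM feature space continuous instead of splitting each
#' population along zero/nonzero count boundaries.
#'
#' @return named list of four marker-mean vectors.
#' @export
four_population_profiles <- function() {
  list(
    cytotoxic = c(CD8 = 80, CD4 = 8, FOXP3 = 8, NKG7 = 80, GZMA = 80, GZMB = 80),
    treg = c(CD8 = 8, CD4 = 80, FOXP3 = 80, NKG7 = 8, GZMA = 8, GZMB = 8),
    helper = c(CD8 = 8, CD4 = 80, FOXP3 = 8, NKG7 = 8, GZMA = 8, GZMB = 8),
    naive_cd8 = c(CD8 = 80, CD4 = 8, FOXP3 = 8, NKG7 = 8, GZMA = 8, GZMB = 8)
  )
}

#' Planted four-population clustering study
#'
#' One replicate of the clustering-recovery experiment: simulate four
#' equally sized populations with the [four_population_profiles()] marker
#' means on a monoclonal TCR background (the planted structure is purely
#' transcriptional, so the clone-size and binding-score features are
#' zero-variance and drop out of the embedding), normalize, assemble
#' features, embed with PCA + UMAP, and cluster with HDBSCAN.
#'
#' @param seed RNG seed for the replicate.
#' @param n_per cells per population.
#' @param min_cluster_size HDBSCAN parameter.
#' @return list: `n_clusters` (non-noise), `labels`, `populations`.
#' @export
four_population_study <- function(seed, n_per = 60L, min_cluster_size = 5L) {
  profs <- four_population_profiles()
  populations <- rep(names(profs), each = n_per)
  cell_ids <- sprintf("cell_%04d", seq_along(populations))
  m <- simulate_expression(cell_ids, populations,
                           expression_spec(profiles = profs), seed = seed)
  norm <- normalize_log2_cpm(m)
  f <- suppressMessages(zscore_columns(
    cbind(norm[, default_markers, drop = FALSE],
          clone_size = 0, binding_score = 0)))
  pca <- run_pca(f)
  umap <- run_umap(pca$coords, seed = seed)
  labels <- run_hdbscan(umap, min_cluster_size = min_cluster_size)
  list(n_clusters = length(setdiff(unique(labels), -1L)),
       labels = labels,
       populations = populations)
}

#' Build the deterministic worked-example fixture
#'
#' Encodes, with no randomness, the repertoire structure of the study this
#' pipeline operationalizes: three maximally expanded full-length clonotypes
#' of 7 cells each; one of the three shares its CDR3 alpha-beta pair with
#' seven further 2-cell clonotypes that differ only in V/J genes (so the
#' pair spans 7 + 7*2 = 21 cells while no single receptor exceeds 7);
#' 100 background 2-cell clonotypes and 1319 singleton clonotypes (1429
#' clonotypes in all, 110 of them surviving the singleton filter, 7.7%).
#' Binding scores set the shared-pair 7-cell clonotype (0.52) above its two
#' rivals (0.31, 0.47); the cytotoxic expression profile is planted on its
#' member cells. Expression counts are deterministic (profile means plus a
#' small index-based ripple), so repeated calls are byte-identical.
#'
#' @return list with `contigs`, `expression`, `tags`, `scores`,
#'   `ground_truth` (as in [simulate_dataset()]).
#' @export
build_paper_fixture <- function() {
  shared_a <- "CAVRDSNYQLIF"
  shared_b <- "CASSLGQAYEQYF"
  main <- data.frame(
    v_alpha = c("TRAV1", "TRAV3", "TRAV5"),
    j_alpha = c("TRAJ33", "TRAJ12", "TRAJ21"),
    cdr3_alpha = c(shared_a, "CAGGGSQGNLIF", "CALSEARQLTF"),
    v_beta = c("TRBV19", "TRBV6", "TRBV28"),
    j_beta = c("TRBJ2-7", "TRBJ1-1", "TRBJ2-1"),
    cdr3_beta = c(shared_b, "CASSQDRNTEAFF", "CASSPTSGSYNEQFF"),
    size = 7L,
    stringsAsFactors = FALSE
  )
  sharers <- data.frame(
    v_alpha = trav_pool[2:8],
    j_alpha = traj_pool[c(1:3, 5:8)],
    cdr3_alpha = shared_a,
    v_beta = trbv_pool[c(1:4, 6:8)],
    j_beta = trbj_pool[c(1:5, 1, 2)],
    cdr3_beta = shared_b,
    size = 2L,
    stringsAsFactors = FALSE
  )
  n_bg2 <- 100L
  n_bg1 <- 1319L
  idx2 <- seq_len(n_bg2)
  idx1 <- n_bg2 + seq_len(n_bg1)
  bg_keys <- function(idx, size) data.frame(
    v_alpha = trav_pool[(idx %% 12L) + 1L],
    j_alpha = traj_pool[((idx %/% 12L) %% 12L) + 1L],
    cdr3_alpha = vapply(idx, aa_code, character(1), len = 9),
    v_beta = trbv_pool[((idx * 5L) %% 12L) + 1L],
    j_beta = trbj_pool[((idx * 7L) %% 6L) + 1L],
    cdr3_beta = vapply(idx + 10000L, aa_code, character(1), len = 10),
    size = size,
    stringsAsFactors = FALSE
  )
  clones <- rbind(main, sharers, bg_keys(idx2, 2L), bg_keys(idx1, 1L))
  n_cells <- sum(clones$size)
  cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
  clone_of_cell <- rep(seq_len(nrow(clones)), clones$size)

  n <- n_cells
  contigs <- data.frame(
    cell_id = rep(cell_ids, each = 2L),
    locus = rep(c("TRA", "TRB"), times = n),
    v_call = as.vector(rbind(clones$v_alpha[clone_of_cell],
                             clones$v_beta[clone_of_cell])),
    j_call = as.vector(rbind(clones$j_alpha[clone_of_cell],
                             clones$j_beta[clone_of_cell])),
    junction_aa = as.vector(rbind(clones$cdr3_alpha[clone_of_cell],
                                  clones$cdr3_beta[clone_of_cell])),
    productive = TRUE,
    umi_count = 1L,
    stringsAsFactors = FALSE
  )

  # deterministic expression: profile mean plus an index ripple in [-2, 2]
  profiles <- expression_spec()$profiles
  markers <- names(profiles$cytotoxic)
  n_genes <- 397L
  n_bg_genes <- n_genes - length(markers)
  gene_ids <- c(markers, sprintf("BG%03d", seq_len(n_bg_genes)))
  pop <- ifelse(clone_of_cell == 1L, "cytotoxic", "other")
  m <- matrix(0L, n, n_genes, dimnames = list(cell_ids, gene_ids))
  ripple <- function(i, j) ((i * 3L + j * 5L) %% 5L) - 2L
  cell_idx <- seq_len(n)
  for (k in seq_along(markers)) {
    mu <- ifelse(pop == "cytotoxic",
                 profiles$cytotoxic[markers[k]], profiles$other[markers[k]])
    m[, k] <- pmax(0L, as.integer(round(mu)) + ripple(cell_idx, k))
  }
  for (k in seq_len(n_bg_genes)) {
    m[, length(markers) + k] <- pmax(0L, 5L + ripple(cell_idx, k + 6L))
  }

  tags <- data.frame(
    cell_id = cell_ids,
    donor = paste0("donor_", (seq_len(n) %% 3L) + 1L),
    stringsAsFactors = FALSE
  )

  ctx <- peptide_context()
  cells <- pair_chains(contigs)
  table <- count_clonotypes(cells, "full_length")
  scores <- stub_predictor(build_predictor_input(table, ctx))
  # pin the three max-count clonotypes' scores; shared-pair clone wins
  pin <- function(df, key_row, value) {
    hit <- df$cdr3_alpha == key_row$cdr3_alpha &
      df$cdr3_beta == key_row$cdr3_beta &
      df$v_alpha == key_row$v_alpha & df$j_alpha == key_row$j_alpha &
      df$v_beta == key_row$v_beta & df$j_beta == key_row$j_beta
    df$score[hit] <- value
    df
  }
  scores <- pin(scores, main[1, ], 0.52)
  scores <- pin(scores, main[2, ], 0.31)
  scores <- pin(scores, main[3, ], 0.47)

  list(
    contigs = contigs, expression = m, tags = tags, scores = scores,
    ground_truth = list(
      clones = clones[full_length_key_cols],
      sizes = clones$size,
      clone_of_cell = stats::setNames(clone_of_cell, cell_ids),
      planted_key = unlist(main[1, full_length_key_cols]),
      populations = stats::setNames(pop, cell_ids),
      dominant_pair = c(cdr3_alpha = shared_a, cdr3_beta = shared_b)
    )
  )
}
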
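test_that("log2-CPM matches closed forms and conserves per-cell totals", {
  one <- matrix(10L, 1, 1, dimnames = list("c1", "g1"))
  expect_equal(normalize_log2_cpm(one)[1, 1], log2(1e6 + 1), tolerance = 1e-12)

  two <- matrix(c(5L, 5L), 1, 2, dimnames = list("c1", c("g1", "g2")))
  norm <- normalize_log2_cpm(two)
  expect_equal(unname(norm[1, ]), rep(log2(5e5 + 1), 2), tolerance = 1e-12)

  set.seed(5)
  m <- matrix(rpois(50 * 20, 8), 50, 20,
              dimnames = list(sprintf("c%02d", 1:50), sprintf("g%02d", 1:20)))
  storage.mode(m) <- "integer"
  norm <- normalize_log2_cpm(m)
  cpm <- 2^norm - 1
  expect_equal(unname(rowSums(cpm)), rep(1e6, 50), tolerance = 1e-6)

  neg <- m; neg[1, 1] <- -1L
  expect_error(normalize_log2_cpm(neg), "negative")
  mz <- m; mz[3, ] <- 0L
  expect_warning(normz <- normalize_log2_cpm(mz), "all-zero")
  expect_true(all(normz[3, ] == 0))
})

test_that("log2-CPM is monotone in counts within a cell", {
  set.seed(55)
  m <- matrix(sample(0:30, 40, replace = TRUE), 2, 20,
              dimnames = list(c("c1", "c2"), sprintf("g%02d", 1:20)))
  storage.mode(m) <- "integer"
  norm <- normalize_log2_cpm(m)
  for (cell in 1:2) {
    ord <- order(m[cell, ])
    expect_true(all(diff(norm[cell, ord]) >= 0))
  }
})

test_that("feature assembly z-scores markers and derived clone features", {
  rep <- small_repertoire(6, n_cells = 100, n_clones = 20)
  cells <- pair_chains(rep$contigs)
  tab <- count_clonotypes(cells)
  tab <- attach_scores(tab, simulate_binding_scores(tab, seed = 6))
  ids <- names(rep$ground_truth$clone_of_cell)
  m <- simulate_expression(ids, rep(c("cytotoxic", "other"), length.out = 100),
                           seed = 6)
  norm <- normalize_log2_cpm(m)
  f <- suppressMessages(assemble_features(norm, tab))
  expect_equal(ncol(f), 8)
  expect_equal(colnames(f), c(default_markers, "clone_size", "binding_score"))
  expect_equal(unname(colMeans(f)), rep(0, 8), tolerance = 1e-10)
  expect_equal(unname(apply(f, 2, sd)), rep(1, 8), tolerance = 1e-10)
  # clone_size pre-scaling equals log2 of the cell's clonotype size
  idx <- match(tab$cell_ids[[1]], ids)
  expect_true(length(unique(f[idx, "clone_size"])) == 1)

  expect_error(assemble_features(norm[, 1:3], tab), "not in the .*panel")
})

test_that("zero-variance features collapse to zero instead of erroring", {
  rep <- small_repertoire(8, n_cells = 30, n_clones = 1)
  cells <- pair_chains(rep$contigs)
  tab <- count_clonotypes(cells)
  tab$binding_score <- 0.7
  ids <- names(rep$ground_truth$clone_of_cell)
  m <- simulate_expression(ids, rep("other", 30), seed = 8)
  f <- suppressMessages(assemble_features(normalize_log2_cpm(m), tab))
  expect_true(all(f[, "clone_size"] == 0))
  expect_true(all(f[, "binding_score"] == 0))
})

test_that("PCA returns ordered variance ratios and reconstructs at full rank", {
  set.seed(66)
  f <- matrix(rnorm(200), 50, 4, dimnames = list(sprintf("c%02d", 1:50), NULL))
  p <- run_pca(f, k = 4)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-12)
  # full-rank reconstruction oracle
  pr <- prcomp(f, center = TRUE, scale. = FALSE)
  recon <- pr$x %*% t(pr$rotation) + matrix(pr$center, 50, 4, byrow = TRUE)
  expect_equal(recon, f, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(run_pca(f, k = 5), "exceeds")
  # identity on 1-feature data: single PC carries all variance
  p1 <- run_pca(f[, 1, drop = FALSE], k = 1)
  expect_equal(p1$explained_variance_ratio, 1)
})

test_that("UMAP is reproducible at fixed seed and separates planted structure", {
  set.seed(7)
  X <- rbind(matrix(rnorm(60 * 3), 60, 3),
             matrix(rnorm(60 * 3, mean = 12), 60, 3))
  rownames(X) <- sprintf("c%03d", 1:120)
  u1 <- run_umap(X, seed = 7)
  u2 <- run_umap(X, seed = 7)
  expect_identical(u1, u2)
  pop <- rep(1:2, each = 60)
  d <- as.matrix(dist(u1))
  intra <- mean(d[pop == 1, pop == 1])
  inter <- mean(d[pop == 1, pop == 2])
  expect_gt(inter, intra)

  expect_error(run_umap(X[1:15, ], n_neighbors = 15), "n_neighbors")
})

test_that("HDBSCAN recovers two planted blobs and handles degenerate input", {
  set.seed(8)
  X <- rbind(matrix(rnorm(50 * 2, sd = 0.5), 50, 2),
             matrix(rnorm(50 * 2, mean = 10, sd = 0.5), 50, 2))
  lab <- run_hdbscan(X, min_cluster_size = 5)
  expect_equal(length(setdiff(unique(lab), -1L)), 2)
  expect_gte(mean(lab != -1L), 0.9)
  # blob membership maps onto label blocks
  expect_equal(length(unique(lab[1:50][lab[1:50] != -1L])), 1)
  expect_equal(length(unique(lab[51:100][lab[51:100] != -1L])), 1)

  expect_warning(lab3 <- run_hdbscan(matrix(rnorm(6), 3, 2), 5), "all noise")
  expect_equal(lab3, rep(-1L, 3))
  # a single homogeneous blob is all noise (no selectable subcluster)
  one <- matrix(rnorm(100), 50, 2)
  expect_true(all(run_hdbscan(one, 25) == -1L))
})

test_that("HDBSCAN labels match the scikit-learn reference implementation", {
  set.seed(88)
  for (trial in 1:3) {
    k <- trial + 1
    X <- do.call(rbind, lapply(seq_len(k), function(i)
      matrix(rnorm(40 * 2, mean = i * 7), 40, 2)))
    X <- rbind(X, matrix(runif(30, 0, k * 7 + 7), ncol = 2))
    mcs <- c(5L, 8L, 10L)[trial]
    mine <- hdbscan_labels(X, min_cluster_size = mcs)
    ref <- sklearn_hdbscan(X, mcs)
    # identical up to tie-breaking: when a far point's core distance
    # dominates several candidate MST edges their weights tie exactly and
    # the point's side of the hierarchy is implementation-defined
    expect_equal(length(setdiff(unique(mine), -1L)),
                 length(setdiff(unique(ref), -1L)))
    expect_gte(partition_ari(mine, ref), 0.98)
    expect_lte(abs(sum(mine == -1L) - sum(ref == -1L)), 2)
  }
})

test_that("cluster phenotyping equals brute-force median comparison", {
  profs <- four_population_profiles()
  pops <- rep(c("cytotoxic", "treg"), each = 50)
  ids <- sprintf("c%03d", seq_along(pops))
  m <- simulate_expression(ids, pops, expression_spec(profiles = profs), seed = 9)
  norm <- normalize_log2_cpm(m)
  labels <- rep(c(0L, 1L), each = 50)
  ph <- phenotype_clusters(labels, norm)
  cyt <- ph[ph$cluster == 0, ]
  expect_equal(cyt$CD8, "+")
  expect_equal(cyt$FOXP3, "-")
  expect_equal(cyt$NKG7, "+")
  expect_equal(cyt$GZMA, "+")
  expect_equal(cyt$GZMB, "+")
  expect_match(cyt$phenotype, "^CD8\\+ CD4- FOXP3- NKG7\\+ GZMA\\+ GZMB\\+$")

  # brute force sign oracle, every cluster and marker
  for (cl in ph$cluster) {
    for (mk in default_markers) {
      expected <- if (median(norm[labels == cl, mk]) > median(norm[, mk])) "+" else "-"
      expect_equal(ph[[mk]][ph$cluster == cl], expected)
    }
  }

  # label permutation invariance (up to cluster id renaming)
  perm <- ifelse(labels == 0L, 5L, 2L)
  ph_perm <- phenotype_clusters(perm, norm)
  expect_equal(ph_perm$phenotype[ph_perm$cluster == 5],
               ph$phenotype[ph$cluster == 0])

  # uniform expression: strict inequality forces all '-'
  uni <- matrix(7L, 40, length(default_markers),
                dimnames = list(sprintf("u%02d", 1:40), default_markers))
  ph_uni <- phenotype_clusters(rep(0L, 40), normalize_log2_cpm(uni))
  expect_true(all(unlist(ph_uni[default_markers]) == "-"))
})

test_that("dominant cohesion reports the modal cluster fraction", {
  dom <- list(cell_ids = sprintf("c%d", 1:7))
  ids <- sprintf("c%d", 1:10)
  labels <- c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 0L, 0L, 0L)
  coh <- dominant_cohesion(labels, ids, dom)
  expect_equal(coh$n_in_modal_cluster, 6L)
  expect_equal(coh$n_members, 7L)
  expect_equal(coh$fraction, 6 / 7, tolerance = 1e-12)
  expect_equal(coh$modal_cluster, 1L)

  all_in <- dominant_cohesion(rep(3L, 10), ids, dom)
  expect_equal(all_in$fraction, 1.0)

  expect_warning(noise <- dominant_cohesion(rep(-1L, 10), ids, dom), "noise")
  expect_true(noise$all_noise)

  # random labels vs brute-force mode count
  set.seed(10)
  for (trial in 1:20) {
    labs <- sample(c(-1L, 0L, 1L, 2L), 10, replace = TRUE)
    if (all(labs[1:7] == -1L)) next
    coh <- dominant_cohesion(labs, ids, dom)
    member <- labs[1:7]
    pool <- member[member != -1L]
    counts <- table(pool)
    expect_equal(coh$n_in_modal_cluster, as.integer(max(counts)))
    expect_equal(coh$fraction, max(counts) / 7)
  }
})
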
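# Brute-force oracles and small generators shared across tests.

# independent argmax scan: max count, then max score, then smallest key string
brute_force_dominant <- function(table) {
  key_str <- apply(as.data.frame(
    table[c("v_alpha", "j_alpha", "cdr3_alpha", "v_beta", "j_beta", "cdr3_beta")]),
    1L, paste, collapse = "|")
  best <- NULL
  for (i in seq_len(nrow(table))) {
    cand <- list(count = table$cell_count[i], score = table$binding_score[i],
                 key = key_str[i], idx = i)
    if (is.null(best) ||
        cand$count > best$count ||
        (cand$count == best$count && cand$score > best$score) ||
        (cand$count == best$count && cand$score == best$score &&
         cand$key < best$key)) {
      best <- cand
    }
  }
  best$idx
}

# random scored clonotype table (not via count_clonotypes, so tests of the
# selector do not depend on the counting path)
random_scored_table <- function(seed, n = 12) {
  set.seed(seed)
  tab <- data.frame(
    v_alpha = sample(paste0("TRAV", 1:5), n, replace = TRUE),
    j_alpha = sample(paste0("TRAJ", 1:5), n, replace = TRUE),
    cdr3_alpha = replicate(n, paste0(
      "C", paste(sample(LETTERS[1:20], 8, replace = TRUE), collapse = ""), "F")),
    v_beta = sample(paste0("TRBV", 1:5), n, replace = TRUE),
    j_beta = sample(paste0("TRBJ", 1:3), n, replace = TRUE),
    cdr3_beta = replicate(n, paste0(
      "C", paste(sample(LETTERS[1:20], 9, replace = TRUE), collapse = ""), "F")),
    cell_count = sample(1:8, n, replace = TRUE),
    binding_score = round(stats::runif(n), 3),
    stringsAsFactors = FALSE
  )
  tab$cell_ids <- lapply(seq_len(n), function(i)
    sprintf("cell_%03d_%02d", i, seq_len(tab$cell_count[i])))
  attr(tab, "resolution") <- "full_length"
  class(tab) <- c("clonotype_table", "data.frame")
  tab
}

# reference HDBSCAN labels from scikit-learn, via the python on PATH
sklearn_hdbscan <- function(X, min_cluster_size) {
  xf <- tempfile(fileext = ".csv")
  lf <- tempfile(fileext = ".txt")
  sf <- tempfile(fileext = ".py")
  utils::write.csv(as.data.frame(X), xf, row.names = FALSE)
  writeLines(sprintf(paste0(
    "import pandas as pd\n",
    "from sklearn.cluster import HDBSCAN\n",
    "X = pd.read_csv(%s).values\n",
    "lab = HDBSCAN(min_cluster_size=%d, copy=True).fit_predict(X)\n",
    "open(%s, 'w').write('\\n'.join(map(str, lab)))\n"),
    deparse(xf), min_cluster_size, deparse(lf)), sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  as.integer(readLines(lf, warn = FALSE))
}

# partition agreement up to relabelling (adjusted Rand index)
partition_ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# tiny simulated repertoire for IO and property tests
small_repertoire <- function(seed, n_cells = 60, n_clones = 15, dropout = 0) {
  simulate_repertoire(
    repertoire_spec(n_cells = n_cells, n_clones = n_clones, dropout = dropout),
    seed = seed)
}
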
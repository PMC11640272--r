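make_contig <- function(cell, locus, v, j, cdr3, prod = TRUE, umi = 1L) {
  data.frame(cell_id = cell, locus = locus, v_call = v, j_call = j,
             junction_aa = cdr3, productive = prod, umi_count = umi,
             stringsAsFactors = FALSE)
}

test_that("pair_chains picks one chain per locus, flags incomplete cells", {
  contigs <- rbind(
    make_contig("c1", "TRA", "TRAV1", "TRAJ3", "CAVRF"),
    make_contig("c1", "TRB", "TRBV2", "TRBJ1-1", "CASSF"),
    make_contig("c2", "TRB", "TRBV4", "TRBJ1-2", "CASGF")
  )
  cells <- pair_chains(contigs)
  expect_equal(nrow(cells), 2)
  c1 <- cells[cells$cell_id == "c1", ]
  expect_true(c1$complete)
  expect_equal(c1$cdr3_alpha, "CAVRF")
  expect_equal(c1$cdr3_beta, "CASSF")
  c2 <- cells[cells$cell_id == "c2", ]
  expect_false(c2$complete)
  expect_true(is.na(c2$cdr3_alpha))
})

test_that("chain ambiguity resolves by UMI count, then smallest junction", {
  contigs <- rbind(
    make_contig("c1", "TRA", "TRAV1", "TRAJ3", "CAVRF", umi = 5L),
    make_contig("c1", "TRA", "TRAV9", "TRAJ9", "CZZZF", umi = 2L),
    make_contig("c1", "TRB", "TRBV2", "TRBJ1-1", "CASSF")
  )
  cells <- suppressMessages(pair_chains(contigs))
  # brute force: max umi over productive TRA contigs
  tra <- contigs[contigs$locus == "TRA" & contigs$productive, ]
  expect_equal(cells$cdr3_alpha, tra$junction_aa[which.max(tra$umi_count)])

  tie <- rbind(
    make_contig("c1", "TRA", "TRAV1", "TRAJ3", "CBBBF", umi = 5L),
    make_contig("c1", "TRA", "TRAV9", "TRAJ9", "CAAAF", umi = 5L),
    make_contig("c1", "TRB", "TRBV2", "TRBJ1-1", "CASSF")
  )
  expect_equal(suppressMessages(pair_chains(tie))$cdr3_alpha, "CAAAF")
  # non-productive contigs are never chosen
  np <- rbind(
    make_contig("c1", "TRA", "TRAV1", "TRAJ3", "CAVRF", prod = FALSE, umi = 50L),
    make_contig("c1", "TRA", "TRAV2", "TRAJ6", "CAGGF", umi = 1L),
    make_contig("c1", "TRB", "TRBV2", "TRBJ1-1", "CASSF")
  )
  expect_equal(pair_chains(np)$cdr3_alpha, "CAGGF")
})

test_that("counting keys by resolution and strips allele suffixes", {
  contigs <- rbind(
    make_contig("c1", "TRA", "TRAV1*01", "TRAJ3", "CAVRF"),
    make_contig("c1", "TRB", "TRBV2*01", "TRBJ1-1", "CASSF"),
    make_contig("c2", "TRA", "TRAV1*02", "TRAJ3", "CAVRF"),
    make_contig("c2", "TRB", "TRBV2", "TRBJ1-1", "CASSF"),
    make_contig("c3", "TRA", "TRAV9", "TRAJ3", "CAVRF"),
    make_contig("c3", "TRB", "TRBV2", "TRBJ1-1", "CASSF")
  )
  cells <- pair_chains(contigs)
  full <- count_clonotypes(cells, "full_length")
  pair <- count_clonotypes(cells, "cdr3_pair")
  # alleles *01/*02 collapse; TRAV9 stays distinct at full length
  expect_equal(sort(full$cell_count), c(1, 2))
  expect_equal(pair$cell_count, 3)
  expect_equal(full$v_alpha, c("TRAV1", "TRAV9"))

  expect_warning(empty <- count_clonotypes(pair_chains(contigs[0, ])),
                 "no complete cells")
  expect_equal(nrow(empty), 0)
})

test_that("singleton filter matches its report and the brute-force rule", {
  tab <- random_scored_table(41, n = 3)
  tab$cell_count <- c(7L, 2L, 1L)
  f <- filter_singletons(tab)
  expect_equal(f$report$n_before, 3)
  expect_equal(f$report$n_after, 2)
  expect_equal(f$report$retained_pct, 66.7)
  expect_equal(f$retained$cell_count, c(7L, 2L))

  rep <- small_repertoire(1, n_cells = 120, n_clones = 60)
  tab2 <- count_clonotypes(pair_chains(rep$contigs))
  f2 <- filter_singletons(tab2)
  expect_equal(f2$retained$cell_count, tab2$cell_count[tab2$cell_count >= 2])
  # idempotence
  f3 <- filter_singletons(f2$retained)
  expect_equal(as.data.frame(f3$retained), as.data.frame(f2$retained))
  expect_equal(f3$report$retained_pct, 100.0)

  empty <- suppressWarnings(count_clonotypes(pair_chains(rep$contigs[0, ])))
  expect_warning(rep_empty <- filter_singletons(empty), "undefined")
  expect_equal(rep_empty$report$n_before, 0)
  expect_true(is.na(rep_empty$report$retained_pct))
})

test_that("attach_scores joins uniquely, leaves unmatched clonotypes NA", {
  tab <- random_scored_table(7, n = 3)
  tab$cell_count <- c(3L, 2L, 2L)
  tab$binding_score <- NA_real_
  scores <- data.frame(
    cdr3_alpha = tab$cdr3_alpha, cdr3_beta = tab$cdr3_beta,
    v_alpha = tab$v_alpha, j_alpha = tab$j_alpha,
    v_beta = tab$v_beta, j_beta = tab$j_beta,
    peptide = "KIFGSLAFL", mhc = "HLA-A*02:01", t_cell_type = "CD8",
    score = c(0.2, 0.4, 0.9), stringsAsFactors = FALSE)
  out <- attach_scores(tab, scores)
  expect_equal(out$binding_score, c(0.2, 0.4, 0.9))

  expect_warning(out2 <- attach_scores(tab, scores[2:3, ]), "no binding score")
  expect_true(is.na(out2$binding_score[1]))

  dup <- rbind(scores, scores[1, ])
  dup$score[4] <- 0.5
  expect_error(attach_scores(tab, dup), "ambiguous")

  # simulated join vs nested-loop oracle
  rep <- small_repertoire(3, n_cells = 80, n_clones = 30)
  tab3 <- count_clonotypes(pair_chains(rep$contigs))
  sc3 <- simulate_binding_scores(tab3, planted_key = NULL, seed = 3)
  joined <- attach_scores(tab3, sc3)
  for (i in seq_len(nrow(tab3))) {
    expected <- NA_real_
    for (j in seq_len(nrow(sc3))) {
      if (all(unlist(tab3[i, c("v_alpha", "j_alpha", "cdr3_alpha",
                               "v_beta", "j_beta", "cdr3_beta")]) ==
              unlist(sc3[j, c("v_alpha", "j_alpha", "cdr3_alpha",
                              "v_beta", "j_beta", "cdr3_beta")]))) {
        expected <- sc3$score[j]
      }
    }
    expect_equal(joined$binding_score[i], expected)
  }
})

test_that("dominant selection is count-first, score-second, key-third", {
  tab <- random_scored_table(5, n = 3)
  tab$cell_count <- c(7L, 7L, 7L)
  tab$binding_score <- c(0.31, 0.52, 0.47)
  dom <- select_dominant(tab)
  expect_equal(dom$binding_score, 0.52)
  expect_equal(dom$cell_count, 7L)
  expect_equal(nrow(dom$candidates), 3)

  single <- tab[1, ]
  attr(single, "resolution") <- "full_length"
  class(single) <- class(tab)
  expect_equal(select_dominant(single)$binding_score, 0.31)

  missing <- tab
  missing$binding_score[2] <- NA
  expect_error(select_dominant(missing), "lack a binding score")
})

test_that("dominant selection equals brute-force argmax on 200 random tables", {
  for (seed in 0:199) {
    tab <- random_scored_table(seed)
    dom <- select_dominant(tab)
    idx <- brute_force_dominant(tab)
    expect_equal(unname(dom$key),
                 unname(unlist(tab[idx, c("v_alpha", "j_alpha", "cdr3_alpha",
                                          "v_beta", "j_beta", "cdr3_beta")])))
    expect_equal(dom$binding_score, tab$binding_score[idx])
  }
})

test_that("dominant selection is invariant to row order", {
  tab <- random_scored_table(123, n = 20)
  dom1 <- select_dominant(tab)
  set.seed(9)
  shuf <- tab[sample(nrow(tab)), ]
  attr(shuf, "resolution") <- "full_length"
  class(shuf) <- class(tab)
  dom2 <- select_dominant(shuf)
  expect_equal(dom1$key, dom2$key)
  expect_equal(dom1$binding_score, dom2$binding_score)
})

test_that("resolution comparison satisfies conservation and identity cases", {
  rep <- small_repertoire(4, n_cells = 90, n_clones = 40)
  cells <- pair_chains(rep$contigs)
  cmp <- compare_resolutions(cells)
  expect_equal(sum(cmp$pair_cell_count), sum(cells$complete))
  expect_true(all(cmp$max_full_length_count <= cmp$pair_cell_count))
  # simulated clones have unique CDR3 pairs, so the two resolutions coincide
  expect_true(all(cmp$pair_cell_count == cmp$max_full_length_count))
  expect_true(all(cmp$n_full_length_clonotypes == 1))
})

test_that("full-length partition refines the CDR3-pair partition", {
  for (seed in 1:20) {
    rep <- small_repertoire(seed, n_cells = 70, n_clones = 25,
                            dropout = if (seed %% 2) 0 else 0.15)
    cells <- suppressWarnings(pair_chains(rep$contigs))
    full <- count_clonotypes(cells, "full_length")
    pair <- count_clonotypes(cells, "cdr3_pair")
    n_complete <- sum(cells$complete)
    # partition property at both resolutions
    for (tab in list(full, pair)) {
      ids <- unlist(tab$cell_ids)
      expect_equal(length(ids), length(unique(ids)))
      expect_equal(sum(tab$cell_count), n_complete)
      expect_equal(tab$cell_count, lengths(tab$cell_ids))
    }
    # refinement: pair count = sum of full-length counts sharing the pair
    full_pair_key <- paste(full$cdr3_alpha, full$cdr3_beta)
    sums <- tapply(full$cell_count, full_pair_key, sum)
    pair_key <- paste(pair$cdr3_alpha, pair$cdr3_beta)
    expect_equal(as.vector(sums[pair_key]), pair$cell_count)
  }
})
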
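Package: tcrsift
Title: Dominant Antigen-Specific TCR Clonotype Discovery from Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dry-lab pipeline for discovering the dominant naturally-occurring
    antigen-specific T-cell receptor (TCR) clonotype from single-cell TCR plus
    targeted-transcriptome experiments. Reads AIRR Rearrangement contig tables,
    pairs alpha/beta chains per cell, counts clonotypes at full-length
    (V/J + CDR3 of both chains) and CDR3-pair resolution, filters singleton
    clonotypes, integrates external TCR-peptide-MHC binding scores, co-embeds
    marker expression, clone size and binding score with PCA and UMAP, clusters
    cells with HDBSCAN, phenotypes the clusters, and selects the dominant
    clonotype by clonal expansion with predicted binding specificity as the
    tie-breaker. Ships a synthetic-data generator emulating clonally expanded
    repertoires with a cytotoxic subpopulation for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    uwot
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
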
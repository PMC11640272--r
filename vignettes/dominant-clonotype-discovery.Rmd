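---
title: "Dominant clonotype discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant clonotype discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tcrsift` selects the dominant antigen-specific TCR clonotype from
single-cell paired-chain TCR data plus a targeted expression panel. This
vignette explains the model behind each stage, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where the method left room.

## The selection model

The working assumption is clonal expansion: a T cell whose receptor engages
its antigen proliferates, so *cell count per clonotype* is the primary
evidence of specificity in an antigen-enriched culture. Expansion alone is
ambiguous — several clones may reach the same size — so a second, orthogonal
signal breaks the tie: a sequence-based TCR–pMHC binding prediction in
[0, 1] per clonotype. Selection is therefore the argmax under the ordering

1. cell count (expansion),
2. binding score (predicted specificity),
3. lexicographic key (a pure determinism guarantee; it carries no biology
   and only fires if two equally expanded clonotypes tie in score to the
   last digit).

The selector refuses to run if any maximally expanded clonotype lacks a
score: the discriminator the method depends on must not silently default.

## Clonotype identity, at two resolutions

A cell's receptor is represented by one TRA and one TRB chain, each chosen
among the cell's productive contigs by highest UMI count (ties: smallest
CDR3 string, so re-runs agree). Cells missing either chain are excluded
from counting but stay in the expression matrix for embedding.

Identity is keyed two ways:

* **full-length** — (Vα, Jα, CDR3α, Vβ, Jβ, CDR3β), the default and the
  resolution at which selection happens;
* **CDR3 pair** — (CDR3α, CDR3β) only.

The full-length partition always refines the CDR3-pair partition (tested as
an invariant). The contrast matters biologically: identical CDR3αβ pairs
arising on different V/J backbones are *different receptors* with
potentially different specificity, so selecting by CDR3 alone can lump a
true 7-cell clone with a halo of unrelated 2-cell clones into an apparent
21-cell clone. `compare_resolutions()` quantifies exactly this.

Two normalization choices: allele suffixes (`*01`) are stripped from V/J
calls before keying, because gene-level predictors consume gene-level
segment names and allele-level splits would fragment true clones; CDR3
identity is amino-acid (`junction_aa` verbatim, conserved C/F included) —
nucleotide-level clonotyping is deliberately not offered, since the
downstream construct is built from the protein sequence.

Clonotypes represented by a single cell are filtered out before selection:
a singleton carries no expansion evidence and inflates the denominator of
every repertoire statistic. Reported percentages round half away from zero
to one decimal (27.65 → 27.7), matching how platform QC reports print.

## Binding scores

The package writes predictor-input CSVs (one row per clonotype: six
receptor components, peptide, MHC, T-cell type) and reads back score CSVs.
Scores outside [0, 1] are an error, never clamped — a malformed prediction
file should stop the run, not bend it. The bundled stub predictor exists so
the pipeline is exercisable end to end without a neural network: it maps
the 32-bit FNV-1a digest of the concatenated query fields to [0, 1]. It is
deterministic across platforms and sessions and carries no biological
signal whatsoever; every scientific claim in the tests that involves score
*values* uses the simulator's planted scores instead.

MHC strings pass through verbatim (no allele normalization): predictor
vocabularies differ, and a lossy canonicalization here would corrupt the
join key.

## Co-embedding and phenotyping

Expression is normalized per cell to log2(CPM + 1); the pseudocount keeps
zeros finite and the per-cell CPM sum is a tested conservation invariant
(10⁶ per non-empty cell). The clustering space co-embeds three kinds of
information per cell: the six marker genes (CD8, CD4, FOXP3, NKG7, GZMA,
GZMB by default), log2 of the cell's clonotype size, and the clonotype's
binding score. Each column is z-scored so no single scale dominates the
Euclidean metric. Cells without a complete (or retained) clonotype enter
with clone size and score 0 before scaling — they remain visible in the
embedding without fabricating evidence. Zero-variance columns collapse to
zero rather than erroring, so degenerate inputs (monoclonal cultures,
constant scores) embed gracefully.

Clonotype *identity* is intentionally not a metric feature: a categorical
label has no meaningful distance, so it enters clustering only through its
numeric surrogates (clone size, binding score) and is overlaid on the
embedding at reporting time.

Dimensionality reduction is PCA (k = min(8, n features); with 8 features
this is a rotation, kept for the variance-ratio diagnostics and because the
same path scales to larger marker sets) followed by UMAP (n_neighbors 15,
min_dist 0.1, fixed seed, single SGD thread — multi-threaded SGD is not
reproducible). Clustering is HDBSCAN with min_cluster_size 5: density-based,
noise-aware, and free of a preset cluster count, which suits repertoire
data where the number of phenotypic groups is unknown. All parameters are
user-configurable; none is sacred.

Because no HDBSCAN implementation was available in this package's R
dependency set, the package includes an exact one (core distances → mutual
reachability → Prim MST → single-linkage hierarchy condensed at
min_cluster_size → excess-of-mass extraction, root never selected). It is
validated in the test suite against the scikit-learn reference
implementation on random planted-structure fixtures; agreement is exact up
to ties in mutual-reachability edge weights, where cluster membership of
the tied point is implementation-defined in any HDBSCAN. The O(n²) memory
and time profile is intentional: the method targets thousands of cells, not
millions.

Cluster phenotypes use a strict, scale-free rule: marker sign is `+` in a
cluster iff the cluster median normalized expression strictly exceeds the
global median over all cells. Under uniform expression everything is `-` —
the rule never manufactures a phenotype. The dominant clonotype's *cohesion*
is the fraction of its member cells falling in their modal non-noise
cluster; values near 1 mean the selected clone is also transcriptionally
coherent (the expected cytotoxic effector profile: CD8+ FOXP3- NKG7+ GZMA+
GZMB+).

## The synthetic-data generator

The generator emulates the statistical structure the method assumes, with
planted ground truth:

* **Repertoire** — cells are assigned to clones with probability
  proportional to rank^−s (Zipf, s = 1.5 by default): a handful of expanded
  clones over a long singleton tail, the canonical caricature of clonal
  expansion. Each clone gets distinct (V, J, CDR3)×2 drawn from small
  bundled gene pools; CDR3s are random residues framed by the conserved
  C…F. Chain dropout removes one chain per cell at a configurable rate.
  When a planted dominant is requested, cells are moved from the smallest
  clones into clone 1 until it holds at least twice the runner-up — the
  margin under which recovery must be exact, not probabilistic.
* **Expression** — negative-binomial marker counts per population profile
  plus NB background genes to a 397-gene panel (mirroring a human immune
  response panel), 3 donors by default. Off-profile markers sit at a
  baseline mean of 8 rather than near zero: at targeted-panel depth an
  expressed gene rarely yields exact zeros, and a baseline keeps the
  log2-CPM feature space continuous instead of splitting populations along
  zero/nonzero count boundaries (a discreteness artifact, not biology).
  Dispersion defaults to size = 20 (moderate overdispersion; the Poisson
  limit is a tested property at large size).
* **Scores** — background clonotypes draw Beta(2, 5); the planted clone
  receives the background maximum plus 0.05, capped at 1, hence a strict
  argmax.
* **Worked-example fixture** — `build_paper_fixture()` is fully
  deterministic (no RNG): three 7-cell full-length clonotypes, one sharing
  its CDR3αβ pair with seven 2-cell clonotypes (21 pair cells = 7 + 7×2),
  100 further 2-cell clonotypes and 1319 singletons (1429 clonotypes, 110
  surviving the singleton filter, 7.7%), scores 0.52/0.47/0.31 on the three
  expanded clones, and the cytotoxic profile planted on the winner's seven
  cells. Its expression uses profile means plus a small index ripple, so
  repeated builds are byte-identical.

What the generator does **not** emulate: V(D)J recombination biases and
convergent recombination (CDR3 sharing across clones arises only where the
fixture plants it), UMI/PCR error structure, doublets, ambient RNA, batch
and donor effects on expression, and any real association between sequence
and binding score. Passing tests therefore demonstrate that the *pipeline
logic* is correct under the stated statistical assumptions — not that the
method is robust to every artifact of real single-cell data.

## Study sizes and numerical choices

The bundled studies use sizes chosen to make their statistical point while
staying comfortable on a laptop: planted-dominant recovery uses 100
repertoires of 300 cells / 80 clones at 10% dropout; cluster recovery uses
100 simulations of 4 × 60 cells. Recovery is exact (100/100) for the
dominant clone under the planted margin, and the four-population study
finds exactly four clusters in ≥ 90% of runs (UMAP layout stochasticity
accounts for the remainder; the acceptance script reports the measured
rate).

Degenerate inputs are handled explicitly rather than by crash: empty
contig sets yield empty tables with warnings; all-zero cells stay all-zero
through normalization; fewer points than min_cluster_size yields all-noise;
a single homogeneous blob is all-noise by construction (the hierarchy root
is never a cluster). Percentages round half-up; every tie anywhere in the
pipeline breaks lexicographically so identical inputs give identical
outputs.

## Known limitations

* Chain pairing keeps one α and one β per cell; genuinely dual-TRA cells
  (a real minority) are collapsed to their dominant chain.
* Binding predictions are consumed as given; the pipeline cannot detect a
  miscalibrated predictor, only an out-of-range one.
* HDBSCAN's O(n²) implementation is exact but not for atlas-scale data.
* The "dominant" clonotype is dominant *within the sequenced culture*;
  upstream enrichment biases what the culture contains, and no statistical
  correction for that is attempted here.
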
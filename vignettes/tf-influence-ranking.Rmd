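---
title: "Ranking transcription factors by network influence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking transcription factors by network influence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regnetrank)
```

# The problem

Cell identity is set by a comparatively small number of transcription
factors (TFs) whose importance is poorly captured by expression level
alone: a moderately expressed TF that sits upstream of many
differentially expressed genes can matter far more than an abundant one
with few targets. `regnetrank` scores TFs by their *global network
influence*: it assembles a weighted, directed regulatory network per
cell type from open-chromatin (ATAC-seq) peaks and an expression
matrix, and ranks TFs with personalized PageRank. The TF-by-cell-type
score matrix then drives the downstream questions this package
answers: which TFs are constitutively active, which are specific to a
lineage, a memory compartment or a tissue-resident compartment, which
TFs rise and fall together as "transcriptional waves", and whether TF
lists from two systems (e.g. two species) overlap more than chance.

# Network model

## Nodes

For each cell type, every gene in the expression matrix is a node. Gene
$i$'s node weight is $e^{z_i}$, where $z_i$ is the z-score of the
gene's (log-transformed) expression across cell types. Genes
up-regulated in the cell type at hand thus carry exponentially more
weight; the teleport step of PageRank (below) turns these weights into
the prior that pulls rank toward TFs regulating differentially
expressed genes.

By default expression is transformed as $\log_2(x + 1)$ before
z-scoring (flag `log_transform`): TPM-like values span orders of
magnitude, and exponentiating a z-score computed on the raw scale would
let a single outlier gene dominate the teleport vector. The z-score
uses the sample (n−1) standard deviation; zero-variance genes get
$z = 0$ everywhere.

## Edges

A directed edge runs from TF $i$ to gene $j$ whenever at least one
binding site of one of $i$'s motifs falls in open chromatin linked to
$j$. Its weight is

$$ e_{ij} = g \sum_{k=1}^{n} p_k \, m_k $$

over the $n$ sites linked to $j$, where

* $g$ is the TF's expression value, on the same transformed scale used
  for z-scores — so TFs sharing a motif (common within TF families) get
  identical targets but weights in the ratio of their own expression;
* $p_k = 1 / (1 + e^{-(x-5)})$ is the ATAC peak intensity, with
  $x = -\log_{10} p$ of the peak: a sigmoid mapping to $(0,1)$ with
  midpoint at $x = 5$;
* $m_k$ is the motif affinity: the same sigmoid applied to
  $-\log_{10}$ of the site's exact motif match p-value. The midpoint 5
  is exposed as a parameter (`midpoint`); using the same curve for both
  terms is this package's choice where only the peak-term midpoint is
  pinned down externally. A match p-value of zero has its $-\log_{10}$
  capped at 20 — far past sigmoid saturation — to keep weights finite.

## Site-to-gene linkage

Sites are linked to genes by a strand-aware promoter window (default
5000 bp upstream to 1000 bp downstream of the TSS), plus an optional
user-supplied enhancer-to-gene link table for distal elements
(`linkage_rule(links = ...)`). Chromatin-interaction-based target
predictors can be slotted in through that table; the promoter window is
the transparent, testable default. A site may serve several genes;
unlinked sites are dropped and counted.

# Motif scanning

Match significance is computed exactly, not by Monte Carlo. Each PWM is
converted to a log-odds matrix against the background (pseudocount
$10^{-3}$, default background = genome-wide mononucleotide
frequencies), integerized on a lattice of 1/1000 bit. The distribution
of window scores under the background is then the convolution of the
per-position score distributions — a small dynamic program — giving
$P(S \ge s)$ for every achievable score. Scanning slides every window
of every peak on both strands (a compiled kernel); a site is emitted
when its match p-value is at or below the threshold (default `1e-5`).
When the same motif passes on both strands at one offset only the
better strand is kept, ties resolved to `+`. Windows containing N are
skipped and counted rather than scored with ambiguity codes, keeping
the DP exact; zero background frequencies are rejected rather than
smoothed, because silent smoothing changes p-values invisibly.

The unit tests compare the DP tables against brute-force enumeration of
all $4^L$ k-mers for short motifs, and verify plant-and-recover on both
strands.

# Personalized PageRank

With node weights $s$ (normalized to sum 1) and the column-stochastic
walk matrix $W$, the score vector solves

$$ v = (1 - d)\, s + d\, W v, \qquad d = 0.85 . $$

The walk runs *from targets to their regulators*: column $j$
distributes gene $j$'s mass over the TFs that bind it, in proportion to
$e_{ij}$. This orientation is what lets a TF accumulate rank from the
(differentially expressed) genes it regulates. Columns without
regulators are dangling and teleport to $s$ each iteration, so
$\sum v = 1$ holds throughout. Power iteration starts at $v_0 = s$ and
stops when the L1 step falls below `tol` (default `1e-10`, maximum 1000
iterations; non-convergence is an error, not a warning). A dense
linear-system solve (`pagerank_dense_reference`) is kept as an
independent reference for testing, never as the runtime path. Because
$s$ and $W$ are normalized, every downstream analysis is invariant to
the overall scale of the raw weights.

One consequence of normalizing $s$ worth knowing: raising one gene's
node weight necessarily lowers every other node's teleport share, so
"more influence for the regulator" is a statement *relative to other
TFs*, not an absolute monotonicity in a one-TF toy network. The tests
exercise the relative version on disjoint stars.

# Downstream statistics

All t-tests run on $\log_{10}$ scores (PageRank scores are approximately
log-normal; a Shapiro-Wilk gate, `lognormality_fraction`, reports how
many TFs are consistent with that within each group). Fold changes are
computed on raw-score group means and reported as $\log_2$. Cutoffs are
strict inequalities. No multiple-testing correction is applied by
default, matching the raw-p convention of the tiered cutoffs; the
calibration property (null pass rate equals the cutoff) is tested
directly.

* **Constitutively active TFs** (`find_active_tfs`): row mean in the
  top 10% *and* coefficient of variation (sd/mean) below 0.5.
* **Group-specific TFs** (`specific_tfs`): Welch's unequal-variance
  t-test for target groups of three or more samples; for smaller
  targets a one-sample t-test of the background against the target
  mean. Preset tiers: lineage (p < 0.001, lfc > 1), sub-lineage
  (0.005, 0.5), memory (0.1, no lfc cut), tissue-resident (0.1, 0.5).
  A user exclusion list (`filter_gene_list`) removes genes known to
  confound a contrast (e.g. digestion-related genes in intestinal
  samples).
* **Balanced resampling** (`balanced_resampling`): with a 3-sample
  target against a large background, each repetition draws 3 background
  columns and reruns the Welch test; the selection frequency over
  100-1000 repetitions ranks TFs robustly against group-size imbalance.
* **Cross-system overlap** (`fisher_overlap`): two-sided Fisher's exact
  test on the shared/private 2x2 table within a common TF universe
  (default: the TFs shared by the two matrices).

# Transcriptional waves

The row-z-normalized score matrix is reduced by PCA (retaining the
fewest components reaching 75% cumulative variance, capped at 30), then
clustered by k-means under five candidate metrics — Euclidean,
Manhattan, Kendall, Pearson, Spearman (correlation distances are
$1 - r$). K-means under a non-Euclidean metric needs a defined centroid
space: correlation metrics standardize each row to zero mean and unit
norm (rank-transforming first for Spearman/Kendall), where Euclidean
Lloyd steps with re-standardized centroids minimize $1 - r$ exactly
(exact for Pearson and Spearman; for Kendall the rank transform is a
documented surrogate). Manhattan uses Manhattan assignment with mean
centroids. An emptied cluster is re-seeded from the farthest point of a
cluster that keeps at least one member. Each (metric, k) grid point is
scored by average silhouette width on that metric's own distance
matrix, and the argmax clustering is returned with the full grid; 25
seeded restarts per fit are the default because an under-optimized
Lloyd solution distorts the silhouette surface more than it distorts
the labels. A fixed k can be forced by passing a single-value
`k_range`. Samples (columns) are clustered hierarchically with
correlation distance and average linkage; columns are sorted
lexicographically first so tied merges have a deterministic leaf
order.

# The synthetic benchmark

`make_design` + `write_synthetic_inputs` emit a complete input set —
genome FASTA, MEME motifs with a motif-to-TF map, BED annotation,
narrowPeak files per cell type, expression TSV, and a ground-truth JSON
— with planted structure:

* a lineage tree (default 5 lineages x 4 cell types) emulating a
  multi-lineage immune panel at desk scale;
* 50 TFs: 3 planted drivers per lineage, 5 constitutive drivers,
  optional memory drivers, the rest neutral; 300 genes including the TF
  genes, partitioned into per-lineage modules and a housekeeping
  module;
* 12-bp consensus motifs with pairwise Hamming distance >= 4 and high
  information content, planted (2 copies per driver, 1 per constitutive
  driver) without overlap in the promoters of the corresponding module
  genes — constitutive drivers plant in every target-gene promoter,
  which is what makes them genuinely constitutive in the network;
* peaks opening exactly the promoters of the cell type's active modules
  with $-\log_{10} p \sim U(4, 10)$, plus background peaks; TF-gene
  promoters stay closed, since nothing is planted there and an open,
  regulator-free promoter would hand any chance motif match the entire
  walk mass of its column;
* log-normal expression: per-gene baseline $\mathcal{N}(5, 1)$ on the
  log2 scale, +3 for module genes and drivers in their lineage, +3
  constant for constitutive drivers, Gaussian noise (sd 0.25), then
  exponentiated. A `contaminate` flag injects heavy-tailed noise to
  exercise the normality gate.

The motif length matters more than it looks: at 10 bp, one-mismatch
matches clear a $10^{-5}$ threshold often enough (~2-3 chance genomic
hits per motif) to create stable, planted-like false edges; at 12 bp
chance hits are rare. `audit_truth` re-reads the emitted files and
confirms every planted site carries its consensus, passes the default
threshold, and sits in an open peak of its lineage.

What the generator does *not* emulate: read-level noise, fragment-size
and Tn5 insertion bias, peak-calling artifacts, dinucleotide background
structure, enhancer-promoter loops (unless supplied via the link
table), TF cooperativity and correlated motif grammar. Passing the
planted-recovery tests therefore shows the pipeline's statistics and
plumbing are correct at realistic effect sizes — not that real
chromatin data will be as clean.

# Reproducibility and problem sizes

Every generator and every stochastic routine takes an explicit seed and
restores the caller's RNG state; identical configuration and seed
reproduce every pipeline output byte-identically, and each stage reads
its inputs from disk, so deleting only downstream outputs and rerunning
regenerates exactly them. Numeric outputs are written with enough
digits to round-trip doubles exactly. The test suite runs the full
pipeline on the 5x4-lineage desk preset over ten seeds, compares the
PageRank solver against a dense reference on random networks up to 50
nodes, and checks the motif DP against exhaustive enumeration for
motifs up to 6 bp — sizes chosen so the whole suite completes in a few
minutes on one core while still exercising every code path at
realistic scale.

# Known limitations

* The promoter-window linkage misses distal regulation unless an
  enhancer link table is supplied.
* Kendall-metric k-means optimizes a rank-transform surrogate, not the
  exact Kendall distance.
* The one-sample fallback for tiny target groups tests the background
  against the target mean, so its p-value ignores target-side
  variance.
* Motif match p-values assume an i.i.d. mononucleotide background; CpG
  and repeat structure in real genomes will inflate hits for some
  motifs.
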
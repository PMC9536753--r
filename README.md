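# regnetrank

Systems-level identification of key transcription factors (TFs) from
matched open-chromatin (ATAC-seq) and expression (RNA-seq) data.
`regnetrank` builds a weighted, directed regulatory network per cell
type, ranks every TF by personalized PageRank, and runs the downstream
analyses that turn the score matrix into biology: constitutively active
TFs, lineage- / memory- / tissue-resident-specific TFs, balanced
resampling for unbalanced contrasts, cross-species overlap tests, and
clustering of TF activity patterns ("transcriptional waves").

It is aimed at computational biologists who have per-cell-type peak
calls, a genome, a motif library, and a gene-by-cell-type expression
matrix, and want a reproducible, testable ranking of candidate driver
TFs — plus a synthetic benchmark with planted ground truth to validate
the whole pipeline without touching real data.

## The model

For each cell type, a network is assembled in which every gene is a
node with weight `e^z` (`z` = z-score of its log2 expression across
cell types), and each TF→gene edge carries weight

```
e_ij = g * Σ_k p_k · m_k
```

summed over the TF's binding sites linked to the gene: `g` is the TF's
expression, `p_k = 1/(1 + e^-(x-5))` the sigmoid-rescaled ATAC peak
intensity (`x = -log10 p` of the peak), and `m_k` the same sigmoid
applied to the site's exact motif match `-log10 p`. Binding sites come
from scanning PWMs inside peaks with exact match p-values (integerized
log-odds + dynamic programming, no Monte Carlo) and are linked to genes
through strand-aware promoter windows or a user-supplied enhancer–gene
table. TF influence is the personalized PageRank vector

```
v = (1 - d) s + d W v,   d = 0.85
```

where `s` holds the normalized node weights and `W` walks from each
gene to its regulators in proportion to edge weight, so TFs that
regulate many up-regulated genes rank high. See the methods vignette
(`vignettes/tf-influence-ranking.Rmd`) for the full account.

## Worked example

Generate a small synthetic cohort with planted drivers (3 lineages × 4
cell types, 20 TFs of which 2 per lineage are planted lineage drivers
and 3 are constitutive), then run the full pipeline:

```r
library(regnetrank)

design <- make_design(n_lineages = 3, cells_per_lineage = 4, n_tfs = 20,
                      n_genes = 120, n_drivers_per_lineage = 2,
                      n_constitutive = 3, seed = 7)
write_synthetic_inputs(design, "demo_in")

cfg <- run_config("demo_in", "demo_out", lineage_of = design$lineage_of,
                  metrics = c("euclidean", "pearson"), k_range = 2:6,
                  seed = 7)
res <- run_all(cfg)

round(1000 * res$pagerank[1:6, 1:4], 2)
#>       L1.c1 L1.c2 L1.c3 L1.c4
#> TF001 78.33 86.91 90.01 95.90
#> TF002 80.36 89.76 91.90 95.76
#> TF003  1.05  2.01  1.49  2.31
#> TF004  4.36  2.98  1.89  2.37
#> TF005  2.62  1.95  1.96  2.34
#> TF006  1.51  1.26  1.66  2.26
```

TF001 and TF002 — the two drivers planted in lineage L1 — carry ~40×
the PageRank of other TFs in the L1 cell types. The specificity stage
(Welch t-test on log10 scores, p < 0.001 and log2 fold change > 1)
calls exactly the six planted drivers, each in its own lineage:

```r
sp <- res$specificity
sp[sp$pass == TRUE, c("lineage", "tf", "p_value", "log2_fc")]
#>  lineage    tf  p_value log2_fc
#>       L1 TF001 7.74e-13    5.13
#>       L1 TF002 8.60e-10    5.00
#>       L2 TF003 8.33e-12    5.79
#>       L2 TF004 4.63e-10    4.82
#>       L3 TF005 2.23e-13    5.58
#>       L3 TF006 3.15e-11    5.30
```

`res$active_tfs` returns `TF008, TF009` — planted constitutive drivers
whose mean score ranks in the top 10% with a coefficient of variation
below 0.5 (with 20 TFs the top decile has two slots). The clustering
stage selects the Pearson metric by silhouette width. Every stage's
output (binding sites, networks, the PageRank matrix, calls, clusters)
is written under `demo_out/`, and rerunning with the same config and
seed reproduces it byte-for-byte.

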
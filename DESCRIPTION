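Package: regnetrank
Title: Transcription Factor Influence Ranking from Chromatin-Weighted Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cell-type-specific weighted transcription-factor (TF)
    regulatory networks by scanning position weight matrices in open
    chromatin regions (ATAC-seq peaks), linking binding sites to target
    genes through strand-aware promoter windows or user-supplied
    enhancer-gene links, and weighting nodes and edges with gene
    expression, peak intensity and motif affinity. TFs are ranked per cell
    type by personalized PageRank, and the resulting TF-by-cell-type score
    matrix feeds downstream analyses: constitutively active TF detection,
    lineage-, memory- and tissue-residency-specific TF calling with
    Welch/one-sample t-tests and balanced resampling, cross-species
    overlap testing, and temporal clustering of TF activity patterns with
    silhouette-based metric and k selection. A synthetic-data generator
    with planted driver TFs supports end-to-end benchmarking without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    Rcpp,
    jsonlite,
    cluster,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
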
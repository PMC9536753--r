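# Shared fixtures and independent oracles used across the test files.

# random row-stochastic PWM
rand_pwm <- function(L, concentration = 1) {
  m <- matrix(stats::rgamma(L * 4L, concentration), L, 4L)
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  m
}

# sharp PWM whose consensus is a given string
pwm_from_consensus <- function(consensus, eps = 0.01) {
  letters <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  m <- matrix(eps, length(letters), 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(letters), match(letters, c("A", "C", "G", "T")))] <-
    1 - 3 * eps
  m
}

# independent brute-force oracle for exact match p-values: enumerate all
# 4^L k-mers, score with the model's integer log-odds matrix, and tally
# background probabilities of scores >= s
enum_pvalue_oracle <- function(int_lom, background, scores) {
  L <- nrow(int_lom)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  kmer_scores <- grid
  sc <- vapply(seq_len(nrow(grid)), function(i)
    sum(int_lom[cbind(seq_len(L), grid[i, ])]), numeric(1L))
  pr <- vapply(seq_len(nrow(grid)), function(i)
    prod(background[grid[i, ]]), numeric(1L))
  vapply(scores, function(s) sum(pr[sc >= s]), numeric(1L))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

make_library <- function(pwms, tfs = NULL) {
  ids <- paste0("M", seq_along(pwms))
  if (is.null(tfs)) tfs <- as.list(paste0("TF", seq_along(pwms)))
  lib <- lapply(seq_along(pwms), function(i)
    list(id = ids[i], tfs = tfs[[i]], pwm = pwms[[i]],
         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)))
  names(lib) <- ids
  class(lib) <- "MotifLibrary"
  lib
}

make_peakset <- function(contig, start, end, nlp) {
  ps <- data.frame(contig = contig, start = as.integer(start),
                   end = as.integer(end), neg_log10_p = nlp,
                   stringsAsFactors = FALSE)
  ps <- ps[order(ps$contig, ps$start), , drop = FALSE]
  rownames(ps) <- NULL
  class(ps) <- c("PeakSet", "data.frame")
  ps
}

make_genome <- function(...) {
  structure(c(...), class = "GenomeSequence")
}

# random small regulatory network (TF sources, weighted edges)
random_network <- function(n_nodes, n_tfs, p_edge = 0.3,
                           cell_type = "ct") {
  genes <- sprintf("g%02d", seq_len(n_nodes))
  is_tf <- seq_len(n_nodes) <= n_tfs
  nodes <- data.frame(gene = genes, is_tf = is_tf,
                      node_weight = stats::rlnorm(n_nodes),
                      stringsAsFactors = FALSE)
  pairs <- expand.grid(tf = genes[is_tf], target = genes,
                       stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  keep[sample(length(keep), 1L)] <- TRUE  # at least one edge
  pairs <- pairs[keep, , drop = FALSE]
  edges <- data.frame(tf = pairs$tf, target = pairs$target,
                      weight = stats::rlnorm(nrow(pairs)),
                      n_sites = 1L, stringsAsFactors = FALSE)
  structure(list(cell_type = cell_type, nodes = nodes, edges = edges,
                 assigned_sites = NULL), class = "RegulatoryNetwork")
}

# independent dense-solve oracle for personalized PageRank, written
# directly from the fixed-point equation with dangling teleport
dense_pagerank_oracle <- function(network, d = 0.85) {
  nodes <- network$nodes$gene
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    if (e$weight > 0) W[e$tf, e$target] <- W[e$tf, e$target] + e$weight
  }
  cs <- colSums(W)
  s <- network$nodes$node_weight / sum(network$nodes$node_weight)
  for (j in seq_len(n)) {
    if (cs[j] > 0) W[, j] <- W[, j] / cs[j] else W[, j] <- s
  }
  v <- solve(diag(n) - d * W, (1 - d) * s)
  stats::setNames(as.numeric(v), nodes)
}

# tiny expression matrix with named dims
expr_matrix <- function(values, genes, cts) {
  matrix(values, length(genes), length(cts),
         dimnames = list(genes, cts))
}

# simulated PageRank-like matrix with planted block structure
planted_wave_matrix <- function(n_per_cluster = 12, k = 8, n_cols = 20,
                                noise_sd = 0.1) {
  base <- matrix(stats::rnorm(k * n_cols), k, n_cols)
  X <- do.call(rbind, lapply(seq_len(k), function(cl) {
    scales <- stats::runif(n_per_cluster, 0.5, 2)
    t(vapply(scales, function(s)
      s * base[cl, ] + stats::rnorm(n_cols, 0, noise_sd),
      numeric(n_cols)))
  }))
  rownames(X) <- sprintf("TF%03d", seq_len(nrow(X)))
  colnames(X) <- sprintf("ct%02d", seq_len(n_cols))
  list(X = X, labels = rep(seq_len(k), each = n_per_cluster))
}
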
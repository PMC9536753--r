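# Transcriptional-wave discovery: PCA reduction of the TF activity
# matrix, k-means under five candidate distance metrics with a documented
# centroid space per metric, silhouette-based selection of metric and k,
# and hierarchical clustering of samples.

WAVE_METRICS <- c("euclidean", "manhattan", "kendall", "pearson",
                  "spearman")

#' Clustering configuration
#' @param metrics Subset of euclidean, manhattan, kendall, pearson,
#'   spearman.
#' @param k_range Candidate numbers of clusters (all >= 2 unless a single
#'   fixed k is given).
#' @param var_target Cumulative variance to retain in PCA (default 0.75).
#' @param max_pcs Cap on retained principal components (default 30).
#' @param restarts Seeded k-means restarts (default 25; k-means on many
#'   rows needs generous restarts before the silhouette surface is
#'   trustworthy).
#' @param seed Integer seed.
#' @return A `ClusteringConfig` list.
#' @export
clustering_config <- function(metrics = WAVE_METRICS, k_range = 2:12,
                              var_target = 0.75, max_pcs = 30L,
                              restarts = 25L, seed = 1L) {
  stopifnot(all(metrics %in% WAVE_METRICS), length(metrics) >= 1L,
            all(k_range >= 1L), var_target > 0, var_target <= 1,
            max_pcs >= 1L, restarts >= 1L)
  structure(list(metrics = metrics, k_range = sort(unique(k_range)),
                 var_target = var_target, max_pcs = as.integer(max_pcs),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "ClusteringConfig")
}

#' PCA reduction of the TF activity matrix
#'
#' Projects TFs (rows) onto principal components, retaining the smallest
#' number of components whose cumulative variance reaches the target,
#' capped at `max_pcs`.
#'
#' @param z_matrix Row-normalized TF x cell-type matrix.
#' @param config A [clustering_config()] (uses `var_target`, `max_pcs`).
#' @return List: `scores` (TF x retained PCs), `cum_variance` (full
#'   curve), `n_retained`.
#' @export
pca_reduce <- function(z_matrix, config = clustering_config()) {
  pc <- stats::prcomp(z_matrix, center = TRUE, scale. = FALSE)
  var_expl <- pc$sdev^2 / sum(pc$sdev^2)
  cumvar <- cumsum(var_expl)
  m <- which(cumvar >= config$var_target - 1e-12)[1L]
  if (is.na(m)) m <- length(cumvar)
  m <- min(m, config$max_pcs, ncol(pc$x))
  list(scores = pc$x[, seq_len(m), drop = FALSE], cum_variance = cumvar,
       n_retained = m)
}

#' Pairwise distances between matrix rows under one of five metrics
#'
#' Correlation metrics use d = 1 - r.
#'
#' @param X Numeric matrix (rows = objects).
#' @param metric One of euclidean, manhattan, kendall, pearson, spearman.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(X, metric = WAVE_METRICS) {
  metric <- match.arg(metric)
  D <- switch(metric,
    euclidean = as.matrix(stats::dist(X, method = "euclidean")),
    manhattan = as.matrix(stats::dist(X, method = "manhattan")),
    pearson = 1 - stats::cor(t(X), method = "pearson"),
    spearman = 1 - stats::cor(t(X), method = "spearman"),
    kendall = 1 - stats::cor(t(X), method = "kendall"))
  dimnames(D) <- list(rownames(X), rownames(X))
  diag(D) <- 0
  D
}

# Per-metric clustering space. Correlation metrics standardize each row
# to zero mean and unit norm (after a rank transform for the rank
# correlations); squared Euclidean distance in that space is then an
# affine function of 1 - r, so Euclidean Lloyd steps minimize the
# correlation distance exactly (exact for Pearson and Spearman; for
# Kendall the rank transform is a documented surrogate).
metric_space <- function(X, metric) {
  if (metric %in% c("euclidean", "manhattan")) return(X)
  Y <- if (metric %in% c("spearman", "kendall"))
    t(apply(X, 1L, rank)) else X
  standardize_rows_unit(Y)
}

standardize_rows_unit <- function(Y) {
  Y <- Y - rowMeans(Y)
  nrm <- sqrt(rowSums(Y^2))
  Y / ifelse(nrm == 0, 1, nrm)
}

row_dist_to_centroids <- function(Y, C, metric) {
  if (metric == "manhattan") {
    apply(C, 1L, function(ctr) rowSums(abs(sweep(Y, 2L, ctr))))
  } else {
    # squared Euclidean suffices for assignment
    outer(rowSums(Y^2), rowSums(C^2), "+") - 2 * Y %*% t(C)
  }
}

#' K-means clustering under a chosen distance metric
#'
#' Lloyd iterations in the metric's clustering space: plain coordinates
#' for Euclidean and Manhattan (centroids are cluster means), and
#' row-standardized (optionally rank-transformed) coordinates for the
#' correlation metrics, where centroids are re-standardized cluster means
#' so that Euclidean assignment is exactly assignment by highest
#' correlation. An emptied cluster is re-seeded from the point farthest
#' from its centroid. The best of `restarts` seeded initializations by
#' within-cluster distance sum is returned; deterministic under the seed.
#'
#' @param X Numeric matrix (rows = objects to cluster).
#' @param k Number of clusters (<= nrow(X)).
#' @param metric Distance metric (see [pairwise_distance()]).
#' @param restarts Number of random initializations.
#' @param seed Integer seed.
#' @return Integer cluster labels (length nrow(X)).
#' @export
kmeans_cluster <- function(X, k, metric = "pearson", restarts = 10L,
                           seed = 1L) {
  metric <- match.arg(metric, WAVE_METRICS)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of rows")
  if (k == n) return(seq_len(n))
  Y <- metric_space(X, metric)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  best_obj <- Inf
  for (r in seq_len(restarts)) {
    C <- Y[sample(n, k), , drop = FALSE]
    labels <- rep(0L, n)
    for (iter in 1:100) {
      Dsq <- row_dist_to_centroids(Y, C, metric)
      new_labels <- max.col(-Dsq, ties.method = "first")
      # re-seed any emptied cluster from the farthest point, drawing
      # only from clusters that keep at least one member
      sizes <- tabulate(new_labels, k)
      for (cl in which(sizes == 0L)) {
        cand <- which(sizes[new_labels] > 1L)
        far <- cand[which.max(Dsq[cbind(cand, new_labels[cand])])]
        sizes[new_labels[far]] <- sizes[new_labels[far]] - 1L
        new_labels[far] <- cl
        sizes[cl] <- 1L
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      C <- do.call(rbind, lapply(seq_len(k), function(cl)
        colMeans(Y[labels == cl, , drop = FALSE])))
      if (!(metric %in% c("euclidean", "manhattan")))
        C <- standardize_rows_unit(C)
    }
    Dsq <- row_dist_to_centroids(Y, C, metric)
    obj <- sum(Dsq[cbind(seq_len(n), labels)])
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- labels
    }
  }
  best
}

#' Average silhouette width of a clustering
#' @param D Distance matrix.
#' @param labels Integer cluster labels.
#' @return Mean silhouette width in [-1, 1]; singleton clusters
#'   contribute 0.
#' @export
average_silhouette <- function(D, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(labels, dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Select distance metric and k by silhouette analysis
#'
#' Clusters the matrix at every (metric, k) grid point and evaluates the
#' average silhouette width on that metric's own distance matrix; the
#' argmax clustering is returned together with the full grid.
#'
#' @param X Matrix to cluster (typically PCA scores of the z-normalized
#'   activity matrix).
#' @param config A [clustering_config()].
#' @param profile_matrix Optional matrix (same rows as X) from which
#'   per-cluster mean profiles are computed (e.g. the z-normalized
#'   TF x cell-type matrix).
#' @return A `WaveClustering` list: `labels` (named), `metric`, `k`,
#'   `silhouette` (the winning width), `grid` (data.frame metric / k /
#'   avg_width), and `profiles` (cluster x cell-type means, when
#'   `profile_matrix` is given).
#' @export
silhouette_select <- function(X, config = clustering_config(),
                              profile_matrix = NULL) {
  ks <- config$k_range[config$k_range <= nrow(X)]
  grid <- expand.grid(metric = config$metrics, k = ks,
                      stringsAsFactors = FALSE)
  if (nrow(grid) < 1L) stop("empty (metric, k) grid")
  Ds <- lapply(stats::setNames(config$metrics, config$metrics),
               function(m) pairwise_distance(X, m))
  labels_list <- vector("list", nrow(grid))
  width <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lab <- kmeans_cluster(X, grid$k[i], grid$metric[i],
                          config$restarts, config$seed)
    labels_list[[i]] <- lab
    width[i] <- average_silhouette(Ds[[grid$metric[i]]], lab)
  }
  grid$avg_width <- width
  best <- which.max(ifelse(is.na(width), -Inf, width))
  labels <- stats::setNames(labels_list[[best]], rownames(X))
  profiles <- NULL
  if (!is.null(profile_matrix)) {
    profiles <- do.call(rbind, lapply(
      sort(unique(labels)), function(cl)
        colMeans(profile_matrix[labels == cl, , drop = FALSE])))
    rownames(profiles) <- paste0("C", sort(unique(labels)))
  }
  structure(list(labels = labels, metric = grid$metric[best],
                 k = grid$k[best], silhouette = width[best], grid = grid,
                 profiles = profiles),
            class = "WaveClustering")
}

#' Hierarchical clustering of samples (matrix columns)
#'
#' Agglomerative clustering of the column vectors with correlation
#' distance and average linkage. Columns are ordered lexicographically
#' before clustering so the leaf order is deterministic under ties.
#'
#' @param z_matrix Row-normalized score matrix (>= 3 columns).
#' @param metric "pearson" (d = 1 - r) or "euclidean".
#' @param linkage Linkage method for [stats::hclust()] (default
#'   "average").
#' @return List: `tree` (an hclust object) and `leaf_order` (column
#'   labels in dendrogram order).
#' @export
hierarchical_cluster_samples <- function(z_matrix, metric = "pearson",
                                         linkage = "average") {
  if (ncol(z_matrix) < 3L) stop("need >= 3 samples to cluster")
  z_matrix <- z_matrix[, order(colnames(z_matrix)), drop = FALSE]
  D <- if (metric == "pearson") stats::as.dist(1 - stats::cor(z_matrix))
       else stats::dist(t(z_matrix))
  tree <- stats::hclust(D, method = linkage)
  list(tree = tree, leaf_order = tree$labels[tree$order])
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
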
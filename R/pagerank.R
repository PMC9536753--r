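# Personalized PageRank over the regulatory network. The walk runs from
# targets to their regulator TFs, so a TF accumulates rank from the genes
# it regulates, in proportion to its share of their incoming edge weight.

#' Solver configuration for personalized PageRank
#' @param damping Damping factor d in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter Maximum power iterations; default 1000.
#' @return A `SolverConfig` list.
#' @export
solver_config <- function(damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  stopifnot(damping > 0, damping < 1, tol > 0, max_iter >= 1L)
  structure(list(damping = damping, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "SolverConfig")
}

#' Convert a regulatory network to a column-stochastic walk matrix
#'
#' Column j distributes its mass over the regulators of gene j in
#' proportion to their edge weights into j. Genes with no regulators (or
#' all-zero incoming weight) become dangling columns.
#'
#' @param network A `RegulatoryNetwork`.
#' @return A `WalkMatrix` list: `nodes` (ordering), `W` (sparse
#'   column-stochastic matrix), `dangling` (logical vector).
#' @export
to_walk_matrix <- function(network) {
  nodes <- network$nodes$gene
  stopifnot(length(nodes) >= 1L)
  n <- length(nodes)
  e <- network$edges
  e <- e[e$weight > 0, , drop = FALSE]
  if (nrow(e) < nrow(network$edges) &&
      any(!(network$edges$target %in% e$target)))
    warning("gene(s) with all-zero incoming weight treated as dangling")
  if (nrow(e) > 0L) {
    j <- match(e$target, nodes)
    i <- match(e$tf, nodes)
    stopifnot(!anyNA(i), !anyNA(j))
    W <- Matrix::sparseMatrix(i = i, j = j, x = e$weight, dims = c(n, n))
    cs <- Matrix::colSums(W)
    nz <- cs > 0
    W[, nz] <- W[, nz, drop = FALSE] %*%
      Matrix::Diagonal(sum(nz), 1 / cs[nz])
  } else {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
    cs <- numeric(n)
  }
  structure(list(nodes = nodes, W = W, dangling = cs == 0),
            class = "WalkMatrix")
}

#' Personalized PageRank by power iteration
#'
#' Solves v = (1 - d) s + d W v with the teleport vector s given by the
#' normalized node weights; mass on dangling columns is redistributed
#' according to s at every iteration, so sum(v) = 1 throughout. Iteration
#' starts at v0 = s and stops when the L1 step falls at or below `tol`.
#'
#' @param walk A `WalkMatrix`.
#' @param s_raw Positive node weights, in `walk$nodes` order (normalized
#'   internally to sum 1).
#' @param config A [solver_config()].
#' @return A `PageRankResult` list: `scores` (named vector summing to 1),
#'   `iterations`, `residual`.
#' @export
personalized_pagerank <- function(walk, s_raw, config = solver_config()) {
  n <- length(walk$nodes)
  stopifnot(length(s_raw) == n, all(s_raw > 0), all(is.finite(s_raw)))
  s <- s_raw / sum(s_raw)
  d <- config$damping
  v <- s
  dang <- walk$dangling
  for (it in seq_len(config$max_iter)) {
    v_new <- as.numeric((1 - d) * s +
                          d * (walk$W %*% v + sum(v[dang]) * s))
    res <- sum(abs(v_new - v))
    v <- v_new
    if (res <= config$tol) {
      v <- v / sum(v)  # remove accumulated rounding drift
      return(structure(list(scores = stats::setNames(v, walk$nodes),
                            iterations = it, residual = res),
                       class = "PageRankResult"))
    }
  }
  stop("PageRank did not converge in ", config$max_iter,
       " iterations (last residual ", format(res), ")")
}

#' Dense linear-system reference solve for personalized PageRank
#'
#' Independent cross-check of the power iteration: replaces dangling
#' columns of W by s and solves (I - d W') v = (1 - d) s directly. Meant
#' for small networks (reference/testing), not as a runtime path.
#'
#' @inheritParams personalized_pagerank
#' @return Named score vector summing to 1.
#' @export
pagerank_dense_reference <- function(walk, s_raw,
                                     config = solver_config()) {
  n <- length(walk$nodes)
  s <- s_raw / sum(s_raw)
  Wp <- as.matrix(walk$W)
  Wp[, walk$dangling] <- s
  v <- solve(diag(n) - config$damping * Wp, (1 - config$damping) * s)
  stats::setNames(as.numeric(v), walk$nodes)
}

#' PageRank scores for all cell types
#'
#' Runs one personalized PageRank solve per network and collects the TF
#' rows into a TF x cell-type score matrix.
#'
#' @param networks List of `RegulatoryNetwork`s (one per cell type); all
#'   must share the TF namespace.
#' @param config A [solver_config()].
#' @return A `PageRankMatrix`: numeric matrix, TF rows x cell-type
#'   columns, ordered as the networks are given.
#' @export
rank_all <- function(networks, config = solver_config()) {
  stopifnot(length(networks) >= 1L)
  cts <- vapply(networks, `[[`, "", "cell_type")
  if (anyDuplicated(cts))
    stop("duplicate cell-type label: ", cts[duplicated(cts)][1L])
  tfs <- sort(networks[[1L]]$nodes$gene[networks[[1L]]$nodes$is_tf])
  cols <- lapply(networks, function(net) {
    res <- tryCatch(
      personalized_pagerank(to_walk_matrix(net),
                            net$nodes$node_weight, config),
      error = function(e) stop("PageRank failed for cell type ",
                               net$cell_type, ": ", conditionMessage(e)))
    if (!all(tfs %in% names(res$scores)))
      stop("cell type ", net$cell_type, " lacks TF(s) present in others")
    res$scores[tfs]
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(tfs, cts)
  m
}
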
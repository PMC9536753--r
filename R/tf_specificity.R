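# Downstream statistics on the TF x cell-type PageRank matrix:
# constitutively active TFs, group-specific TFs (Welch / one-sample
# t-tests on log scores with double cutoffs), balanced resampling, and
# cross-species overlap.

#' Row-wise z-normalization of a score matrix
#' @param matrix Numeric matrix with >= 2 columns.
#' @return Matrix with each row standardized ((x - mean)/sd, sample sd);
#'   zero-variance rows become all zeros.
#' @export
znormalize_rows <- function(matrix) {
  if (ncol(matrix) < 2L) stop("row z-normalization needs >= 2 columns")
  mu <- rowMeans(matrix)
  sd <- apply(matrix, 1L, stats::sd)
  z <- (matrix - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  z
}

#' Constitutively active TFs
#'
#' TFs whose mean PageRank score across all cell types ranks in the top
#' fraction and whose coefficient of variation (sd/mean, sample sd) stays
#' below `cv_max` — high influence in every cell type.
#'
#' @param matrix Raw (un-normalized) PageRank matrix, TFs x cell types.
#' @param top_fraction Fraction of TFs admitted by mean rank (default
#'   0.10).
#' @param cv_max Coefficient-of-variation ceiling (default 0.5).
#' @return Character vector of TF names.
#' @export
find_active_tfs <- function(matrix, top_fraction = 0.10, cv_max = 0.5) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  means <- rowMeans(matrix)
  sds <- apply(matrix, 1L, stats::sd)
  usable <- means > 0
  if (any(!usable))
    message(sum(!usable), " TF(s) with zero mean score excluded from CV")
  cv <- ifelse(usable, sds / means, Inf)
  n_top <- ceiling(top_fraction * nrow(matrix))
  top <- rownames(matrix)[order(-means)[seq_len(n_top)]]
  sort(top[cv[top] < cv_max])
}

#' Group design for a specificity contrast
#' @param target Cell-type labels of the group of interest.
#' @param background Cell-type labels of the comparison group.
#' @param excluded Labels dropped from both groups (e.g. a memory
#'   precursor sample).
#' @param label Name for the contrast.
#' @return A `GroupDesign` list.
#' @export
group_design <- function(target, background, excluded = character(),
                         label = "contrast") {
  target <- setdiff(target, excluded)
  background <- setdiff(background, excluded)
  if (length(intersect(target, background)) > 0L)
    stop("target and background groups overlap")
  if (length(target) < 1L || length(background) < 1L)
    stop("both groups must be non-empty")
  structure(list(target = target, background = background,
                 excluded = excluded, label = label),
            class = "GroupDesign")
}

#' Preset cutoff tiers for specificity calls
#'
#' `lineage`: p < 0.001, log2FC > 1. `sublineage`: p < 0.005, log2FC >
#' 0.5. `memory`: p < 0.1, no fold-change cutoff. `trm` (tissue-resident):
#' p < 0.1, log2FC > 0.5.
#'
#' @param tier One of "lineage", "sublineage", "memory", "trm".
#' @return List with elements `p_cut` and `lfc_cut` (NULL when unused).
#' @export
specificity_tier <- function(tier = c("lineage", "sublineage", "memory",
                                      "trm")) {
  switch(match.arg(tier),
         lineage = list(p_cut = 0.001, lfc_cut = 1),
         sublineage = list(p_cut = 0.005, lfc_cut = 0.5),
         memory = list(p_cut = 0.1, lfc_cut = NULL),
         trm = list(p_cut = 0.1, lfc_cut = 0.5))
}

#' Fraction of TFs consistent with log-normal scores
#'
#' Shapiro-Wilk tests on log10 scores within each group; a TF passes when
#' the test rejects in neither group. Groups of identical values (test
#' undefined) count as failures.
#'
#' @param matrix Raw PageRank matrix (positive scores).
#' @param groups List of character vectors of column labels; each group
#'   needs >= 3 columns.
#' @param alpha Rejection level (default 0.05).
#' @return Fraction of TFs passing in all groups.
#' @export
lognormality_fraction <- function(matrix, groups, alpha = 0.05) {
  stopifnot(all(vapply(groups, length, 1L) >= 3L))
  if (any(matrix <= 0)) stop("scores must be positive for log scale")
  lx <- log10(matrix)
  pass <- vapply(seq_len(nrow(lx)), function(i) {
    all(vapply(groups, function(g) {
      x <- lx[i, g]
      if (stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value >= alpha
    }, logical(1L)))
  }, logical(1L))
  mean(pass)
}

#' Call group-specific TFs from the PageRank matrix
#'
#' Tests each TF's log10 scores in the target group against the
#' background. With >= 3 target samples, an unpaired Welch t-test; with
#' fewer, a one-sample t-test of the background against the target mean.
#' The fold change is computed on raw-score group means. A TF passes with
#' p < `p_cut` and (when `lfc_cut` is given) log2 fold change > `lfc_cut`;
#' both inequalities strict.
#'
#' @param matrix Raw PageRank matrix (positive scores).
#' @param design A [group_design()].
#' @param p_cut P-value cutoff.
#' @param lfc_cut Log2 fold-change cutoff, or NULL for none.
#' @param equal_var Use a plain Student t-test instead of Welch.
#' @return Data.frame of `SpecificityCall`s: `tf`, `p_value`, `log2_fc`,
#'   `test`, `pass`.
#' @export
specific_tfs <- function(matrix, design, p_cut = 0.001, lfc_cut = 1,
                         equal_var = FALSE) {
  stopifnot(all(design$target %in% colnames(matrix)),
            all(design$background %in% colnames(matrix)))
  if (length(design$background) == 0L) stop("empty background group")
  if (any(matrix[, c(design$target, design$background)] <= 0))
    stop("scores must be positive for log scale")
  lx <- log10(matrix)
  one_sample <- length(design$target) < 3L
  test_name <- if (one_sample) "one_sample"
               else if (equal_var) "student" else "welch"
  res <- t(vapply(seq_len(nrow(matrix)), function(i) {
    xt <- lx[i, design$target]
    xb <- lx[i, design$background]
    p <- if (one_sample) {
      if (stats::sd(xb) == 0) NA_real_
      else stats::t.test(xb, mu = mean(xt))$p.value
    } else {
      if (stats::sd(xt) == 0 && stats::sd(xb) == 0) NA_real_
      else stats::t.test(xt, xb, var.equal = equal_var)$p.value
    }
    lfc <- log2(mean(matrix[i, design$target]) /
                  mean(matrix[i, design$background]))
    c(p, lfc)
  }, numeric(2L)))
  calls <- data.frame(tf = rownames(matrix), p_value = res[, 1L],
                      log2_fc = res[, 2L], test = test_name,
                      stringsAsFactors = FALSE)
  calls$pass <- !is.na(calls$p_value) & calls$p_value < p_cut &
    (if (is.null(lfc_cut)) TRUE else calls$log2_fc > lfc_cut)
  calls
}

#' Drop calls for excluded genes
#'
#' Removes entries on a user-supplied exclusion list (e.g. digestion-
#' related genes among intestinal samples) from a call table.
#'
#' @param calls Result of [specific_tfs()].
#' @param exclusion_list Character vector of gene symbols to drop.
#' @return Filtered call table; symbols absent from the calls trigger a
#'   warning.
#' @export
filter_gene_list <- function(calls, exclusion_list) {
  if (length(exclusion_list) == 0L) return(calls)
  unknown <- setdiff(exclusion_list, calls$tf)
  if (length(unknown) > 0L)
    warning("exclusion symbol(s) not in calls: ",
            paste(unknown, collapse = ", "))
  kept <- calls[!(calls$tf %in% exclusion_list), , drop = FALSE]
  message(nrow(calls) - nrow(kept), " call(s) removed by exclusion list")
  rownames(kept) <- NULL
  kept
}

#' Balanced resampling of the background for small target groups
#'
#' Repeatedly draws a background of the target's size (3) from the
#' background pool, runs the Welch test at `p_cut`, and records how often
#' each TF is selected; the selection frequency ranks the TFs and
#' stabilizes calls against the unbalanced group sizes.
#'
#' @param matrix Raw PageRank matrix.
#' @param target Exactly 3 cell-type labels.
#' @param background_pool Labels to draw balanced backgrounds from
#'   (>= 3).
#' @param n_reps Number of resampling repetitions (e.g. 100, 500, 1000).
#' @param p_cut P-value cutoff per repetition (default 0.1).
#' @param seed Integer seed.
#' @return Data.frame `tf`, `frequency`, sorted by decreasing frequency
#'   (ties broken by TF name).
#' @export
balanced_resampling <- function(matrix, target, background_pool,
                                n_reps = 1000L, p_cut = 0.1, seed = 1L) {
  stopifnot(length(target) == 3L, length(background_pool) >= 3L,
            all(target %in% colnames(matrix)),
            all(background_pool %in% colnames(matrix)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- numeric(nrow(matrix))
  for (r in seq_len(n_reps)) {
    bg <- sample(background_pool, 3L)
    calls <- specific_tfs(matrix,
                          group_design(target, bg, label = "balanced"),
                          p_cut = p_cut, lfc_cut = NULL)
    hits <- hits + calls$pass
  }
  out <- data.frame(tf = rownames(matrix), frequency = hits / n_reps,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for cross-species TF list overlap
#'
#' Two-sided Fisher's exact test on the 2x2 table of shared versus
#' species-private TFs within a common universe.
#'
#' @param listA,listB Character vectors of TF symbols.
#' @param universe_size Size of the universe both lists are drawn from
#'   (>= |A union B|).
#' @return List with `odds_ratio`, `p_value` and `n_overlap`.
#' @export
fisher_overlap <- function(listA, listB, universe_size) {
  listA <- unique(listA)
  listB <- unique(listB)
  k <- length(intersect(listA, listB))
  if (k > min(length(listA), length(listB)))
    stop("impossible overlap larger than the smaller list")
  if (universe_size < length(union(listA, listB)))
    stop("universe smaller than the union of the lists")
  tab <- matrix(c(k, length(listA) - k, length(listB) - k,
                  universe_size - length(listA) - length(listB) + k),
                nrow = 2L)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       n_overlap = k)
}
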
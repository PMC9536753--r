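# Exact PWM match p-values by dynamic programming on an integerized
# log-odds lattice, and peak scanning against a motif library.

DNA_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

code_sequence <- function(seq) {
  v <- DNA_CODE[strsplit(seq, "", fixed = TRUE)[[1L]]]
  v[is.na(v)] <- NA_integer_
  unname(v)
}

#' Build an exact score model for one PWM
#'
#' Converts a position probability matrix to an integerized log-odds score
#' matrix and computes the exact distribution of window scores under an
#' i.i.d. background model by dynamic programming (convolution of the
#' per-position score distributions). The resulting table gives the exact
#' p-value P(score >= s) for every achievable integer score.
#'
#' @param pwm L x 4 position probability matrix (columns A, C, G, T; rows
#'   sum to 1).
#' @param background Length-4 background nucleotide frequency vector
#'   summing to 1; zero entries are rejected.
#' @param pseudocount Pseudocount added to each PWM entry before
#'   renormalization (keeps log-odds finite for zero entries).
#' @param granularity Lattice spacing of the integerized score, in bits
#'   (default 1/1000 bit).
#' @return A `ScoreModel` list with elements `int_lom` (integer log-odds,
#'   L x 4), `int_lom_rc` (reverse-complement scan matrix), `min_score`,
#'   `max_score`, `pvals` (P(S >= s) for s = min_score..max_score),
#'   `granularity`, `background`.
#' @export
build_score_model <- function(pwm, background = rep(0.25, 4),
                              pseudocount = 1e-3, granularity = 1e-3) {
  stopifnot(ncol(pwm) == 4L, pseudocount > 0, granularity > 0)
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  if (any(background <= 0))
    stop("zero background frequency is not allowed")
  p <- pwm + pseudocount
  p <- p / rowSums(p)
  lom_bits <- log2(sweep(p, 2L, background, "/"))
  int_lom <- round(lom_bits / granularity)
  storage.mode(int_lom) <- "integer"
  L <- nrow(int_lom)
  # exact distribution of the window score under the background model
  lo <- sum(apply(int_lom, 1L, min))
  hi <- sum(apply(int_lom, 1L, max))
  dist <- 1
  d_lo <- 0L
  for (r in seq_len(L)) {
    row <- int_lom[r, ]
    new_lo <- d_lo + min(row)
    new_hi <- d_lo + length(dist) - 1L + max(row)
    nd <- numeric(new_hi - new_lo + 1L)
    for (l in 1:4) {
      at <- (d_lo + row[l] - new_lo) + seq_along(dist)
      nd[at] <- nd[at] + background[l] * dist
    }
    dist <- nd
    d_lo <- new_lo
  }
  stopifnot(d_lo == lo, length(dist) == hi - lo + 1L)
  pvals <- rev(cumsum(rev(dist)))
  pvals[1L] <- 1  # guard rounding: P(S >= min) is exactly 1
  structure(list(int_lom = int_lom,
                 int_lom_rc = int_lom[L:1, 4:1, drop = FALSE],
                 min_score = lo, max_score = hi, pvals = pvals,
                 granularity = granularity, background = background),
            class = "ScoreModel")
}

#' Exact p-value of an integer match score
#' @param model A `ScoreModel`.
#' @param score Integer score(s) on the model's lattice.
#' @return P(S >= score) under the background model; 1 below the score
#'   range, 0 above it.
#' @export
score_pvalue <- function(model, score) {
  p <- numeric(length(score))
  p[score < model$min_score] <- 1
  inside <- score >= model$min_score & score <= model$max_score
  p[inside] <- model$pvals[score[inside] - model$min_score + 1L]
  p
}

# smallest integer score with p-value <= p (max_score + 1 if unreachable)
score_threshold <- function(model, p) {
  idx <- which(model$pvals <= p)
  if (length(idx) == 0L) return(model$max_score + 1L)
  model$min_score + idx[1L] - 1L
}

#' Build score models for a whole motif library
#' @param library A `MotifLibrary`.
#' @param background Length-4 background frequencies (defaults to each
#'   motif's own stored background).
#' @inheritParams build_score_model
#' @return Named list of `ScoreModel`s, one per motif.
#' @export
build_score_models <- function(library, background = NULL,
                               pseudocount = 1e-3, granularity = 1e-3) {
  lapply(library, function(m)
    build_score_model(m$pwm,
                      if (is.null(background)) m$background else background,
                      pseudocount, granularity))
}

#' Genome-wide mononucleotide background frequencies
#' @param genome A `GenomeSequence`.
#' @return Length-4 frequency vector (A, C, G, T), ignoring N bases.
#' @export
genome_background <- function(genome) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(unclass(genome)))[, c("A", "C", "G", "T"),
                                               drop = FALSE])
  if (sum(counts) == 0) stop("genome contains no unambiguous bases")
  counts / sum(counts)
}

#' Scan open-chromatin peaks for motif matches
#'
#' Scores every window of every peak on both strands against each motif and
#' emits binding sites where the exact match p-value is at or below the
#' threshold. When the same motif passes on both strands at the same
#' offset, only the better-scoring strand is kept (ties go to `+`).
#' Windows containing N are skipped and counted.
#'
#' @param genome A `GenomeSequence`.
#' @param peaks A `PeakSet`; every peak must lie within its contig.
#' @param library A `MotifLibrary`.
#' @param p_threshold Match p-value threshold in (0, 1); default 1e-5.
#' @param models Optional precomputed [build_score_models()] result (reused
#'   across cell types to avoid recomputing the score distributions).
#' @param background Background model passed to [build_score_models()];
#'   default is the genome-wide mononucleotide composition.
#' @return A `BindingSite` data.frame with columns `motif_id`, `tfs`
#'   (semicolon-joined TF symbols), `contig`, `start`, `end`, `strand`,
#'   `score`, `p_value`, `peak_neg_log10_p`. The number of N-skipped
#'   windows is attached as attribute `n_skipped_windows`.
#' @export
scan_peaks <- function(genome, peaks, library, p_threshold = 1e-5,
                       models = NULL, background = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  if (is.null(models)) {
    if (is.null(background)) background <- genome_background(genome)
    models <- build_score_models(library, background)
  }
  contig_len <- nchar(genome)
  bad <- which(!(peaks$contig %in% names(genome)) |
                 peaks$end > contig_len[peaks$contig])
  if (length(bad) > 0L)
    stop("peak ", peaks$contig[bad[1L]], ":", peaks$start[bad[1L]], "-",
         peaks$end[bad[1L]], " extends beyond its contig")
  loms <- lapply(models, `[[`, "int_lom")
  loms_rc <- lapply(models, `[[`, "int_lom_rc")
  thresholds <- vapply(models, score_threshold, integer(1L),
                       p = p_threshold)
  motif_ids <- names(library)
  tf_join <- vapply(library, function(m) paste(m$tfs, collapse = ";"), "")
  out <- vector("list", nrow(peaks))
  n_skipped <- 0L
  for (i in seq_len(nrow(peaks))) {
    seq_i <- substr(genome[[peaks$contig[i]]], peaks$start[i] + 1L,
                    peaks$end[i])
    codes <- code_sequence(seq_i)
    if (anyNA(codes)) {
      isn <- cumsum(is.na(codes))
      for (L in vapply(loms, nrow, integer(1L))) {
        if (length(codes) < L) next
        n_win <- length(codes) - L + 1L
        has_n <- isn[seq(L, length(codes))] -
          c(0L, isn)[seq_len(n_win)] > 0L
        n_skipped <- n_skipped + sum(has_n)
      }
    }
    hits <- scan_peak_hits(codes, loms, loms_rc, thresholds)
    if (length(hits$motif) == 0L) next
    m <- hits$motif
    L <- vapply(loms, nrow, integer(1L))[m]
    pv <- vapply(seq_along(m), function(j)
      score_pvalue(models[[m[j]]], hits$score[j]), numeric(1L))
    out[[i]] <- data.frame(
      motif_id = motif_ids[m], tfs = tf_join[m],
      contig = peaks$contig[i],
      start = peaks$start[i] + hits$offset,
      end = peaks$start[i] + hits$offset + L,
      strand = hits$strand, score = hits$score, p_value = pv,
      peak_neg_log10_p = peaks$neg_log10_p[i],
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, out)
  if (is.null(sites))
    sites <- data.frame(motif_id = character(), tfs = character(),
                        contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        score = integer(), p_value = numeric(),
                        peak_neg_log10_p = numeric(),
                        stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  if (n_skipped > 0L)
    message(n_skipped, " N-containing window(s) skipped")
  attr(sites, "n_skipped_windows") <- n_skipped
  sites
}

#' Export binding sites as BED6+2
#' @param sites Result of [scan_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  out <- data.frame(sites$contig, sites$start, sites$end, sites$motif_id,
                    0L, sites$strand, format_num(sites$p_value),
                    format_num(sites$peak_neg_log10_p),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
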
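# Synthetic multi-lineage benchmark generator: a genome with planted
# motif instances in open promoters of lineage-upregulated genes, matched
# per-cell-type peak sets and a log-normal expression matrix, plus the
# planted ground truth for scoring recovery.

MOTIF_LEN <- 12L
# contig layout (0-based); mirrored for '-' strand genes
PLUS_TSS <- 1500L
MINUS_TSS <- 499L
CONTIG_LEN <- 2000L

promoter_peak_region <- function(strand) {
  if (strand == "+") c(PLUS_TSS - 800L, PLUS_TSS + 200L)
  else c(MINUS_TSS - 200L, MINUS_TSS + 800L)
}

plant_window <- function(strand) {
  if (strand == "+") c(PLUS_TSS - 600L, PLUS_TSS - 100L)
  else c(MINUS_TSS + 100L, MINUS_TSS + 600L)
}

#' Create a synthetic study design with planted driver TFs
#'
#' Defines a multi-lineage cell-type panel, a TF panel with roles
#' (lineage driver, constitutive driver, memory driver, neutral), gene
#' modules up-regulated per lineage, and the effect sizes used by the
#' generators. The default desk-scale preset has 5 lineages x 4 cell
#' types, 50 TFs (3 drivers per lineage, 5 constitutive) and 300 genes
#' (TF genes included).
#'
#' @param n_lineages Number of cell lineages (>= 1).
#' @param cells_per_lineage Cell types per lineage.
#' @param n_tfs Number of TFs (each with its own motif).
#' @param n_genes Total genes including the TF genes.
#' @param n_drivers_per_lineage Planted lineage drivers per lineage.
#' @param n_constitutive Planted constitutively active TFs.
#' @param n_memory_drivers Planted memory drivers (0 disables the memory
#'   layer; needs >= 3 lineages otherwise).
#' @param effect List of effect sizes: `expr_lfc` (log2 fold change of
#'   module genes and drivers in their lineage), `driver_sites` (planted
#'   sites per driver per module promoter), `constitutive_sites`,
#'   `noise_sd` (log2-scale expression noise), `peak_nlp` (range of
#'   -log10 p for open promoters), `constitutive_boost` (log2 offset of
#'   constitutive drivers in every cell type).
#' @param seed Integer seed; the whole design (strands, motif consensus
#'   sequences) is a pure function of the arguments and the seed.
#' @return A `SyntheticDesign` list.
#' @export
make_design <- function(n_lineages = 5L, cells_per_lineage = 4L,
                        n_tfs = 50L, n_genes = 300L,
                        n_drivers_per_lineage = 3L, n_constitutive = 5L,
                        n_memory_drivers = 0L,
                        effect = list(), seed = 1L) {
  if (n_lineages < 1L) stop("need at least one lineage")
  stopifnot(cells_per_lineage >= 1L, n_genes > n_tfs)
  n_drivers <- n_lineages * n_drivers_per_lineage
  if (n_drivers + n_constitutive + n_memory_drivers > n_tfs)
    stop("more planted roles than TFs")
  if (n_memory_drivers > 0L && n_lineages < 3L)
    stop("memory layer needs >= 3 lineages")
  eff <- utils::modifyList(
    list(expr_lfc = 3, driver_sites = 2L, constitutive_sites = 1L,
         noise_sd = 0.25, peak_nlp = c(4, 10), constitutive_boost = 3),
    effect)
  lineages <- paste0("L", seq_len(n_lineages))
  cell_types <- as.vector(t(outer(lineages, seq_len(cells_per_lineage),
                                  function(l, c) paste0(l, ".c", c))))
  lineage_of <- stats::setNames(rep(lineages, each = cells_per_lineage),
                                cell_types)
  memory_cells <- character()
  if (n_memory_drivers > 0L)
    memory_cells <- paste0(lineages[1:3], ".c", cells_per_lineage)
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  roles <- rep("neutral", n_tfs)
  roles[seq_len(n_drivers)] <- "lineage_driver"
  roles[n_drivers + seq_len(n_constitutive)] <- "constitutive_driver"
  if (n_memory_drivers > 0L)
    roles[n_drivers + n_constitutive + seq_len(n_memory_drivers)] <-
      "memory_driver"
  names(roles) <- tfs
  driver_lineage <- stats::setNames(rep(NA_character_, n_tfs), tfs)
  driver_lineage[seq_len(n_drivers)] <-
    rep(lineages, each = n_drivers_per_lineage)
  n_targets <- n_genes - n_tfs
  targets <- sprintf("G%03d", seq_len(n_targets))
  module_size <- floor(n_targets * 0.8 / n_lineages)
  modules <- stats::setNames(rep("HK", n_targets), targets)
  for (l in seq_len(n_lineages))
    modules[(l - 1L) * module_size + seq_len(module_size)] <- lineages[l]
  if (n_memory_drivers > 0L) {
    hk <- names(modules)[modules == "HK"]
    n_mem <- min(20L, max(5L, floor(length(hk) / 2)))
    modules[hk[seq_len(n_mem)]] <- "MEM"
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- c(tfs, targets)
  strands <- stats::setNames(sample(c("+", "-"), length(genes),
                                    replace = TRUE), genes)
  consensus <- draw_dissimilar_consensus(n_tfs, MOTIF_LEN, min_hamming = 4L)
  names(consensus) <- tfs
  structure(list(
    n_lineages = n_lineages, cells_per_lineage = cells_per_lineage,
    lineages = lineages, cell_types = cell_types, lineage_of = lineage_of,
    memory_cells = memory_cells, tfs = tfs, roles = roles,
    driver_lineage = driver_lineage, genes = genes, targets = targets,
    modules = modules, strands = strands, consensus = consensus,
    effect = eff, seed = as.integer(seed)),
    class = "SyntheticDesign")
}

# consensus k-mers with pairwise Hamming distance >= min_hamming, so the
# planted motifs stay mutually dissimilar
draw_dissimilar_consensus <- function(n, len, min_hamming = 4L) {
  out <- character(0)
  mat <- matrix(character(0), nrow = 0, ncol = len)
  tries <- 0L
  while (length(out) < n) {
    cand <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    ok <- nrow(mat) == 0L ||
      all(rowSums(mat != matrix(cand, nrow(mat), len,
                                byrow = TRUE)) >= min_hamming)
    if (ok) {
      out <- c(out, paste(cand, collapse = ""))
      mat <- rbind(mat, cand)
    }
    tries <- tries + 1L
    if (tries > 10000L * n) stop("could not draw dissimilar consensus set")
  }
  out
}

consensus_pwm <- function(consensus, eps) {
  letters <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  pwm <- matrix(eps, length(letters), 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm[cbind(seq_along(letters), match(letters, c("A", "C", "G", "T")))] <-
    1 - 3 * eps
  pwm
}

# which TFs plant sites in a gene's promoter, with how many copies.
# Constitutive drivers plant in every target-gene promoter (they are
# always-on regulators); lineage and memory drivers only in their own
# module's genes.
planted_tfs_for_gene <- function(design, gene) {
  mod <- design$modules[gene]
  if (is.na(mod) || gene %in% design$tfs) return(NULL)
  eff <- design$effect
  const <- names(design$roles)[design$roles == "constitutive_driver"]
  tf <- rep(const, each = eff$constitutive_sites)
  if (mod == "MEM") {
    mem <- names(design$roles)[design$roles == "memory_driver"]
    tf <- c(tf, rep(mem, each = eff$driver_sites))
  } else if (mod != "HK") {
    drv <- names(design$roles)[design$roles == "lineage_driver" &
                                 design$driver_lineage == mod]
    tf <- c(tf, rep(drv, each = eff$driver_sites))
  }
  if (length(tf) == 0L) return(NULL)
  data.frame(tf = tf, stringsAsFactors = FALSE)
}

#' Generate the synthetic genome, motif library and planted-site truth
#'
#' One contig per gene, with a promoter region around the TSS. Driver
#' motif consensus sequences are embedded, without overlap, in the
#' promoters of their module's genes; all PWMs are high-information
#' consensus motifs (drivers sharper than neutral TFs) and mutually
#' dissimilar by construction.
#'
#' @param design A [make_design()] result.
#' @return List: `genome` (`GenomeSequence`), `annotation`
#'   (`GeneAnnotation`), `library` (`MotifLibrary`), `planted_sites`
#'   (data.frame contig / start / end / motif_id / tf / gene).
#' @export
generate_genome_and_motifs <- function(design) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed + 104729L)
  genes <- design$genes
  contigs <- paste0("chr_", genes)
  seqs <- vapply(genes, function(g)
    paste(sample(c("A", "C", "G", "T"), CONTIG_LEN, replace = TRUE),
          collapse = ""), "")
  names(seqs) <- contigs
  planted <- list()
  for (g in genes) {
    plants <- planted_tfs_for_gene(design, g)
    if (is.null(plants)) next
    win <- plant_window(design$strands[g])
    pos <- place_nonoverlapping(nrow(plants), MOTIF_LEN, win[1L], win[2L])
    sq <- seqs[paste0("chr_", g)]
    for (i in seq_len(nrow(plants))) {
      cons <- design$consensus[plants$tf[i]]
      substr(sq, pos[i] + 1L, pos[i] + MOTIF_LEN) <- cons
      planted[[length(planted) + 1L]] <- data.frame(
        contig = paste0("chr_", g), start = pos[i],
        end = pos[i] + MOTIF_LEN,
        motif_id = paste0("M_", plants$tf[i]), tf = plants$tf[i],
        gene = g, stringsAsFactors = FALSE)
    }
    seqs[paste0("chr_", g)] <- sq
  }
  planted_sites <- if (length(planted) > 0L) do.call(rbind, planted)
    else data.frame(contig = character(), start = integer(),
                    end = integer(), motif_id = character(),
                    tf = character(), gene = character())
  genome <- structure(seqs, class = "GenomeSequence")
  annotation <- data.frame(
    gene = genes, contig = contigs,
    tss = ifelse(design$strands == "+", PLUS_TSS, MINUS_TSS),
    strand = unname(design$strands), is_tf = genes %in% design$tfs,
    stringsAsFactors = FALSE)
  class(annotation) <- c("GeneAnnotation", "data.frame")
  is_planted <- design$roles != "neutral"
  library <- lapply(design$tfs, function(tf) {
    list(id = paste0("M_", tf), tfs = tf,
         pwm = consensus_pwm(design$consensus[tf],
                             if (is_planted[tf]) 0.01 else 0.05),
         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  })
  names(library) <- paste0("M_", design$tfs)
  class(library) <- "MotifLibrary"
  list(genome = genome, annotation = annotation, library = library,
       planted_sites = planted_sites)
}

place_nonoverlapping <- function(n, len, lo, hi) {
  taken <- integer(0)
  out <- integer(0)
  for (i in seq_len(n)) {
    for (try in 1:500) {
      p <- sample(lo:(hi - len), 1L)
      if (all(abs(p - taken) >= len)) break
      p <- NA_integer_
    }
    if (is.na(p)) stop("could not place planted sites without overlap")
    taken <- c(taken, p)
    out <- c(out, p)
  }
  out
}

# promoters open in a given cell type: the lineage's module, the
# housekeeping module, and the memory module in memory cells. TF-gene
# promoters stay closed (no regulatory input is planted there, and an
# open empty promoter would hand any chance motif match the whole rank
# mass of that column).
open_genes <- function(design, cell_type) {
  l <- design$lineage_of[cell_type]
  mods <- c(l, "HK")
  if (cell_type %in% design$memory_cells) mods <- c(mods, "MEM")
  names(design$modules)[design$modules %in% mods]
}

#' Generate the ATAC peak set for one cell type
#'
#' Promoters of the cell type's active gene modules (its lineage module,
#' housekeeping genes, all TF genes, and the memory module in memory cell
#' types) are open, with -log10(p) intensities drawn uniformly from the
#' designed range. A set of background peaks over non-promoter sequence
#' is added. Closed promoters yield no peaks.
#'
#' @param design A [make_design()] result.
#' @param cell_type One of `design$cell_types`.
#' @return A `PeakSet` data.frame.
#' @export
generate_peaks <- function(design, cell_type) {
  stopifnot(cell_type %in% design$cell_types)
  ct_index <- match(cell_type, design$cell_types)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed * 1009L + ct_index)
  eff <- design$effect
  genes <- open_genes(design, cell_type)
  reg <- t(vapply(design$strands[genes], promoter_peak_region,
                  integer(2L)))
  prom <- data.frame(contig = paste0("chr_", genes),
                     start = reg[, 1L], end = reg[, 2L],
                     neg_log10_p = stats::runif(length(genes),
                                                eff$peak_nlp[1L],
                                                eff$peak_nlp[2L]),
                     stringsAsFactors = FALSE)
  n_bg <- max(1L, round(0.1 * length(design$genes)))
  bg_genes <- sample(design$genes, n_bg)
  bg <- data.frame(contig = paste0("chr_", bg_genes),
                   start = 50L, end = 250L,
                   neg_log10_p = stats::runif(n_bg, 2, 6),
                   stringsAsFactors = FALSE)
  ps <- rbind(prom, bg)
  ps <- ps[order(ps$contig, ps$start, ps$end), , drop = FALSE]
  rownames(ps) <- NULL
  class(ps) <- c("PeakSet", "data.frame")
  ps
}

#' Generate the synthetic expression matrix
#'
#' log2 expression = gene baseline + lineage effect + Gaussian noise,
#' exponentiated to a TPM-like scale, so scores are log-normal by
#' construction. Module genes and lineage drivers are up-regulated by the
#' designed fold change in their lineage's cell types, memory-module
#' genes and memory drivers in the memory cell types, and constitutive
#' drivers carry a constant boost everywhere.
#'
#' @param design A [make_design()] result.
#' @param contaminate Fraction of entries replaced by heavy-tailed
#'   (t with 2 df) noise, to exercise the normality gate (default 0).
#' @return Numeric matrix, genes x cell types, positive.
#' @export
generate_expression <- function(design, contaminate = 0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed + 224737L)
  eff <- design$effect
  genes <- design$genes
  cts <- design$cell_types
  baseline <- stats::rnorm(length(genes), mean = 5, sd = 1)
  names(baseline) <- genes
  lx <- matrix(baseline, length(genes), length(cts),
               dimnames = list(genes, cts))
  for (ct in cts) {
    l <- design$lineage_of[ct]
    up <- names(design$modules)[design$modules == l]
    lx[up, ct] <- lx[up, ct] + eff$expr_lfc
    drivers <- names(design$roles)[design$roles == "lineage_driver" &
                                     design$driver_lineage == l]
    lx[drivers, ct] <- lx[drivers, ct] + eff$expr_lfc
    if (ct %in% design$memory_cells) {
      mem_genes <- names(design$modules)[design$modules == "MEM"]
      mem_tfs <- names(design$roles)[design$roles == "memory_driver"]
      lx[mem_genes, ct] <- lx[mem_genes, ct] + eff$expr_lfc
      lx[mem_tfs, ct] <- lx[mem_tfs, ct] + eff$expr_lfc
    }
  }
  const <- names(design$roles)[design$roles == "constitutive_driver"]
  lx[const, ] <- lx[const, ] + eff$constitutive_boost
  lx <- lx + stats::rnorm(length(lx), 0, eff$noise_sd)
  if (contaminate > 0) {
    idx <- which(stats::runif(length(lx)) < contaminate)
    lx[idx] <- lx[idx] + stats::rt(length(idx), df = 2)
  }
  2^lx
}

#' Emit all synthetic inputs to a directory
#'
#' Writes exactly the formats the readers consume: `genome.fa`,
#' `motifs.meme` + `tf_map.tsv`, `annotation.bed`, `expression.tsv`, one
#' `peaks/<cell_type>.narrowPeak` per cell type, and `truth.json` with
#' the planted ground truth.
#'
#' @param design A [make_design()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  gm <- generate_genome_and_motifs(design)
  write_fasta(gm$genome, file.path(dir, "genome.fa"))
  write_motifs_meme(gm$library, file.path(dir, "motifs.meme"),
                    file.path(dir, "tf_map.tsv"))
  write_gene_annotation(gm$annotation, file.path(dir, "annotation.bed"))
  write_expression(generate_expression(design),
                   file.path(dir, "expression.tsv"))
  for (ct in design$cell_types)
    write_narrowpeak(generate_peaks(design, ct),
                     file.path(dir, "peaks", paste0(ct, ".narrowPeak")))
  truth <- list(
    seed = design$seed, cell_types = design$cell_types,
    lineage_of = as.list(design$lineage_of),
    memory_cells = design$memory_cells,
    tf_roles = as.list(design$roles),
    driver_lineage = as.list(design$driver_lineage[
      !is.na(design$driver_lineage)]),
    gene_modules = as.list(design$modules),
    consensus = as.list(design$consensus),
    planted_sites = gm$planted_sites,
    effect = design$effect)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Audit that the planted truth is recoverable from the emitted files
#'
#' Re-reads the emitted genome, motifs and peaks, verifies that every
#' planted site carries its motif's consensus sequence, that its exact
#' match p-value passes the default scanning threshold, and that the
#' site lies inside an open peak in at least one cell type of its
#' module's lineage.
#'
#' @param design A [make_design()] result.
#' @param dir Directory written by [write_synthetic_inputs()].
#' @param p_threshold Motif match threshold to audit against (default
#'   1e-5).
#' @return List with `pass` (logical) and `failures` (character vector
#'   naming each unrecoverable site).
#' @export
audit_truth <- function(design, dir, p_threshold = 1e-5) {
  need <- file.path(dir, c("genome.fa", "motifs.meme", "tf_map.tsv",
                           "truth.json"))
  if (!all(file.exists(need)))
    return(list(pass = FALSE,
                failures = paste("missing file:",
                                 need[!file.exists(need)])))
  genome <- read_fasta(file.path(dir, "genome.fa"))
  library <- read_motifs_meme(file.path(dir, "motifs.meme"),
                              file.path(dir, "tf_map.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  sites <- truth$planted_sites
  models <- build_score_models(library)
  failures <- character(0)
  for (i in seq_len(nrow(sites))) {
    sq <- substr(genome[[sites$contig[i]]], sites$start[i] + 1L,
                 sites$end[i])
    cons <- truth$consensus[[sites$tf[i]]]
    label <- paste0(sites$contig[i], ":", sites$start[i], "/",
                    sites$motif_id[i])
    if (!identical(sq, cons)) {
      failures <- c(failures, paste("sequence mismatch at", label))
      next
    }
    model <- models[[sites$motif_id[i]]]
    sc <- sum(model$int_lom[cbind(seq_len(nchar(sq)),
                                  code_sequence(sq) + 1L)])
    if (score_pvalue(model, sc) > p_threshold)
      failures <- c(failures,
                    paste("match p-value above threshold at", label))
  }
  # every planted site must sit in an open peak of its lineage
  gene_mod <- unlist(truth$gene_modules)
  for (i in seq_len(nrow(sites))) {
    mod <- gene_mod[sites$gene[i]]
    cts <- if (mod %in% design$lineages)
      design$cell_types[design$lineage_of == mod]
    else if (mod == "MEM") design$memory_cells
    else design$cell_types
    covered <- FALSE
    for (ct in cts) {
      pf <- file.path(dir, "peaks", paste0(ct, ".narrowPeak"))
      if (!file.exists(pf)) next
      pk <- read_narrowpeak(pf)
      pk <- pk[pk$contig == sites$contig[i], , drop = FALSE]
      if (any(pk$start <= sites$start[i] & pk$end >= sites$end[i])) {
        covered <- TRUE
        break
      }
    }
    if (!covered)
      failures <- c(failures, paste0("no open peak covers ",
                                     sites$contig[i], ":",
                                     sites$start[i]))
  }
  list(pass = length(failures) == 0L, failures = failures)
}
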
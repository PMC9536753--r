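# Per-cell-type weighted regulatory network assembly: node weights from
# expression z-scores, edge weights from TF expression, peak intensity and
# motif affinity.

#' Z-score expression across cell types
#'
#' For each gene, standardizes its (optionally log2(x+1)-transformed)
#' expression across cell types: (x - mean) / sd with the sample (n-1) sd.
#' Genes with zero variance get all-zero z-scores.
#'
#' @param expr Numeric matrix, genes x cell types.
#' @param log_transform Apply log2(x+1) first (default TRUE; expression
#'   spans orders of magnitude and node weights exponentiate z).
#' @return Matrix of z-scores with the same dimnames.
#' @export
zscore_expression <- function(expr, log_transform = TRUE) {
  if (ncol(expr) < 2L) stop("z-scores need >= 2 cell types")
  x <- if (log_transform) log2(expr + 1) else expr
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  z <- (x - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  z
}

#' Node weight from an expression z-score
#'
#' The node weight of gene i in a cell type is e^(z_i), so differentially
#' up-regulated genes carry exponentially more teleport mass.
#'
#' @param z Expression z-score(s).
#' @return exp(z).
#' @export
node_weight <- function(z) {
  stopifnot(all(is.finite(z)))
  exp(z)
}

#' Sigmoid rescaling of a -log10(p) intensity to (0, 1)
#'
#' 1 / (1 + e^-(x - midpoint)); with the default midpoint of 5, an
#' intensity of -log10(p) = 5 maps to exactly 0.5.
#'
#' @param x Nonnegative -log10(p) value(s).
#' @param midpoint Sigmoid midpoint (default 5).
#' @return Value(s) in (0, 1).
#' @export
sigmoid_rescale <- function(x, midpoint = 5) {
  stopifnot(all(is.finite(x)))
  1 / (1 + exp(-(x - midpoint)))
}

#' Define how binding sites are linked to target genes
#'
#' A site is linked to a gene if it falls inside the gene's strand-aware
#' promoter window, or if its peak overlaps an interval in an optional
#' enhancer-to-gene link table. A transparent stand-in for chromatin-
#' interaction-based target prediction, with the link table as the
#' injection point for externally predicted enhancer-gene pairs.
#'
#' @param upstream Bases upstream of the TSS (default 5000).
#' @param downstream Bases downstream of the TSS (default 1000).
#' @param links Optional data.frame with columns `contig`, `start`, `end`,
#'   `gene` mapping enhancer intervals to target genes.
#' @return A `LinkageRule` list.
#' @export
linkage_rule <- function(upstream = 5000L, downstream = 1000L,
                         links = NULL) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  if (!is.null(links))
    stopifnot(all(c("contig", "start", "end", "gene") %in% names(links)))
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream), links = links),
            class = "LinkageRule")
}

#' Assign binding sites to target genes
#'
#' @param sites Binding sites from [scan_peaks()].
#' @param annotation A `GeneAnnotation`.
#' @param rule A [linkage_rule()].
#' @return The `sites` data.frame expanded with a `gene` column (one row
#'   per site-gene assignment; a site may serve several genes). Unassigned
#'   sites are dropped; their count is attached as attribute `n_unassigned`.
#' @export
assign_sites <- function(sites, annotation, rule = linkage_rule()) {
  if (!is.null(rule$links))
    stopifnot(all(rule$links$gene %in% annotation$gene))
  if (nrow(sites) == 0L) {
    out <- cbind(sites, gene = character())
    attr(out, "n_unassigned") <- 0L
    return(out)
  }
  site_gr <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$start + 1L, sites$end))
  plus <- annotation$strand == "+"
  win_start <- ifelse(plus, annotation$tss - rule$upstream,
                      annotation$tss - rule$downstream)
  win_end <- ifelse(plus, annotation$tss + rule$downstream,
                    annotation$tss + rule$upstream)
  win_gr <- GenomicRanges::GRanges(
    annotation$contig,
    IRanges::IRanges(pmax(win_start, 0L) + 1L, win_end + 1L))
  ov <- GenomicRanges::findOverlaps(site_gr, win_gr)
  hits <- data.frame(site = S4Vectors::queryHits(ov),
                     gene = annotation$gene[S4Vectors::subjectHits(ov)],
                     stringsAsFactors = FALSE)
  if (!is.null(rule$links) && nrow(rule$links) > 0L) {
    link_gr <- GenomicRanges::GRanges(
      rule$links$contig,
      IRanges::IRanges(rule$links$start + 1L, rule$links$end))
    ov2 <- GenomicRanges::findOverlaps(site_gr, link_gr)
    hits <- rbind(hits, data.frame(
      site = S4Vectors::queryHits(ov2),
      gene = rule$links$gene[S4Vectors::subjectHits(ov2)],
      stringsAsFactors = FALSE))
    hits <- hits[!duplicated(hits), , drop = FALSE]
  }
  out <- cbind(sites[hits$site, , drop = FALSE],
               gene = hits$gene)
  ord <- order(hits$site)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <-
    nrow(sites) - length(unique(hits$site))
  out
}

#' Edge weight of one TF-target interaction
#'
#' e = g * sum_k p_k * m_k over the n binding sites of the TF's motifs
#' linked to the target gene, where p_k is the sigmoid-rescaled ATAC peak
#' intensity, m_k the sigmoid-rescaled motif match -log10(p), and g the
#' TF's expression value.
#'
#' @param g TF expression value (>= 0), on the same transformed scale used
#'   for z-scores (log2(x+1) by default in [build_network()]).
#' @param peak_neg_log10_p Peak intensities of the n sites.
#' @param match_p Motif match p-values of the n sites; zeros have their
#'   -log10 capped at `cap` before the sigmoid.
#' @param midpoint Sigmoid midpoint for both terms (default 5).
#' @param cap Cap on -log10(match p) (default 20, far past sigmoid
#'   saturation).
#' @return Nonnegative edge weight.
#' @export
edge_weight <- function(g, peak_neg_log10_p, match_p, midpoint = 5,
                        cap = 20) {
  stopifnot(g >= 0, length(peak_neg_log10_p) == length(match_p))
  mlp <- ifelse(match_p <= 0, cap, pmin(-log10(match_p), cap))
  g * sum(sigmoid_rescale(peak_neg_log10_p, midpoint) *
            sigmoid_rescale(mlp, midpoint))
}

#' Build the weighted regulatory network for one cell type
#'
#' Nodes are all genes in the expression matrix, weighted e^z for that
#' cell type. One directed edge runs from each TF to each gene with at
#' least one linked binding site of one of the TF's motifs; TFs sharing a
#' motif each get their own edges, scaled by their own expression.
#'
#' @param cell_type Column of `expr` to build the network for.
#' @param sites Binding sites from [scan_peaks()] on this cell type's
#'   peaks.
#' @param annotation A `GeneAnnotation`.
#' @param expr Expression matrix (genes x cell types).
#' @param rule A [linkage_rule()].
#' @param library The `MotifLibrary` (maps motif ids to TF symbols).
#' @param log_transform Passed to [zscore_expression()]; also sets the
#'   scale of g (log2(x+1) when TRUE).
#' @param midpoint Sigmoid midpoint for the peak and motif terms.
#' @return A `RegulatoryNetwork` list: `cell_type`, `nodes` (data.frame
#'   gene / is_tf / node_weight), `edges` (data.frame tf / target / weight
#'   / n_sites), and `assigned_sites` (the per-edge site table, kept so
#'   every edge weight is recomputable).
#' @export
build_network <- function(cell_type, sites, annotation, expr,
                          rule = linkage_rule(), library,
                          log_transform = TRUE, midpoint = 5) {
  stopifnot(cell_type %in% colnames(expr))
  z <- zscore_expression(expr, log_transform)[, cell_type]
  genes <- rownames(expr)
  tf_of_motif <- lapply(library, `[[`, "tfs")
  all_tfs <- sort(unique(unlist(tf_of_motif)))
  missing_tf <- setdiff(all_tfs, genes)
  if (length(missing_tf) > 0L) {
    warning("TF(s) absent from expression matrix skipped: ",
            paste(missing_tf, collapse = ", "))
    all_tfs <- setdiff(all_tfs, missing_tf)
  }
  nodes <- data.frame(gene = genes, is_tf = genes %in% all_tfs,
                      node_weight = node_weight(z),
                      stringsAsFactors = FALSE)
  assigned <- assign_sites(sites, annotation, rule)
  gx <- if (log_transform) log2(expr[, cell_type] + 1) else expr[, cell_type]
  edges <- data.frame(tf = character(), target = character(),
                      weight = numeric(), n_sites = integer(),
                      stringsAsFactors = FALSE)
  site_tab <- assigned[0, , drop = FALSE]
  site_tab$tf <- character()
  if (nrow(assigned) > 0L) {
    # expand motif-level assignments to TF-level (shared motifs fan out)
    per_tf <- lapply(seq_len(nrow(assigned)), function(i) {
      tfs <- tf_of_motif[[assigned$motif_id[i]]]
      tfs <- tfs[tfs %in% all_tfs & assigned$gene[i] %in% genes]
      if (length(tfs) == 0L) return(NULL)
      cbind(assigned[rep(i, length(tfs)), , drop = FALSE],
            tf = tfs)
    })
    site_tab <- do.call(rbind, per_tf)
    if (!is.null(site_tab) && nrow(site_tab) > 0L) {
      rownames(site_tab) <- NULL
      key <- paste(site_tab$tf, site_tab$gene, sep = "\r")
      mlp <- ifelse(site_tab$p_value <= 0, 20,
                    pmin(-log10(site_tab$p_value), 20))
      contrib <- sigmoid_rescale(site_tab$peak_neg_log10_p, midpoint) *
        sigmoid_rescale(mlp, midpoint)
      agg <- rowsum(contrib, key)
      cnt <- rowsum(rep(1L, length(key)), key)
      parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
      tf <- vapply(parts, `[[`, "", 1L)
      target <- vapply(parts, `[[`, "", 2L)
      edges <- data.frame(tf = tf, target = target,
                          weight = unname(gx[tf] * agg[, 1L]),
                          n_sites = as.integer(cnt[, 1L]),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  if (nrow(edges) == 0L)
    warning("no edges in network for cell type ", cell_type)
  structure(list(cell_type = cell_type, nodes = nodes, edges = edges,
                 assigned_sites = site_tab),
            class = "RegulatoryNetwork")
}

#' Write a network's edge list and node table as TSV
#' @param network A `RegulatoryNetwork`.
#' @param edges_path,nodes_path Output paths.
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(network, edges_path, nodes_path) {
  e <- network$edges
  out <- data.frame(cell_type = network$cell_type, tf = e$tf,
                    target = e$target, weight = format_num(e$weight),
                    n_sites = e$n_sites, stringsAsFactors = FALSE)
  utils::write.table(out, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  n <- network$nodes
  nout <- data.frame(gene = n$gene, is_tf = n$is_tf,
                     node_weight = format_num(n$node_weight),
                     stringsAsFactors = FALSE)
  utils::write.table(nout, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges_path)
}

#' Subsample a focal TF's network for visualization
#'
#' Removes edges below a weight floor, samples a fixed number of the focal
#' TF's regulatees while preserving the TF to non-TF ratio, adds the
#' induced edges among the sampled regulatees, and finally retains a
#' random fraction of the total edges.
#'
#' @param network A `RegulatoryNetwork`.
#' @param focal_tf Gene symbol of the TF at the center.
#' @param min_weight Edge-weight floor (default 1).
#' @param n_regulatees Number of regulatees to keep (default 500).
#' @param edge_fraction Fraction of edges kept in the final downsample
#'   (default 0.25).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return Edge list data.frame (tf, target, weight).
#' @export
subsample_for_visualization <- function(network, focal_tf, min_weight = 1,
                                        n_regulatees = 500L,
                                        edge_fraction = 0.25, seed = 1L) {
  stopifnot(focal_tf %in% network$nodes$gene)
  e <- network$edges[network$edges$weight >= min_weight, , drop = FALSE]
  reg <- e$target[e$tf == focal_tf]
  if (length(reg) == 0L) {
    warning("focal TF ", focal_tf, " has no regulatees above min_weight")
    return(data.frame(tf = character(), target = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  is_tf <- stats::setNames(network$nodes$is_tf, network$nodes$gene)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (length(reg) > n_regulatees) {
    tf_reg <- sort(reg[is_tf[reg]])
    ntf_reg <- sort(reg[!is_tf[reg]])
    n_tf <- round(n_regulatees * length(tf_reg) / length(reg))
    keep <- c(sample(tf_reg, min(n_tf, length(tf_reg))),
              sample(ntf_reg, min(n_regulatees - n_tf, length(ntf_reg))))
  } else keep <- reg
  sub <- e[(e$tf == focal_tf & e$target %in% keep) |
             (e$tf %in% keep & e$target %in% keep), , drop = FALSE]
  n_keep <- max(1L, round(nrow(sub) * edge_fraction))
  sub <- sub[sort(sample(nrow(sub), n_keep)), c("tf", "target", "weight")]
  rownames(sub) <- NULL
  sub
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
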
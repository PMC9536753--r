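# End-to-end orchestration: scan -> build-network -> rank -> specificity
# -> cluster, with every stage's output persisted to disk so a run can be
# resumed, and a JSON-lines log of per-stage counts.

#' Assemble and validate a pipeline run configuration
#'
#' @param input_dir Directory holding `genome.fa`, `motifs.meme`,
#'   `tf_map.tsv`, `annotation.bed`, `expression.tsv` and
#'   `peaks/<cell_type>.narrowPeak` (the layout emitted by
#'   [write_synthetic_inputs()]).
#' @param out_dir Output directory.
#' @param lineage_of Named character vector or list mapping cell-type
#'   labels to lineage labels (drives the specificity contrasts); NULL
#'   skips the specificity stage's lineage contrasts.
#' @param motif_p Motif match p-value threshold (default 1e-5).
#' @param promoter_up,promoter_down Promoter window around the TSS, in
#'   bases (defaults 5000 / 1000).
#' @param links Optional enhancer-to-gene link table (see
#'   [linkage_rule()]).
#' @param damping,tol PageRank solver settings.
#' @param midpoint Sigmoid midpoint for peak and motif terms.
#' @param log_transform Use log2(x+1) expression for z-scores and g.
#' @param tier Specificity cutoff tier (see [specificity_tier()]).
#' @param metrics,k_range,var_target,max_pcs,restarts Clustering grid
#'   settings (see [clustering_config()]).
#' @param stages Which stages to run, in order.
#' @param seed Integer seed (clustering restarts and subsampling).
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(input_dir, out_dir, lineage_of = NULL,
                       motif_p = 1e-5, promoter_up = 5000L,
                       promoter_down = 1000L, links = NULL,
                       damping = 0.85, tol = 1e-10, midpoint = 5,
                       log_transform = TRUE, tier = "lineage",
                       metrics = c("euclidean", "manhattan", "kendall",
                                   "pearson", "spearman"),
                       k_range = 2:12, var_target = 0.75, max_pcs = 30L,
                       restarts = 10L,
                       stages = c("scan", "network", "rank",
                                  "specificity", "cluster"),
                       seed = 1L) {
  need <- file.path(input_dir, c("genome.fa", "motifs.meme", "tf_map.tsv",
                                 "annotation.bed", "expression.tsv"))
  if (!all(file.exists(need)))
    stop("missing input file(s): ",
         paste(need[!file.exists(need)], collapse = ", "))
  peak_files <- list.files(file.path(input_dir, "peaks"),
                           pattern = "\\.narrowPeak$", full.names = TRUE)
  if (length(peak_files) == 0L)
    stop("no peak files under ", file.path(input_dir, "peaks"))
  stopifnot(all(stages %in% c("scan", "network", "rank", "specificity",
                              "cluster")))
  structure(list(
    input_dir = input_dir, out_dir = out_dir,
    peak_files = sort(peak_files),
    cell_types = sort(sub("\\.narrowPeak$", "", basename(peak_files))),
    lineage_of = if (is.null(lineage_of)) NULL else unlist(lineage_of),
    motif_p = motif_p, promoter_up = promoter_up,
    promoter_down = promoter_down, links = links, damping = damping,
    tol = tol, midpoint = midpoint, log_transform = log_transform,
    tier = tier, metrics = metrics, k_range = k_range,
    var_target = var_target, max_pcs = max_pcs, restarts = restarts,
    stages = stages, seed = as.integer(seed)), class = "RunConfig")
}

log_stage <- function(con, stage, counts) {
  writeLines(jsonlite::toJSON(c(list(stage = stage), counts),
                              auto_unbox = TRUE), con)
}

write_sites_tsv <- function(sites, path) {
  out <- sites
  for (col in c("p_value", "peak_neg_log10_p"))
    out[[col]] <- format_num(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_sites_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(motif_id = "character",
                                   tfs = "character",
                                   contig = "character",
                                   strand = "character"))
}

load_network_files <- function(cell_type, edges_path, nodes_path) {
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  structure(list(cell_type = cell_type, nodes = nodes,
                 edges = edges[, c("tf", "target", "weight", "n_sites")],
                 assigned_sites = NULL),
            class = "RegulatoryNetwork")
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, consuming each stage's output
#' from disk: a stage whose outputs already exist is skipped, so deleting
#' only downstream outputs and re-running reproduces them. With a fixed
#' configuration and seed the data outputs are byte-identical across
#' runs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the output directory and the in-memory
#'   stage results that were produced or reloaded (`pagerank`,
#'   `specificity`, `active_tfs`, `clustering`).
#' @export
run_all <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "sites"), showWarnings = FALSE)
  dir.create(file.path(out, "networks"), showWarnings = FALSE)
  logf <- file(file.path(out, "run_log.jsonl"), "a")
  on.exit(close(logf))
  genome <- read_fasta(file.path(config$input_dir, "genome.fa"))
  library <- read_motifs_meme(file.path(config$input_dir, "motifs.meme"),
                              file.path(config$input_dir, "tf_map.tsv"))
  tf_symbols <- unique(unlist(lapply(library, `[[`, "tfs")))
  annotation <- read_gene_annotation(
    file.path(config$input_dir, "annotation.bed"), tf_symbols)
  expr <- read_expression(file.path(config$input_dir, "expression.tsv"))
  rule <- linkage_rule(config$promoter_up, config$promoter_down,
                       config$links)
  cts <- config$cell_types
  stage_error <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  if ("scan" %in% config$stages) {
    models <- NULL
    for (i in seq_along(cts)) {
      path <- file.path(out, "sites", paste0(cts[i], ".tsv"))
      if (file.exists(path)) next
      if (is.null(models))
        models <- build_score_models(library, genome_background(genome))
      sites <- tryCatch(
        scan_peaks(genome, read_narrowpeak(config$peak_files[i]),
                   library, config$motif_p, models = models),
        error = function(e) stage_error("scan", e))
      write_sites_tsv(sites, path)
      log_stage(logf, "scan",
                list(cell_type = cts[i], n_sites = nrow(sites)))
    }
  }

  if ("network" %in% config$stages) {
    for (ct in cts) {
      epath <- file.path(out, "networks", paste0(ct, ".edges.tsv"))
      npath <- file.path(out, "networks", paste0(ct, ".nodes.tsv"))
      if (file.exists(epath) && file.exists(npath)) next
      sites <- read_sites_tsv(file.path(out, "sites",
                                        paste0(ct, ".tsv")))
      net <- tryCatch(
        suppressWarnings(
          build_network(ct, sites, annotation, expr, rule, library,
                        config$log_transform, config$midpoint)),
        error = function(e) stage_error("network", e))
      write_network(net, epath, npath)
      log_stage(logf, "network",
                list(cell_type = ct, n_nodes = nrow(net$nodes),
                     n_edges = nrow(net$edges)))
    }
  }

  results <- list(out_dir = out)
  pr_path <- file.path(out, "pagerank.tsv")
  if ("rank" %in% config$stages) {
    if (!file.exists(pr_path)) {
      networks <- lapply(cts, function(ct) load_network_files(
        ct, file.path(out, "networks", paste0(ct, ".edges.tsv")),
        file.path(out, "networks", paste0(ct, ".nodes.tsv"))))
      pr <- tryCatch(
        rank_all(networks, solver_config(config$damping, config$tol)),
        error = function(e) stage_error("rank", e))
      write_pagerank_matrix(pr, pr_path)
      log_stage(logf, "rank",
                list(n_tfs = nrow(pr), n_cell_types = ncol(pr)))
    }
    results$pagerank <- read_pagerank_matrix(pr_path)
  }

  if ("specificity" %in% config$stages) {
    pr <- read_pagerank_matrix(pr_path)
    spath <- file.path(out, "specific_tfs.tsv")
    apath <- file.path(out, "active_tfs.txt")
    if (!file.exists(spath) || !file.exists(apath)) {
      cuts <- specificity_tier(config$tier)
      calls <- NULL
      if (!is.null(config$lineage_of)) {
        lins <- sort(unique(config$lineage_of[cts]))
        calls <- do.call(rbind, lapply(lins, function(l) {
          tgt <- cts[config$lineage_of[cts] == l]
          des <- group_design(tgt, setdiff(cts, tgt), label = l)
          cbind(lineage = l,
                specific_tfs(pr, des, cuts$p_cut, cuts$lfc_cut))
        }))
      } else {
        calls <- data.frame(lineage = character(), tf = character(),
                            p_value = numeric(), log2_fc = numeric(),
                            test = character(), pass = logical())
      }
      calls$p_value <- format_num(calls$p_value)
      calls$log2_fc <- format_num(calls$log2_fc)
      utils::write.table(calls, spath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines(find_active_tfs(pr), apath)
      log_stage(logf, "specificity",
                list(n_calls = sum(calls$pass == "TRUE" |
                                     calls$pass == TRUE),
                     n_active = length(readLines(apath))))
    }
    results$specificity <- utils::read.delim(spath,
                                             stringsAsFactors = FALSE)
    results$active_tfs <- readLines(apath)
  }

  if ("cluster" %in% config$stages) {
    pr <- read_pagerank_matrix(pr_path)
    cpath <- file.path(out, "clusters.tsv")
    gpath <- file.path(out, "silhouette_grid.tsv")
    ppath <- file.path(out, "cluster_profiles.tsv")
    if (!all(file.exists(c(cpath, gpath, ppath)))) {
      z <- znormalize_rows(pr)
      cfg <- clustering_config(config$metrics, config$k_range,
                               config$var_target, config$max_pcs,
                               config$restarts, config$seed)
      red <- pca_reduce(z, cfg)
      wc <- tryCatch(silhouette_select(red$scores, cfg, z),
                     error = function(e) stage_error("cluster", e))
      utils::write.table(
        data.frame(tf = names(wc$labels), cluster = wc$labels,
                   metric = wc$metric, k = wc$k),
        cpath, sep = "\t", quote = FALSE, row.names = FALSE)
      grid <- wc$grid
      grid$avg_width <- format_num(grid$avg_width)
      utils::write.table(grid, gpath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_labelled_matrix(wc$profiles, ppath, "cluster")
      log_stage(logf, "cluster",
                list(metric = wc$metric, k = wc$k,
                     n_pcs = red$n_retained))
      results$clustering <- wc
    } else {
      results$clustering <- utils::read.delim(cpath,
                                              stringsAsFactors = FALSE)
    }
  }
  invisible(results)
}
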
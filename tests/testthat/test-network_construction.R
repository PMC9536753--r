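test_that("z-scores follow the sample-sd convention", {
  m <- rbind(g1 = c(5, 5, 5), g2 = c(0, 2, 7))
  colnames(m) <- c("a", "b", "c")
  z <- zscore_expression(m, log_transform = FALSE)
  expect_equal(unname(z["g1", ]), c(0, 0, 0))  # zero-variance rule
  expect_equal(unname(z["g2", ]),
               unname((m["g2", ] - 3) / sd(m["g2", ])))

  two <- expr_matrix(c(0, 2), "g", c("a", "b"))
  z2 <- zscore_expression(two, log_transform = FALSE)
  expect_equal(unname(z2["g", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  perm <- c("c", "a", "b")
  expect_equal(zscore_expression(m[, perm], log_transform = FALSE),
               z[, perm])
  expect_error(zscore_expression(m[, "a", drop = FALSE]), ">= 2")
})

test_that("node weight is exp(z) and strictly monotone", {
  expect_equal(node_weight(0), 1)
  expect_equal(node_weight(1), exp(1))
  zs <- sort(rnorm(20))
  expect_true(all(diff(node_weight(zs)) > 0))
})

test_that("sigmoid rescaling hits the midpoint and limits", {
  expect_equal(sigmoid_rescale(5), 0.5)
  expect_equal(sigmoid_rescale(0), 1 / (1 + exp(5)))
  expect_gt(sigmoid_rescale(50), 1 - 1e-12)
  xs <- seq(0, 12, by = 0.5)
  expect_true(all(diff(sigmoid_rescale(xs)) > 0))
})

test_that("edge weight multiplies expression, peak and motif terms", {
  expect_equal(edge_weight(2, 5, 1e-5), 0.5)
  expect_equal(edge_weight(0, 5, 1e-5), 0)
  one <- edge_weight(3, 7, 1e-6)
  expect_equal(edge_weight(3, c(7, 7), c(1e-6, 1e-6)), 2 * one)
  # match p of zero is capped, not infinite
  expect_true(is.finite(edge_weight(1, 5, 0)))
  expect_equal(edge_weight(1, 5, 0),
               edge_weight(1, 5, 1e-25))
})

test_that("sites are assigned by strand-aware promoter windows", {
  ann <- data.frame(
    gene = c("gp", "gm"), contig = c("c1", "c2"),
    tss = c(10000L, 10000L), strand = c("+", "-"), is_tf = FALSE,
    stringsAsFactors = FALSE)
  class(ann) <- c("GeneAnnotation", "data.frame")
  site <- function(contig, start) data.frame(
    motif_id = "M1", tfs = "TF1", contig = contig, start = start,
    end = start + 10L, strand = "+", score = 100L, p_value = 1e-6,
    peak_neg_log10_p = 5, stringsAsFactors = FALSE)

  # 200 bp upstream of a '+' TSS: inside (5000, 1000), outside (100, 100)
  up <- site("c1", 10000L - 210L)
  expect_equal(assign_sites(up, ann, linkage_rule(5000, 1000))$gene, "gp")
  none <- assign_sites(up, ann, linkage_rule(100, 100))
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_unassigned"), 1L)

  # upstream of a '-' gene lies at higher coordinates
  upm <- site("c2", 10000L + 200L)
  expect_equal(assign_sites(upm, ann, linkage_rule(5000, 1000))$gene,
               "gm")
  downm <- site("c2", 10000L - 500L)
  expect_equal(assign_sites(downm, ann,
                            linkage_rule(5000, 1000))$gene, "gm")
  expect_equal(nrow(assign_sites(downm, ann, linkage_rule(5000, 100))),
               0L)

  # enhancer link table reaches a gene on another contig
  links <- data.frame(contig = "c1", start = 500L, end = 700L,
                      gene = "gm", stringsAsFactors = FALSE)
  far <- site("c1", 600L)
  got <- assign_sites(far, ann, linkage_rule(1000, 1000, links))
  expect_equal(got$gene, "gm")
})

test_that("network building plants one edge per (TF, target)", {
  genes <- c("TF1", "g1", "g2", "g3")
  cts <- c("ct1", "ct2")
  expr <- expr_matrix(c(8, 4, 16, 2, 32, 1, 8, 8), genes, cts)
  ann <- data.frame(gene = genes,
                    contig = paste0("chr_", genes),
                    tss = 5000L, strand = "+", is_tf = genes == "TF1",
                    stringsAsFactors = FALSE)
  class(ann) <- c("GeneAnnotation", "data.frame")
  lib <- make_library(list(rand_pwm(6)), tfs = list("TF1"))
  sites <- data.frame(
    motif_id = "M1", tfs = "TF1",
    contig = paste0("chr_", c("g1", "g2", "g3")),
    start = 4500L, end = 4506L, strand = "+", score = 50L,
    p_value = 1e-5, peak_neg_log10_p = 5, stringsAsFactors = FALSE)
  net <- build_network("ct1", sites, ann, expr, linkage_rule(),
                       library = lib)
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$edges$target, c("g1", "g2", "g3"))
  expect_equal(net$edges$tf, rep("TF1", 3))
  g <- log2(expr["TF1", "ct1"] + 1)
  expect_equal(net$edges$weight, rep(g * 0.5 * 0.5, 3))
  expect_equal(net$edges$n_sites, rep(1L, 3))
  # node weights are e^z for the requested cell type
  z <- zscore_expression(expr)[, "ct1"]
  expect_equal(net$nodes$node_weight, unname(exp(z)))
})

test_that("TFs sharing a motif get their own edges scaled by expression", {
  genes <- c("TF1", "TF2", "g1")
  expr <- expr_matrix(c(3, 7, 1, 3, 7, 1), genes, c("ct1", "ct2"))
  ann <- data.frame(gene = genes, contig = paste0("chr_", genes),
                    tss = 5000L, strand = "+",
                    is_tf = genes != "g1", stringsAsFactors = FALSE)
  class(ann) <- c("GeneAnnotation", "data.frame")
  lib <- make_library(list(rand_pwm(6)), tfs = list(c("TF1", "TF2")))
  sites <- data.frame(motif_id = "M1", tfs = "TF1;TF2",
                      contig = "chr_g1", start = 4500L, end = 4506L,
                      strand = "+", score = 10L, p_value = 1e-4,
                      peak_neg_log10_p = 6, stringsAsFactors = FALSE)
  net <- build_network("ct1", sites, ann, expr, linkage_rule(),
                       library = lib)
  expect_equal(nrow(net$edges), 2L)
  w <- setNames(net$edges$weight, net$edges$tf)
  expect_equal(w[["TF1"]] / w[["TF2"]], log2(3 + 1) / log2(7 + 1))
})

test_that("edge weights scale linearly in g and are recomputable", {
  genes <- c("TF1", "TF2", "g1", "g2")
  expr <- expr_matrix(rep(c(4, 9, 2, 5), 2), genes, c("ct1", "ct2"))
  ann <- data.frame(gene = genes, contig = paste0("chr_", genes),
                    tss = 5000L, strand = "+",
                    is_tf = genes %in% c("TF1", "TF2"),
                    stringsAsFactors = FALSE)
  class(ann) <- c("GeneAnnotation", "data.frame")
  lib <- make_library(list(rand_pwm(6), rand_pwm(5)),
                      tfs = list("TF1", "TF2"))
  sites <- data.frame(
    motif_id = c("M1", "M1", "M2"), tfs = c("TF1", "TF1", "TF2"),
    contig = c("chr_g1", "chr_g1", "chr_g2"),
    start = c(4300L, 4600L, 4500L), end = c(4306L, 4606L, 4505L),
    strand = "+", score = 10L, p_value = c(1e-6, 1e-7, 1e-5),
    peak_neg_log10_p = c(4, 4, 8), stringsAsFactors = FALSE)
  net <- build_network("ct1", sites, ann, expr, linkage_rule(),
                       library = lib, log_transform = FALSE)
  # self-consistency: stored weights recomputable from stored sites
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    st <- net$assigned_sites[net$assigned_sites$tf == e$tf &
                               net$assigned_sites$gene == e$target, ]
    expect_equal(e$weight,
                 edge_weight(expr[e$tf, "ct1"], st$peak_neg_log10_p,
                             st$p_value),
                 tolerance = 1e-9)
    expect_equal(e$n_sites, nrow(st))
  }
  # doubling a TF's g doubles its edges and no others
  expr2 <- expr
  expr2["TF1", ] <- expr["TF1", ] * 2
  net2 <- build_network("ct1", sites, ann, expr2, linkage_rule(),
                        library = lib, log_transform = FALSE)
  expect_equal(net2$edges$weight[net2$edges$tf == "TF1"],
               2 * net$edges$weight[net$edges$tf == "TF1"])
  expect_equal(net2$edges$weight[net2$edges$tf == "TF2"],
               net$edges$weight[net$edges$tf == "TF2"])
})

test_that("a siteless network keeps its nodes and warns", {
  genes <- c("TF1", "g1")
  expr <- expr_matrix(c(1, 2, 3, 4), genes, c("ct1", "ct2"))
  ann <- data.frame(gene = genes, contig = paste0("chr_", genes),
                    tss = 100L, strand = "+", is_tf = genes == "TF1",
                    stringsAsFactors = FALSE)
  class(ann) <- c("GeneAnnotation", "data.frame")
  lib <- make_library(list(rand_pwm(4)), tfs = list("TF1"))
  empty_sites <- data.frame(motif_id = character(), tfs = character(),
                            contig = character(), start = integer(),
                            end = integer(), strand = character(),
                            score = integer(), p_value = numeric(),
                            peak_neg_log10_p = numeric())
  expect_warning(
    net <- build_network("ct1", empty_sites, ann, expr, linkage_rule(),
                         library = lib),
    "no edges")
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(net$nodes), 2L)
})

test_that("visualization subsampling preserves the TF ratio deterministically", {
  set.seed(5)
  tfs <- sprintf("T%02d", 1:11)
  nontfs <- sprintf("n%02d", 1:30)
  genes <- c(tfs, nontfs)
  nodes <- data.frame(gene = genes, is_tf = genes %in% tfs,
                      node_weight = 1, stringsAsFactors = FALSE)
  edges <- data.frame(tf = "T01", target = c(tfs[-1], nontfs),
                      weight = 2, n_sites = 1L, stringsAsFactors = FALSE)
  net <- structure(list(cell_type = "ct", nodes = nodes, edges = edges,
                        assigned_sites = NULL),
                   class = "RegulatoryNetwork")
  # 10 TF + 30 non-TF regulatees, n = 20 -> 5 TF + 15 non-TF
  out <- subsample_for_visualization(net, "T01", min_weight = 1,
                                     n_regulatees = 20L,
                                     edge_fraction = 1, seed = 3L)
  kept <- unique(out$target)
  expect_equal(sum(kept %in% tfs), 5L)
  expect_equal(sum(kept %in% nontfs), 15L)
  out2 <- subsample_for_visualization(net, "T01", min_weight = 1,
                                      n_regulatees = 20L,
                                      edge_fraction = 1, seed = 3L)
  expect_identical(out, out2)
  expect_warning(
    empty <- subsample_for_visualization(net, "T01", min_weight = 99),
    "no regulatees")
  expect_equal(nrow(empty), 0L)
})
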
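#' @useDynLib regnetrank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# All genomic intervals are 0-based half-open internally; conversion to and
# from 1-based conventions happens only at the file boundary.

#' Read a genome from a FASTA file
#'
#' Loads all contigs into memory as upper-case DNA strings over the alphabet
#' \{A, C, G, T, N\}. Any other character (including IUPAC ambiguity codes
#' and RNA's U) is rejected with an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A `GenomeSequence`: a named character vector of contig sequences,
#'   one element per contig, with class `"GenomeSequence"`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(startsWith(lines, ">")))
    stop("no records in FASTA file: ", path)
  bad <- which(!startsWith(lines, ">") &
                 grepl("[^ACGTNacgtn]", lines, perl = TRUE) &
                 nzchar(lines))
  if (length(bad) > 0L)
    stop("illegal character in FASTA sequence at line ", bad[1L], " of ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate contig header in FASTA: ", nm[duplicated(nm)][1L])
  x <- toupper(as.character(seqs))
  names(x) <- nm
  if (any(nchar(x) == 0L)) stop("empty sequence for contig: ",
                                nm[nchar(x) == 0L][1L])
  structure(x, class = "GenomeSequence")
}

#' Write a genome to a FASTA file
#'
#' @param genome A `GenomeSequence` (named character vector of contigs).
#' @param path Output path.
#' @param width Line-wrap width (bases per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read ATAC-seq peaks from a narrowPeak/BED file
#'
#' Parses a BED-style file carrying a -log10(p) significance column for each
#' peak (column 8 in the ENCODE narrowPeak convention). Intervals are
#' 0-based half-open as in BED.
#'
#' @param path Path to a narrowPeak or BED file.
#' @param pvalue_column 1-based index of the -log10(p) column (default 8,
#'   the narrowPeak `pValue` field).
#' @return A `PeakSet`: a data.frame with columns `contig`, `start`, `end`,
#'   `neg_log10_p`, sorted by (contig, start).
#' @export
read_narrowpeak <- function(path, pvalue_column = 8L) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no records in peak file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < pvalue_column))
    stop("line ", which(nf < pvalue_column)[1L], ": fewer than ",
         pvalue_column, " columns in ", path)
  contig <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  nlp <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", pvalue_column)))
  bad <- which(is.na(start) | is.na(end) | is.na(nlp))
  if (length(bad) > 0L)
    stop("line ", bad[1L], ": non-numeric coordinate or p-value field")
  bad <- which(start >= end)
  if (length(bad) > 0L)
    stop("line ", bad[1L], ": peak start >= end")
  bad <- which(nlp < 0)
  if (length(bad) > 0L)
    stop("line ", bad[1L], ": negative -log10(p) value")
  ps <- data.frame(contig = contig, start = as.integer(start),
                   end = as.integer(end), neg_log10_p = nlp,
                   stringsAsFactors = FALSE)
  ps <- ps[order(ps$contig, ps$start, ps$end), , drop = FALSE]
  rownames(ps) <- NULL
  class(ps) <- c("PeakSet", "data.frame")
  ps
}

#' Write a PeakSet as narrowPeak
#'
#' Emits BED6+4 with the -log10(p) in the pValue column; name, score,
#' strand, signalValue, qValue and summit fields are fillers.
#'
#' @param peaks A `PeakSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  out <- data.frame(peaks$contig, peaks$start, peaks$end,
                    paste0("peak_", seq_len(n)), 0L, ".",
                    0, format_num(peaks$neg_log10_p), -1, -1,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene expression matrix from TSV
#'
#' First column holds gene symbols, the header row names the cell types.
#' Values must be finite and nonnegative (TPM-like scale); the reader is
#' unit-agnostic.
#'
#' @param path Path to a tab-delimited text file.
#' @return A numeric matrix (genes x cell types) with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs >= 1 cell-type column")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene symbol in expression table: ",
         genes[duplicated(genes)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell-type label: ",
         colnames(m)[duplicated(colnames(m))][1L])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite expression value")
  if (any(m < 0)) stop("negative expression value for gene ",
                       genes[which(rowSums(m < 0) > 0)[1L]])
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#' @param expr Numeric matrix, genes x cell types.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  write_labelled_matrix(expr, path, first_col = "gene")
}

#' Read a gene annotation from BED6
#'
#' Each record gives one gene: `name` is the gene symbol and the TSS is the
#' `start` coordinate for `+` genes and `end - 1` for `-` genes (0-based).
#'
#' @param path Path to a BED6 file.
#' @param tf_symbols Optional character vector of TF gene symbols used to
#'   set the `is_tf` flag (typically from [read_motifs_meme()]'s map).
#' @return A `GeneAnnotation` data.frame with columns `gene`, `contig`,
#'   `tss`, `strand`, `is_tf`.
#' @export
read_gene_annotation <- function(path, tf_symbols = character()) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("gene annotation must be BED6")
  names(df)[1:6] <- c("contig", "start", "end", "gene", "score", "strand")
  if (anyDuplicated(df$gene))
    stop("duplicate gene symbol in annotation: ",
         df$gene[duplicated(df$gene)][1L])
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  ann <- data.frame(gene = df$gene, contig = df$contig,
                    tss = ifelse(df$strand == "+", df$start, df$end - 1L),
                    strand = df$strand,
                    is_tf = df$gene %in% tf_symbols,
                    stringsAsFactors = FALSE)
  class(ann) <- c("GeneAnnotation", "data.frame")
  ann
}

#' Write a gene annotation as BED6
#' @param annotation A `GeneAnnotation`.
#' @param path Output path.
#' @param span Number of bases to span downstream of the TSS for the BED
#'   interval (the TSS itself is recoverable from start/strand).
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path, span = 1L) {
  start <- ifelse(annotation$strand == "+", annotation$tss,
                  annotation$tss - span + 1L)
  out <- data.frame(annotation$contig, start, start + span,
                    annotation$gene, 0L, annotation$strand,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a motif library from MEME minimal format
#'
#' Loads position probability matrices and joins them to the TF genes they
#' represent through an explicit two-column sidecar table (motif id, TF
#' symbol; many-to-many). Motifs without any TF mapping are dropped with a
#' warning, as are map rows referencing absent motifs.
#'
#' @param path Path to a MEME minimal-format motif file.
#' @param tf_map_path Path to a tab-delimited motif-id / TF-symbol table
#'   (no header).
#' @return A `MotifLibrary`: a list of motifs, each a list with elements
#'   `id`, `tfs` (character vector), `pwm` (L x 4 matrix, columns ACGT)
#'   and `background` (length-4 frequency vector).
#' @export
read_motifs_meme <- function(path, tf_map_path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  if (!file.exists(tf_map_path)) stop("TF map file not found: ", tf_map_path)
  lines <- readLines(path, warn = FALSE)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0L && bg_at[1L] < length(lines)) {
    tok <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    if (length(tok) >= 8L) {
      v <- as.numeric(tok[c(2L, 4L, 6L, 8L)])
      if (!any(is.na(v))) bg <- stats::setNames(v, c("A", "C", "G", "T"))
    }
  }
  starts <- grep("^MOTIF\\s", lines)
  if (length(starts) == 0L) stop("no MOTIF records in ", path)
  motifs <- list()
  for (s in starts) {
    id <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[s])), "\\s+")[[1L]][1L]
    hdr <- grep("^letter-probability matrix", lines[seq(s, length(lines))])[1L]
    if (is.na(hdr)) stop("motif ", id, ": missing letter-probability matrix")
    i <- s + hdr - 1L + 1L
    rows <- list()
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+\\s+[0-9.eE+-]+\\s+[0-9.eE+-]+\\s+[0-9.eE+-]+\\s*$",
                 lines[i])) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]])
      i <- i + 1L
    }
    if (length(rows) < 1L) stop("motif ", id, ": empty matrix")
    pwm <- do.call(rbind, rows)
    colnames(pwm) <- c("A", "C", "G", "T")
    if (any(abs(rowSums(pwm) - 1) > 1e-3))
      stop("motif ", id, ": PWM row does not sum to 1 (tolerance 1e-3)")
    pwm <- pwm / rowSums(pwm)
    motifs[[id]] <- list(id = id, tfs = character(), pwm = pwm,
                         background = bg)
  }
  map <- utils::read.delim(tf_map_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(map) < 2L) stop("TF map must have two columns")
  unknown <- setdiff(unique(map[[1L]]), names(motifs))
  if (length(unknown) > 0L)
    warning("TF map references absent motif(s): ",
            paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(map))) {
    id <- map[i, 1L]
    if (id %in% names(motifs))
      motifs[[id]]$tfs <- union(motifs[[id]]$tfs, map[i, 2L])
  }
  unmapped <- names(motifs)[vapply(motifs, function(m) length(m$tfs) == 0L,
                                   logical(1L))]
  if (length(unmapped) > 0L) {
    warning("dropping motif(s) without TF mapping: ",
            paste(unmapped, collapse = ", "))
    motifs <- motifs[setdiff(names(motifs), unmapped)]
  }
  structure(unname(motifs), names = vapply(motifs, `[[`, "", "id"),
            class = "MotifLibrary")
}

#' Write a motif library in MEME minimal format (with TF-map sidecar)
#' @param library A `MotifLibrary`.
#' @param path Output MEME path.
#' @param tf_map_path Output path for the motif-to-TF map TSV.
#' @return `path`, invisibly.
#' @export
write_motifs_meme <- function(library, path, tf_map_path) {
  bg <- library[[1L]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %s C %s G %s T %s", format_num(bg[1L]),
                       format_num(bg[2L]), format_num(bg[3L]),
                       format_num(bg[4L])), ""), con)
  for (m in library) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(m$pwm)), con)
    for (r in seq_len(nrow(m$pwm)))
      writeLines(paste(format_num(m$pwm[r, ]), collapse = "  "), con)
    writeLines("", con)
  }
  map <- do.call(rbind, lapply(library, function(m)
    data.frame(m$id, m$tfs, stringsAsFactors = FALSE)))
  utils::write.table(map, tf_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a PageRank score matrix as TSV
#'
#' Values round-trip through [read_pagerank_matrix()] to at least 12
#' significant digits. Matrices containing non-finite values are refused.
#'
#' @param matrix Numeric matrix, TFs x cell types, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pagerank_matrix <- function(matrix, path) {
  write_labelled_matrix(matrix, path, first_col = "tf")
}

#' Read a PageRank score matrix from TSV
#' @param path Path written by [write_pagerank_matrix()].
#' @return Numeric matrix with dimnames.
#' @export
read_pagerank_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) stop("empty matrix in ", path)
  if (anyDuplicated(df[[1L]])) stop("duplicate row label in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite value in matrix ", path)
  rownames(m) <- df[[1L]]
  m
}

# shared writer for labelled numeric matrices; %.17g keeps full double
# precision so write/read round-trips are exact to the last bit
write_labelled_matrix <- function(m, path, first_col) {
  if (is.null(dim(m)) || nrow(m) == 0L || ncol(m) == 0L)
    stop("refusing to write empty matrix")
  if (any(!is.finite(m))) stop("refusing to write non-finite values")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have row and column names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(first_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(x)
    paste(format_num(x), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

format_num <- function(x) {
  out <- sprintf("%.17g", x)
  # trim to shortest representation that round-trips exactly
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}
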
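#' Read a feature-by-sample expression matrix from TSV
#'
#' First column holds feature ids, the header row holds sample ids. Missing
#' values are rejected: the arrays this pipeline consumes are complete
#' matrices, and every downstream step (correlation, quantile normalization)
#' assumes completeness.
#'
#' @param path TSV file path.
#' @return Numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs an id column and >=1 sample: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values not allowed in expression matrix: ", path)
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param m Matrix with rownames (feature ids) and colnames (sample ids).
#' @param path Output path.
#' @param id_col Name of the first (id) column.
#' @export
write_expression_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read node types (gene / lncRNA) from a two-column TSV
#'
#' @param path TSV with columns node_id, node_type (no header required; a
#'   header row `node_id<TAB>node_type` is tolerated).
#' @return Named character vector mapping node id to `"gene"` or `"lncRNA"`.
#' @export
read_node_types <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) > 0L && identical(tolower(df[1L, 1L]), "node_id")) df <- df[-1L, , drop = FALSE]
  types <- as.character(df[[2L]])
  bad <- setdiff(unique(types), c("gene", "lncRNA"))
  if (length(bad)) stop("unknown node type(s): ", paste(bad, collapse = ", "))
  setNames(types, as.character(df[[1L]]))
}

#' @rdname read_node_types
#' @param types Named character vector as returned by [read_node_types()].
#' @export
write_node_types <- function(types, path) {
  write.table(data.frame(node_id = names(types), node_type = unname(types)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style protein-protein interaction edge list
#'
#' Three tab-separated columns: id_a, id_b, score. Raw STRING combined scores
#' (0-1000) are normalized to interaction probabilities via `score_divisor`.
#'
#' @param path TSV path.
#' @param score_divisor Divisor applied to the score column (e.g. 1000 for raw
#'   STRING exports); default 1 assumes pre-normalized scores.
#' @return data.frame with columns a, b, score; scores validated to lie in
#'   \[0, 1\] after division.
#' @export
read_ppi_tsv <- function(path, score_divisor = 1) {
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) > 0L && is.na(suppressWarnings(as.numeric(df[1L, 3L])))) df <- df[-1L, , drop = FALSE]
  out <- data.frame(a = as.character(df[[1L]]), b = as.character(df[[2L]]),
                    score = as.numeric(df[[3L]]) / score_divisor,
                    stringsAsFactors = FALSE)
  if (any(out$score < 0 | out$score > 1))
    stop("PPI scores outside [0,1] after applying score_divisor = ", score_divisor)
  out
}

#' Read per-disease seed genes from a two-column TSV
#'
#' @param path TSV with columns disease_id, gene_id.
#' @return Named list of character vectors, one per disease.
#' @export
read_seeds_tsv <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) > 0L && identical(tolower(df[1L, 1L]), "disease_id")) df <- df[-1L, , drop = FALSE]
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_seeds_tsv
#' @param seeds Named list of character vectors.
#' @export
write_seeds_tsv <- function(seeds, path) {
  df <- data.frame(disease_id = rep(names(seeds), lengths(seeds)),
                   gene_id = unlist(seeds, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a disease-by-disease phenotype similarity matrix from TSV
#'
#' MimMiner-style exports: disease ids in the header row and first column.
#' The matrix must be square and symmetric with entries in \[0, 1\]. An absent
#' or non-unit diagonal is reset to 1 (self-similarity is maximal).
#'
#' @param path TSV path.
#' @return Symmetric numeric matrix with unit diagonal, disease ids as dimnames.
#' @export
read_phenotype_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1L, stringsAsFactors = FALSE)
  P <- as.matrix(df)
  storage.mode(P) <- "double"
  validate_phenotype(P)
}

#' @rdname read_phenotype_tsv
#' @param P Similarity matrix.
#' @export
write_phenotype_tsv <- function(P, path) {
  write_expression_tsv(P, path, id_col = "disease_id")
}

validate_phenotype <- function(P) {
  if (nrow(P) != ncol(P)) stop("phenotype matrix must be square")
  if (is.null(rownames(P))) rownames(P) <- colnames(P)
  if (!identical(rownames(P), colnames(P)))
    stop("phenotype matrix row/column disease ids disagree")
  if (anyNA(P) || any(P < 0) || any(P > 1))
    stop("phenotype similarities must lie in [0,1]")
  if (max(abs(P - t(P))) > 1e-8) stop("phenotype matrix must be symmetric")
  P <- (P + t(P)) / 2
  diag(P) <- 1
  P
}

#' Read known positives (e.g. disease lncRNAs) from a two-column TSV
#'
#' @param path TSV with columns disease_id, node_id.
#' @return Named list of character vectors.
#' @export
read_positives_tsv <- function(path) read_seeds_tsv(path)

#' Read probe intervals from a BED6 file
#'
#' BED half-open 0-based coordinates are converted to the 1-based closed
#' convention of [GenomicRanges::GRanges] on import. Probe ids come from the
#' BED name column and must be unique. Records with start >= end are rejected
#' by name.
#'
#' @param path BED6 path.
#' @return `GRanges` of probes, names = probe ids.
#' @export
read_probes_bed <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("probe BED needs >=4 columns (chrom,start,end,name)")
  start0 <- as.integer(df[[2L]]); end0 <- as.integer(df[[3L]])
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("malformed interval (start >= end) for probe(s): ",
         paste(df[[4L]][bad], collapse = ", "))
  if (anyDuplicated(df[[4L]])) stop("duplicate probe ids in ", path)
  strand <- if (ncol(df) >= 6L) df[[6L]] else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1L]],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand)
  names(gr) <- df[[4L]]
  gr
}

#' Read gene models (with biotype and exons) from GFF3 or BED12
#'
#' GFF3 input needs `gene` and `exon` features with a `gene_biotype` (or
#' `biotype`) attribute on the gene and `Parent`/`gene_id` linkage on exons.
#' BED12 input encodes exons as blocks; BED12 carries no biotype field, so
#' BED12 callers must pass `biotypes` explicitly.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`) path.
#' @param biotypes Optional named character vector gene_id -> biotype
#'   (`"lncRNA"` or `"coding"`), required for BED12 input.
#' @return List of gene models; each element has `gene_id`, `biotype`,
#'   `exons` (`GRanges`) and `span` (`GRanges` of length 1).
#' @export
read_gene_models <- function(path, biotypes = NULL) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$blocks)) stop("BED gene models must be BED12 (need blocks)")
    if (is.null(biotypes)) stop("BED12 gene models require a `biotypes` vector")
    ids <- gr$name
    models <- lapply(seq_along(gr), function(i) {
      span <- gr[i]
      ex <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(span),
        ranges = IRanges::shift(gr$blocks[[i]], GenomicRanges::start(span) - 1L),
        strand = GenomicRanges::strand(span))
      bt <- biotypes[[ids[i]]]
      if (is.null(bt) || is.na(bt)) stop("no biotype for gene ", ids[i])
      list(gene_id = ids[i], biotype = bt, exons = ex, span = span)
    })
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[gr$type == "gene"]
    exons <- gr[gr$type == "exon"]
    bt <- if (!is.null(genes$gene_biotype)) genes$gene_biotype else genes$biotype
    if (is.null(bt)) stop("GFF3 gene features need a gene_biotype attribute")
    gid <- if (!is.null(genes$ID)) genes$ID else genes$gene_id
    exon_parent <- if (!is.null(exons$Parent)) {
      vapply(exons$Parent, function(p) as.character(p)[1L], character(1))
    } else as.character(exons$gene_id)
    models <- lapply(seq_along(genes), function(i) {
      ex <- exons[exon_parent == gid[i]]
      list(gene_id = gid[i], biotype = bt[i], exons = ex, span = genes[i])
    })
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  validate_gene_models(models)
}

validate_gene_models <- function(models) {
  for (m in models) {
    if (length(m$exons) == 0L) stop("gene ", m$gene_id, " has no exons")
    if (!m$biotype %in% c("lncRNA", "coding"))
      stop("gene ", m$gene_id, ": biotype must be 'lncRNA' or 'coding'")
    if (!all(IRanges::overlapsAny(m$exons, m$span, type = "within")))
      stop("gene ", m$gene_id, ": exon outside gene span")
  }
  models
}
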
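#' Assign exon-array probes to lncRNA genes by interval containment
#'
#' A probe is kept for an lncRNA when it falls completely inside at least one
#' exon of that lncRNA and does not overlap the genomic span of any
#' protein-coding gene. Overlap with the full coding-gene span (introns
#' included) disqualifies a probe: span overlap is the stricter reading and
#' avoids ambiguous intronic signal. Probes contained in exons of two or more
#' distinct lncRNAs are discarded as ambiguous, in the spirit of unique
#' mapping. Finally, lncRNAs retained by fewer than four probes are dropped
#' entirely — a single-digit probe count gives too noisy a summarized value.
#'
#' @param probes `GRanges` of probe intervals (names = probe ids), e.g. from
#'   [read_probes_bed()].
#' @param models Gene model list from [read_gene_models()] (lncRNA and coding
#'   entries mixed).
#' @param stranded If `TRUE`, containment requires strand match; the default
#'   `FALSE` ignores strand, since exon arrays are unstranded at
#'   hybridization.
#' @param min_probes Minimum probes per retained lncRNA (default 4).
#' @return Named character vector mapping probe id to lncRNA gene id.
#' @export
assign_probes <- function(probes, models, stranded = FALSE, min_probes = 4L) {
  if (is.null(names(probes)) || anyDuplicated(names(probes)))
    stop("probes must carry unique names (probe ids)")
  bt <- vapply(models, `[[`, character(1), "biotype")
  lnc <- models[bt == "lncRNA"]
  coding <- models[bt == "coding"]

  if (length(lnc) == 0L) return(setNames(character(0), character(0)))

  # one GRanges of all lncRNA exons, tagged with owning gene
  lnc_exons <- do.call(c, lapply(unname(lnc), function(m) m$exons))
  exon_owner <- rep(vapply(lnc, `[[`, character(1), "gene_id"),
                    vapply(lnc, function(m) length(m$exons), integer(1)))

  hits <- GenomicRanges::findOverlaps(probes, lnc_exons, type = "within",
                                      ignore.strand = !stranded)
  if (length(hits) == 0L) return(setNames(character(0), character(0)))
  cand <- unique(data.frame(probe = names(probes)[S4Vectors::queryHits(hits)],
                            gene = exon_owner[S4Vectors::subjectHits(hits)],
                            stringsAsFactors = FALSE))

  # drop probes overlapping any protein-coding gene span (any overlap)
  if (length(coding)) {
    coding_spans <- do.call(c, lapply(unname(coding), function(m) m$span))
    over <- IRanges::overlapsAny(probes, coding_spans, ignore.strand = !stranded)
    cand <- cand[!cand$probe %in% names(probes)[over], , drop = FALSE]
  }

  # ambiguity: probe inside exons of >= 2 distinct lncRNAs
  n_genes <- table(cand$probe)
  cand <- cand[cand$probe %in% names(n_genes)[n_genes == 1L], , drop = FALSE]

  # >= min_probes probes per retained lncRNA
  n_probes <- table(cand$gene)
  cand <- cand[cand$gene %in% names(n_probes)[n_probes >= min_probes], , drop = FALSE]

  ord <- order(cand$probe)
  setNames(cand$gene[ord], cand$probe[ord])
}

#' Quantile-normalize a feature-by-sample matrix
#'
#' Classic quantile normalization: each column's values are replaced by the
#' mean, across columns, of the values at the same rank, so every column ends
#' with an identical distribution (the vector of row means of column-sorted
#' values). Backed by [limma::normalizeQuantiles()].
#'
#' Ties: with `ties = "first"` (default) tied values are assigned reference
#' quantiles in their original order, which preserves the exact
#' identical-sorted-columns property even in the presence of ties. With
#' `ties = "average"` tied values within a column receive the mean of the
#' reference values at their rank positions (the limma `ties = TRUE`
#' convention); tied entries then share one value and the per-column
#' distributions agree only up to that averaging.
#'
#' @param m Numeric feature-by-sample matrix, no missing values.
#' @param ties `"first"` or `"average"`.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m, ties = c("first", "average")) {
  ties <- match.arg(ties)
  if (!is.matrix(m)) m <- as.matrix(m)
  if (length(m) == 0L) stop("cannot quantile-normalize an empty matrix")
  if (anyNA(m)) stop("missing values not allowed in quantile normalization")
  out <- limma::normalizeQuantiles(m, ties = (ties == "average"))
  dimnames(out) <- dimnames(m)
  out
}

#' Summarize probe intensities into an lncRNA expression matrix
#'
#' Pipeline order is fixed: per-probe log2 transform, then per-lncRNA
#' arithmetic mean over its assigned probes, then quantile normalization
#' across samples. (Averaging on the log2 scale, i.e. a geometric mean of raw
#' intensities, is the conventional choice for multiplicative array noise.)
#'
#' @param raw Probe-by-sample intensity matrix (strictly positive; rownames =
#'   probe ids).
#' @param assignment Probe-to-lncRNA map from [assign_probes()].
#' @param normalize Apply quantile normalization after summarization
#'   (default `TRUE`).
#' @param ties Tie handling for [quantile_normalize()].
#' @return lncRNA-by-sample matrix of normalized log2 expression.
#' @export
summarize_lncrna_expression <- function(raw, assignment, normalize = TRUE,
                                        ties = "first") {
  if (length(assignment) == 0L) stop("empty probe assignment")
  missing <- setdiff(names(assignment), rownames(raw))
  if (length(missing))
    stop("assigned probe(s) missing from intensity matrix: ",
         paste(missing, collapse = ", "))
  sub <- raw[names(assignment), , drop = FALSE]
  if (any(sub <= 0))
    stop("nonpositive intensities: log2 transform undefined")
  lg <- log2(sub)
  genes <- sort(unique(unname(assignment)))
  expr <- do.call(rbind, lapply(genes, function(g) {
    colMeans(lg[names(assignment)[assignment == g], , drop = FALSE])
  }))
  rownames(expr) <- genes
  colnames(expr) <- colnames(raw)
  if (normalize) expr <- quantile_normalize(expr, ties = ties)
  expr
}

#' Re-annotate an exon array to lncRNA expression (file-level wrapper)
#'
#' Reads probe intervals, gene models and raw intensities, runs
#' [assign_probes()] and [summarize_lncrna_expression()], and writes the
#' resulting lncRNA expression matrix.
#'
#' @param probes_path BED6 probe intervals.
#' @param models_path GFF3 (or BED12) gene models.
#' @param intensities_path Probe-by-sample TSV of raw intensities.
#' @param out_path Output TSV for the lncRNA expression matrix.
#' @param stranded Strand-matched assignment (see [assign_probes()]).
#' @param biotypes Passed to [read_gene_models()] for BED12 input.
#' @return Invisibly, the lncRNA expression matrix.
#' @export
reannotate <- function(probes_path, models_path, intensities_path, out_path,
                       stranded = FALSE, biotypes = NULL) {
  probes <- read_probes_bed(probes_path)
  models <- read_gene_models(models_path, biotypes = biotypes)
  raw <- read_expression_tsv(intensities_path)
  assignment <- assign_probes(probes, models, stranded = stranded)
  if (length(assignment) == 0L)
    stop("no probes survived assignment; nothing to summarize")
  expr <- summarize_lncrna_expression(raw, assignment)
  write_expression_tsv(expr, out_path, id_col = "gene_id")
  invisible(expr)
}
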
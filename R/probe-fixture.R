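#' Synthetic probe-level fixture for the re-annotation rules
#'
#' A small, fully deterministic fixture exercising every assignment rule:
#' exon containment, partial-overlap exclusion, coding-gene-span exclusion,
#' the >= 4 probes per lncRNA filter, and ambiguity discard for probes inside
#' exons of two lncRNAs. The expected assignment is enumerated by hand in the
#' returned manifest, independent of the assignment code.
#'
#' Layout (chr1, 1-based closed coordinates):
#' \itemize{
#'   \item `lncA` — two exons, clear of coding genes; probes pA1-pA4 inside
#'     exons (assigned), pA5 straddles an exon boundary (excluded).
#'   \item `lncB` — only 3 contained probes: dropped by the min-probe filter.
#'   \item `lncC` — 4 contained probes, but pC3/pC4 overlap the span of
#'     coding gene `codY`: 2 survive, lncC dropped.
#'   \item `lncD` / `lncE` — overlapping exons; pDE sits in both (ambiguous,
#'     discarded); lncD keeps pD1-pD4 (assigned), lncE has only 2 (dropped).
#'   \item `codX` — a coding gene; probe pX1 lies in its exon only.
#' }
#'
#' @return List with `probes` (`GRanges`), `models` (gene-model list),
#'   `raw` (probe-by-sample intensity matrix), `expected` (probe ->
#'   lncRNA map the rules must produce) and `manifest` (data.frame
#'   probe_id, expected_gene, reason).
#' @export
probe_fixture <- function() {
  gr <- function(starts, ends, strand = "+")
    GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends), strand)

  models <- list(
    lncA = list(gene_id = "lncA", biotype = "lncRNA",
                exons = gr(c(1000L, 1600L), c(1400L, 2000L)),
                span = gr(1000L, 2000L)),
    lncB = list(gene_id = "lncB", biotype = "lncRNA",
                exons = gr(3000L, 4000L), span = gr(3000L, 4000L)),
    lncC = list(gene_id = "lncC", biotype = "lncRNA",
                exons = gr(5000L, 6000L), span = gr(5000L, 6000L)),
    lncD = list(gene_id = "lncD", biotype = "lncRNA",
                exons = gr(7000L, 7500L), span = gr(7000L, 7500L)),
    lncE = list(gene_id = "lncE", biotype = "lncRNA",
                exons = gr(7200L, 7800L), span = gr(7200L, 7800L)),
    codX = list(gene_id = "codX", biotype = "coding",
                exons = gr(c(8000L, 8800L), c(8200L, 9000L)),
                span = gr(8000L, 9000L)),
    codY = list(gene_id = "codY", biotype = "coding",
                exons = gr(5500L, 6500L), span = gr(5500L, 6500L)))

  pr <- data.frame(
    probe_id = c("pA1", "pA2", "pA3", "pA4", "pA5",
                 "pB1", "pB2", "pB3",
                 "pC1", "pC2", "pC3", "pC4",
                 "pD1", "pD2", "pD3", "pD4", "pDE",
                 "pE1", "pE2", "pX1"),
    start = c(1010L, 1100L, 1650L, 1900L, 1390L,
              3010L, 3100L, 3200L,
              5010L, 5100L, 5600L, 5800L,
              7010L, 7050L, 7100L, 7150L, 7250L,
              7600L, 7700L, 8050L),
    stringsAsFactors = FALSE)
  pr$end <- pr$start + 24L
  probes <- gr(pr$start, pr$end)
  names(probes) <- pr$probe_id

  expected <- setNames(rep(c("lncA", "lncD"), each = 4L),
                       c("pA1", "pA2", "pA3", "pA4", "pD1", "pD2", "pD3", "pD4"))

  manifest <- data.frame(
    probe_id = pr$probe_id,
    expected_gene = ifelse(pr$probe_id %in% names(expected),
                           expected[pr$probe_id], NA_character_),
    reason = c(rep("contained in lncA exon, no coding overlap", 4L),
               "straddles lncA exon boundary",
               rep("lncB has only 3 surviving probes", 3L),
               rep("contained in lncC exon, no coding overlap (lncC later dropped: <4 probes)", 2L),
               rep("overlaps coding gene codY span", 2L),
               rep("contained in lncD exon, no coding overlap", 4L),
               "ambiguous: inside exons of lncD and lncE",
               rep("lncE has only 2 surviving probes", 2L),
               "inside coding gene codX only"),
    stringsAsFactors = FALSE)

  samples <- sprintf("S%d", 1:4)
  raw <- outer(seq_len(nrow(pr)), seq_along(samples),
               function(i, j) 2^(((i - 1L) %% 4L) + j))
  dimnames(raw) <- list(pr$probe_id, samples)

  list(probes = probes, models = models, raw = raw,
       expected = expected, manifest = manifest)
}

#' Write the probe fixture to disk in standard formats
#'
#' BED6 for probes (0-based half-open), GFF3 for gene models (with
#' `gene_biotype` attributes), TSV for intensities and JSON for the
#' hand-enumerated manifest — the exact formats [reannotate()] consumes.
#'
#' @param dir Output directory.
#' @return Invisibly, a named vector of the written paths.
#' @export
write_probe_fixture <- function(dir) {
  fx <- probe_fixture()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(probes = file.path(dir, "probes.bed"),
             models = file.path(dir, "models.gff3"),
             raw = file.path(dir, "intensities.tsv"),
             manifest = file.path(dir, "manifest.json"))

  p <- fx$probes
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(p)),
                    start = GenomicRanges::start(p) - 1L,
                    end = GenomicRanges::end(p),
                    name = names(p), score = 0L,
                    strand = as.character(GenomicRanges::strand(p)))
  bed$strand[bed$strand == "*"] <- "+"
  write.table(bed, paths["probes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  rows <- list()
  for (m in fx$models) {
    span <- m$span
    rows[[length(rows) + 1L]] <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(span), IRanges::ranges(span),
      GenomicRanges::strand(span), type = "gene", ID = m$gene_id,
      Parent = NA_character_, gene_biotype = m$biotype)
    for (i in seq_along(m$exons))
      rows[[length(rows) + 1L]] <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(m$exons[i]), IRanges::ranges(m$exons[i]),
        GenomicRanges::strand(m$exons[i]), type = "exon",
        ID = sprintf("%s.exon%d", m$gene_id, i),
        Parent = m$gene_id, gene_biotype = NA_character_)
  }
  gff <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(gff, paths["models"], format = "gff3")

  write_expression_tsv(fx$raw, paths["raw"], id_col = "probe_id")
  jsonlite::write_json(fx$manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
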
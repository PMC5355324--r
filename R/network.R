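#' Per-disease gene/lncRNA co-expression edges
#'
#' Computes Pearson correlations between all gene-gene and gene-lncRNA pairs
#' of one disease's expression matrix and keeps a pair as an edge iff its
#' co-expression score strictly exceeds the threshold for its kind (gene-gene
#' 0.8, gene-lncRNA 0.7 by default). lncRNA-lncRNA pairs are never formed.
#' The co-expression score is the absolute correlation |r| by default;
#' `signed = TRUE` thresholds raw r instead, keeping only strong positive
#' co-expression.
#'
#' Zero-variance features have undefined correlations; their pairs are
#' skipped with a warning.
#'
#' @param values Feature-by-sample matrix of log2 expression (>= 2 samples).
#' @param node_types Named vector mapping every feature id to `"gene"` or
#'   `"lncRNA"`.
#' @param disease_id Disease label carried into the edge set.
#' @param gg_threshold,gl_threshold Thresholds in (0,1) for gene-gene and
#'   gene-lncRNA pairs.
#' @param signed Threshold raw r rather than |r|.
#' @param block_size Number of features correlated per block; results do not
#'   depend on it, it only bounds memory for large feature sets.
#' @return Object of class `coexpression_edges`: list with `disease_id`,
#'   `edges` (data.frame `a`, `b` with a < b) and `node_types` covering all
#'   input features (so isolated nodes survive network integration).
#' @export
compute_coexpression <- function(values, node_types, disease_id,
                                 gg_threshold = 0.8, gl_threshold = 0.7,
                                 signed = FALSE, block_size = 2000L) {
  stopifnot(is.matrix(values), ncol(values) >= 2L)
  if (gg_threshold <= 0 || gg_threshold >= 1 || gl_threshold <= 0 || gl_threshold >= 1)
    stop("thresholds must lie in (0,1)")
  ids <- rownames(values)
  if (is.null(ids) || anyDuplicated(ids)) stop("values needs unique rownames")
  if (!all(ids %in% names(node_types)))
    stop("node_types missing for some features")
  types <- node_types[ids]

  sds <- apply(values, 1L, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate))
    warning(sum(degenerate), " zero-variance feature(s) skipped in ",
            disease_id, ": correlation undefined")

  keep <- which(!degenerate)
  n <- length(keep)
  edges <- list()
  # per-pair threshold by kind; lncRNA-lncRNA pairs get +Inf (never edges)
  kind_thr <- function(ta, tb) {
    thr <- ifelse(ta == "gene" & tb == "gene", gg_threshold,
                  ifelse(ta == "lncRNA" & tb == "lncRNA", Inf, gl_threshold))
    thr
  }
  xt <- t(values[keep, , drop = FALSE])
  for (s in seq(1L, n, by = block_size)) {
    e <- min(s + block_size - 1L, n)
    r <- suppressWarnings(cor(xt[, s:e, drop = FALSE], xt))
    score <- if (signed) r else abs(r)
    ta <- types[keep[s:e]]
    tb <- types[keep]
    thr <- outer(ta, tb, kind_thr)
    hit <- which(score > thr, arr.ind = TRUE)
    if (nrow(hit)) {
      ia <- keep[s:e][hit[, 1L]]
      ib <- keep[hit[, 2L]]
      sel <- ia < ib                       # canonical order, drops self-pairs
      if (any(sel))
        edges[[length(edges) + 1L]] <-
          data.frame(a = ids[ia[sel]], b = ids[ib[sel]], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(disease_id = disease_id, edges = edges, node_types = types),
            class = "coexpression_edges")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Integrate per-disease edge sets into the pan-cancer network
#'
#' Every edge's weight is the fraction of disease types in which the pair
#' passed its co-expression threshold (k of n diseases -> weight k/n), so
#' co-expression weights share the \[0, 1\] scale of the PPI interaction
#' probabilities merged later. Nodes are the union across diseases, including
#' features that formed no edge anywhere.
#'
#' @param edge_sets List of `coexpression_edges`, one per disease; disease
#'   ids must be distinct.
#' @param n_diseases Number of disease types used as the frequency
#'   denominator (defaults to `length(edge_sets)`).
#' @return Object of class `glcpn`: list with `nodes` (named type vector) and
#'   `edges` (data.frame `a`, `b`, `weight`, `n_coexpr`, `ppi_score`;
#'   `ppi_score` is `NA` until [merge_ppi()]).
#' @export
integrate_pan_cancer <- function(edge_sets, n_diseases = length(edge_sets)) {
  stopifnot(n_diseases >= 1L, length(edge_sets) >= 1L)
  dids <- vapply(edge_sets, `[[`, character(1), "disease_id")
  if (anyDuplicated(dids)) stop("duplicate disease_id in edge sets")

  nodes <- character(0)
  for (es in edge_sets) {
    nt <- es$node_types
    clash <- intersect(names(nodes), names(nt))
    if (length(clash) && !identical(nodes[clash], nt[clash]))
      stop("node typed inconsistently across diseases")
    nodes <- c(nodes, nt[setdiff(names(nt), names(nodes))])
  }

  all_edges <- do.call(rbind, lapply(edge_sets, `[[`, "edges"))
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    edges <- data.frame(a = character(0), b = character(0), weight = numeric(0),
                        n_coexpr = integer(0), ppi_score = numeric(0))
  } else {
    key <- pair_key(all_edges$a, all_edges$b)
    cnt <- table(key)
    first <- !duplicated(key)
    edges <- data.frame(a = pmin(all_edges$a, all_edges$b)[first],
                        b = pmax(all_edges$a, all_edges$b)[first],
                        stringsAsFactors = FALSE)
    edges$n_coexpr <- as.integer(cnt[key[first]])
    edges$weight <- edges$n_coexpr / n_diseases
    edges$ppi_score <- NA_real_
    edges <- edges[order(edges$a, edges$b),
                   c("a", "b", "weight", "n_coexpr", "ppi_score")]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, n_diseases = n_diseases),
            class = "glcpn")
}

#' Merge protein-protein interactions into the pan-cancer network
#'
#' PPI-only pairs are added as new edges weighted by their normalized
#' interaction probability. For pairs supported by both sources the edge
#' weight becomes `max(co-expression frequency, ppi score)` — the stronger
#' evidence wins and weights stay in \[0, 1\]. Provenance (`n_coexpr`,
#' `ppi_score`) records both values. No existing edge is ever removed or
#' down-weighted.
#'
#' @param net `glcpn` from [integrate_pan_cancer()].
#' @param ppi data.frame with columns `a`, `b`, `score` (scores in \[0, 1\]),
#'   e.g. from [read_ppi_tsv()].
#' @param default_type Node type assigned to PPI nodes absent from the
#'   co-expression network (proteins, hence `"gene"`).
#' @return Updated `glcpn`.
#' @export
merge_ppi <- function(net, ppi, default_type = "gene") {
  stopifnot(inherits(net, "glcpn"))
  if (nrow(ppi) == 0L) return(net)
  if (any(ppi$score < 0 | ppi$score > 1) || anyNA(ppi$score))
    stop("PPI scores must lie in [0,1]")
  if (any(ppi$a == ppi$b)) stop("PPI self-interactions not allowed")

  # collapse duplicate PPI pairs to their max score
  key <- pair_key(ppi$a, ppi$b)
  o <- order(key, -ppi$score)
  ppi <- ppi[o, ][!duplicated(key[o]), , drop = FALSE]
  key <- pair_key(ppi$a, ppi$b)

  edges <- net$edges
  ekey <- pair_key(edges$a, edges$b)
  idx <- match(key, ekey)

  hit <- !is.na(idx)
  if (any(hit)) {
    edges$ppi_score[idx[hit]] <- ppi$score[hit]
    edges$weight[idx[hit]] <- pmax(edges$weight[idx[hit]], ppi$score[hit])
  }
  if (any(!hit)) {
    new <- data.frame(a = pmin(ppi$a, ppi$b)[!hit], b = pmax(ppi$a, ppi$b)[!hit],
                      weight = ppi$score[!hit], n_coexpr = 0L,
                      ppi_score = ppi$score[!hit], stringsAsFactors = FALSE)
    edges <- rbind(edges, new)
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL

  new_nodes <- setdiff(unique(c(ppi$a, ppi$b)), names(net$nodes))
  nodes <- c(net$nodes, setNames(rep(default_type, length(new_nodes)), new_nodes))

  structure(list(nodes = nodes, edges = edges, n_diseases = net$n_diseases),
            class = "glcpn")
}

#' Build the pan-cancer co-expression network in one call
#'
#' Runs [compute_coexpression()] per disease, [integrate_pan_cancer()] and,
#' when `ppi` is given, [merge_ppi()].
#'
#' @param expr_list Named list of feature-by-sample matrices, one per
#'   disease type (studies of the same disease should be concatenated
#'   sample-wise beforehand, so frequencies count disease types).
#' @param node_types Named feature-type vector covering all features.
#' @param ppi Optional PPI data.frame (`a`, `b`, `score`).
#' @inheritParams compute_coexpression
#' @return A `glcpn`.
#' @export
build_glcpn <- function(expr_list, node_types, ppi = NULL,
                        gg_threshold = 0.8, gl_threshold = 0.7,
                        signed = FALSE, block_size = 2000L) {
  if (is.null(names(expr_list)) || anyDuplicated(names(expr_list)))
    stop("expr_list must be named by distinct disease ids")
  sets <- lapply(names(expr_list), function(d)
    compute_coexpression(expr_list[[d]], node_types, d,
                         gg_threshold = gg_threshold,
                         gl_threshold = gl_threshold,
                         signed = signed, block_size = block_size))
  net <- integrate_pan_cancer(sets, n_diseases = length(expr_list))
  if (!is.null(ppi)) net <- merge_ppi(net, ppi)
  net
}

#' @export
print.glcpn <- function(x, ...) {
  cat("Pan-cancer co-expression network (GLCPN)\n")
  cat("  nodes:", length(x$nodes),
      sprintf("(%d genes, %d lncRNAs)\n",
              sum(x$nodes == "gene"), sum(x$nodes == "lncRNA")))
  cat("  edges:", nrow(x$edges),
      sprintf("(%d with PPI support)\n", sum(!is.na(x$edges$ppi_score))))
  cat("  diseases integrated:", x$n_diseases, "\n")
  invisible(x)
}

#' Write / read a pan-cancer network as edge-list + node-type TSVs
#'
#' @param net A `glcpn`.
#' @param edges_path Edge-list TSV (a, b, weight, n_coexpr, ppi_score).
#' @param nodes_path Node-type TSV.
#' @export
write_glcpn <- function(net, edges_path, nodes_path) {
  write.table(net$edges, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_node_types(net$nodes, nodes_path)
  invisible(net)
}

#' @rdname write_glcpn
#' @param n_diseases Frequency denominator recorded in the restored object.
#' @export
read_glcpn <- function(edges_path, nodes_path, n_diseases = NA_integer_) {
  edges <- read.delim(edges_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  nodes <- read_node_types(nodes_path)
  edges$a <- as.character(edges$a); edges$b <- as.character(edges$b)
  structure(list(nodes = nodes, edges = edges, n_diseases = n_diseases),
            class = "glcpn")
}
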
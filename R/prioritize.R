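#' Column-stochastic transition matrix of a weighted network
#'
#' Walks move *to* a node in proportion to the weights of its incident edges:
#' W\[u, v\] = weight(u, v) / sum_x weight(x, v). Columns of isolated nodes
#' are all zero and flagged in the `"dangling"` attribute; [rwr()] redirects
#' their outgoing mass to the restart vector so probability is conserved.
#'
#' @param net A `glcpn` (or any list with `nodes` and an `edges` data.frame
#'   carrying `a`, `b`, `weight`).
#' @return Sparse `dgCMatrix` with node ids as dimnames and a logical
#'   `"dangling"` attribute marking all-zero columns.
#' @export
transition_matrix <- function(net) {
  ids <- names(net$nodes)
  n <- length(ids)
  if (n == 0L) stop("network is empty")
  e <- net$edges
  if (any(e$weight <= 0) || any(e$weight > 1)) stop("edge weights must lie in (0,1]")
  ia <- match(e$a, ids); ib <- match(e$b, ids)
  if (anyNA(ia) || anyNA(ib)) stop("edge endpoint missing from node table")
  A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = c(e$weight, e$weight), dims = c(n, n),
                            dimnames = list(ids, ids))
  csum <- Matrix::colSums(A)
  dangling <- csum == 0
  inv <- ifelse(dangling, 0, 1 / csum)
  W <- A %*% Matrix::Diagonal(n, inv)
  W <- as(W, "CsparseMatrix")
  dimnames(W) <- list(ids, ids)
  attr(W, "dangling") <- dangling
  W
}

#' Random walk with restart
#'
#' Iterates p <- (1 - r) W p + r p0 from the uniform distribution over the
#' seed nodes until the L1 change drops below `tol`. Mass that would leave
#' through dangling (isolated) columns is redirected to the restart vector,
#' so the returned p always sums to 1. The converged p is the steady-state
#' proximity of every network node to the seed set.
#'
#' @param W Column-stochastic transition matrix from [transition_matrix()].
#' @param seeds Character vector of seed node ids (nonempty, all present in
#'   the network).
#' @param restart Restart probability r in (0,1). Default 0.7, the
#'   community-standard value for disease-gene walks.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return Named numeric score vector over all nodes, summing to 1.
#' @export
rwr <- function(W, seeds, restart = 0.7, tol = 1e-10, max_iter = 1000L) {
  ids <- rownames(W)
  if (length(seeds) == 0L) stop("no seeds for disease: empty seed set")
  if (restart <= 0 || restart >= 1) stop("restart must lie in (0,1)")
  miss <- setdiff(seeds, ids)
  if (length(miss)) stop("seed(s) not in network: ", paste(miss, collapse = ", "))
  dangling <- attr(W, "dangling")
  if (is.null(dangling)) dangling <- Matrix::colSums(W) == 0

  p0 <- numeric(length(ids))
  p0[match(unique(seeds), ids)] <- 1 / length(unique(seeds))
  p <- p0
  for (it in seq_len(max_iter)) {
    lost <- if (any(dangling)) sum(p[dangling]) else 0
    p_new <- as.numeric((1 - restart) * (W %*% p)) +
      (restart + (1 - restart) * lost) * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      names(p) <- ids
      return(p)
    }
  }
  stop(sprintf("rwr did not converge in %d iterations (residual %.3e)",
               max_iter, delta))
}

#' Pool per-disease prediction scores through phenotype similarity
#'
#' Computes the integrated prioritization score s_ik = sum_j P_ij s_jk,
#' i.e. the matrix product P S. The sum includes j = i, so a disease's own
#' prediction scores enter with weight P_ii = 1.
#'
#' @param S Disease-by-node matrix of prediction scores (rows in the same
#'   disease order as `P`).
#' @param P Symmetric disease similarity matrix.
#' @return Disease-by-node matrix of integrated scores.
#' @export
integrate_phenotype <- function(S, P) {
  if (nrow(P) != ncol(P)) stop("phenotype matrix must be square")
  if (nrow(S) != nrow(P))
    stop(sprintf("dimension mismatch: %d score rows vs %d diseases",
                 nrow(S), nrow(P)))
  if (!is.null(rownames(S)) && !is.null(rownames(P)) &&
      !identical(rownames(S), rownames(P)))
    stop("disease ordering of scores and phenotype matrix differs")
  out <- P %*% S
  dimnames(out) <- dimnames(S)
  out
}

#' Prioritize candidate disease lncRNAs and genes on a pan-cancer network
#'
#' The central fitting function. For every disease, the known disease genes
#' are used as the restart set of a random walk with restart over the
#' pan-cancer network, giving a prediction-score vector over all nodes
#' (genes and lncRNAs). The per-disease score rows are then pooled across
#' diseases through the phenotype similarity matrix
#' (s_ik = sum_j P_ij s_jk), so phenotypically similar diseases lend each
#' other evidence. Candidates are ranked by the integrated scores via
#' [predict.lncprior_fit()].
#'
#' @param network A `glcpn` from [build_glcpn()].
#' @param seeds Named list (disease id -> character vector of seed gene ids).
#'   Every disease in `phenotype` must have a nonempty seed set; seed ids
#'   absent from the network are dropped with a warning.
#' @param phenotype Symmetric disease similarity matrix with unit diagonal,
#'   disease ids as dimnames; its row order defines the disease order of the
#'   fit.
#' @param restart,tol,max_iter Passed to [rwr()].
#' @return Object of class `lncprior_fit` with elements `S` (prediction
#'   scores), `integrated` (phenotype-pooled scores), `P`, `seeds`, `network`,
#'   `W` (transition matrix) and `params`.
#' @examples
#' bench <- generate_benchmark(synthetic_spec(n_diseases = 2, n_genes = 60,
#'   n_lncrnas = 30, samples_per_disease = 30, disease_blocks = list(1:2)))
#' net <- build_glcpn(bench$expr, bench$node_types, bench$ppi)
#' fit <- lnc_prioritize(net, bench$seeds, bench$P)
#' head(predict(fit, disease = rownames(bench$P)[1], type = "lncRNA"))
#' @export
lnc_prioritize <- function(network, seeds, phenotype,
                           restart = 0.7, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(network, "glcpn"))
  P <- validate_phenotype(phenotype)
  diseases <- rownames(P)
  if (is.null(diseases)) stop("phenotype matrix needs disease ids as dimnames")
  miss <- setdiff(diseases, names(seeds))
  if (length(miss))
    stop("no seeds for disease: ", paste(miss, collapse = ", "))

  ids <- names(network$nodes)
  seeds <- lapply(setNames(diseases, diseases), function(d) {
    s <- unique(seeds[[d]])
    absent <- setdiff(s, ids)
    if (length(absent)) {
      warning(sprintf("disease %s: %d seed(s) absent from network dropped",
                      d, length(absent)))
      s <- setdiff(s, absent)
    }
    if (length(s) == 0L) stop("no seeds for disease: ", d)
    bad <- s[network$nodes[s] != "gene"]
    if (length(bad))
      stop("seed(s) are not gene-type nodes: ", paste(bad, collapse = ", "))
    s
  })

  W <- transition_matrix(network)
  S <- do.call(rbind, lapply(seeds, function(s)
    rwr(W, s, restart = restart, tol = tol, max_iter = max_iter)))
  rownames(S) <- diseases
  integrated <- integrate_phenotype(S, P)

  structure(list(S = S, integrated = integrated, P = P, seeds = seeds,
                 network = network, W = W,
                 params = list(restart = restart, tol = tol,
                               max_iter = max_iter)),
            class = "lncprior_fit")
}

#' Rank candidate nodes of one disease
#'
#' Nodes of the requested type, minus `exclude`, sorted by descending
#' integrated score; score ties are broken by lexicographic node id, so
#' rankings are deterministic across runs. By default all nodes of the type
#' are ranked — seed genes are only excluded during cross-validation.
#'
#' @param object An `lncprior_fit`.
#' @param disease Disease id to rank for.
#' @param type `"lncRNA"` (default) or `"gene"`.
#' @param exclude Node ids to drop from the ranking (e.g. seeds during LOOCV).
#' @param n Return only the top n rows (default all).
#' @param use Rank by `"integrated"` (default) or raw `"prediction"` scores.
#' @param ... Unused.
#' @return data.frame with columns rank, node_id, node_type, score.
#' @export
predict.lncprior_fit <- function(object, disease, type = c("lncRNA", "gene"),
                                 exclude = NULL, n = Inf,
                                 use = c("integrated", "prediction"), ...) {
  type <- match.arg(type)
  use <- match.arg(use)
  M <- if (use == "integrated") object$integrated else object$S
  if (!disease %in% rownames(M)) stop("unknown disease_id: ", disease)
  nodes <- names(object$network$nodes)[object$network$nodes == type]
  nodes <- setdiff(nodes, exclude)
  sc <- M[disease, nodes]
  o <- order(-sc, nodes)
  out <- data.frame(rank = seq_along(nodes), node_id = nodes[o],
                    node_type = type, score = unname(sc[o]),
                    stringsAsFactors = FALSE)
  head(out, n)
}

#' @rdname predict.lncprior_fit
#' @param fit An `lncprior_fit`.
#' @export
rank_candidates <- function(fit, disease, type = c("lncRNA", "gene"),
                            exclude = NULL, n = Inf) {
  predict(fit, disease = disease, type = type, exclude = exclude, n = n)
}

#' @export
print.lncprior_fit <- function(x, ...) {
  cat("Pan-cancer lncRNA prioritization fit\n")
  cat(sprintf("  diseases: %d  |  nodes: %d (%d genes, %d lncRNAs)\n",
              nrow(x$S), ncol(x$S),
              sum(x$network$nodes == "gene"),
              sum(x$network$nodes == "lncRNA")))
  cat(sprintf("  seeds per disease: %s\n",
              paste(sprintf("%s=%d", names(x$seeds), lengths(x$seeds)),
                    collapse = ", ")))
  cat(sprintf("  restart = %.2f, tol = %.1e\n",
              x$params$restart, x$params$tol))
  invisible(x)
}

#' Summarize a prioritization fit
#'
#' @param object An `lncprior_fit`.
#' @param n_top Top candidates listed per disease.
#' @param type Node type to summarize.
#' @param ... Unused.
#' @export
summary.lncprior_fit <- function(object, n_top = 5L, type = "lncRNA", ...) {
  top <- lapply(setNames(nm = rownames(object$S)), function(d)
    predict(object, d, type = type, n = n_top))
  structure(list(fit = object, top = top, type = type), class = "summary.lncprior_fit")
}

#' @export
print.summary.lncprior_fit <- function(x, ...) {
  print(x$fit)
  for (d in names(x$top)) {
    cat(sprintf("\nTop %s candidates, %s:\n", x$type, d))
    print(x$top[[d]], row.names = FALSE)
  }
  invisible(x)
}

#' Extract score matrices from a fit
#'
#' @param object An `lncprior_fit`.
#' @param type `"integrated"` (phenotype-pooled, default) or `"prediction"`
#'   (raw walk scores).
#' @param ... Unused.
#' @return Disease-by-node score matrix.
#' @export
coef.lncprior_fit <- function(object, type = c("integrated", "prediction"), ...) {
  type <- match.arg(type)
  if (type == "integrated") object$integrated else object$S
}

#' Plot top candidate scores for one disease
#'
#' @param x An `lncprior_fit`.
#' @param disease Disease id (default: first).
#' @param type Node type to plot.
#' @param n Number of top candidates shown.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.lncprior_fit <- function(x, disease = rownames(x$S)[1L],
                              type = "lncRNA", n = 20L, ...) {
  top <- predict(x, disease, type = type, n = n)
  graphics::barplot(rev(top$score), names.arg = rev(top$node_id), horiz = TRUE,
                    las = 1, xlab = "integrated score",
                    main = sprintf("%s: top %s candidates", disease, type), ...)
  invisible(top)
}
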
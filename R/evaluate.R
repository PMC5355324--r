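#' ROC curve and AUC by the rank (Mann-Whitney) statistic
#'
#' AUC = U / (n_pos * n_neg), where U counts score pairs in which a positive
#' outranks a negative, with ties counted 1/2 — the probability that a random
#' positive scores above a random negative. The curve is built by sweeping a
#' descending score threshold with tied scores grouped, so its trapezoidal
#' area equals the rank AUC exactly.
#'
#' @param scores Named numeric vector of node scores.
#' @param positives,negatives Disjoint, nonempty character vectors of node
#'   ids present in `scores`.
#' @param disease_id Optional label carried into the result.
#' @return Object of class `roc_result`: list with `disease_id`, `auc`,
#'   `curve` (data.frame fpr, tpr from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, positives, negatives, disease_id = NA_character_) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("positives and negatives must both be nonempty")
  if (length(intersect(positives, negatives)))
    stop("positives and negatives must be disjoint")
  miss <- setdiff(c(positives, negatives), names(scores))
  if (length(miss)) stop("unscored node(s): ", paste(miss, collapse = ", "))

  sp <- scores[positives]; sn <- scores[negatives]
  np <- length(sp); nn <- length(sn)
  r <- rank(c(sp, sn))                       # midranks handle ties as 1/2
  U <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  auc <- U / (np * nn)

  lab <- c(rep(1L, np), rep(0L, nn))
  sc <- c(sp, sn)
  o <- order(-sc)
  sc <- sc[o]; lab <- lab[o]
  grp <- cumsum(!duplicated(sc))             # tied scores form one threshold step
  tp <- cumsum(lab); fp <- cumsum(1L - lab)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np))

  structure(list(disease_id = disease_id, auc = auc, curve = curve,
                 n_pos = np, n_neg = nn), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC%s: AUC = %.4f (%d positives, %d negatives)\n",
              if (is.na(x$disease_id)) "" else paste0(" [", x$disease_id, "]"),
              x$auc, x$n_pos, x$n_neg), sep = "")
  invisible(x)
}

# negatives for a disease: all nodes of the type not in its positive list
default_negatives <- function(fit, type, positives) {
  setdiff(names(fit$network$nodes)[fit$network$nodes == type], positives)
}

#' Per-disease ROC evaluation of a prioritization fit
#'
#' For each disease with known positives, computes the ROC/AUC of the
#' integrated scores with negatives defaulting to every node of the type not
#' listed as positive for that disease.
#'
#' @param fit An `lncprior_fit`.
#' @param positives Named list (disease id -> positive node ids).
#' @param type Node type evaluated (`"lncRNA"` default).
#' @param scores Optional disease-by-node score matrix to evaluate instead of
#'   `coef(fit)` (used by the ablations).
#' @return List with per-disease `roc_result`s (`per_disease`) and the
#'   unweighted `mean_auc` across evaluated diseases.
#' @export
evaluate_roc <- function(fit, positives, type = "lncRNA", scores = NULL) {
  M <- if (is.null(scores)) fit$integrated else scores
  ds <- intersect(rownames(M), names(positives))
  if (length(ds) == 0L) stop("no disease with positives to evaluate")
  per <- lapply(setNames(nm = ds), function(d) {
    pos <- intersect(positives[[d]], names(fit$network$nodes))
    if (length(pos) == 0L) stop("positives absent from network for ", d)
    roc_auc(M[d, ], pos, default_negatives(fit, type, pos), disease_id = d)
  })
  list(per_disease = per,
       mean_auc = mean(vapply(per, `[[`, numeric(1), "auc")))
}

#' Leave-one-out cross-validation of gene prioritization
#'
#' Each known disease gene is withheld in turn from its disease's seed set,
#' the walk for that disease is honestly recomputed (other diseases' walks
#' are unchanged — their seeds did not change), scores are re-integrated
#' across all diseases, and the held-out gene's rank among all gene-type
#' non-seed candidates is recorded. The LOOCV AUC treats each held-out gene
#' as a positive against all genes never used as a seed for that disease,
#' scored within its own hold-out run (ties count 1/2).
#'
#' Diseases with fewer than two seeds cannot be cross-validated and are
#' skipped with a message.
#'
#' @param fit An `lncprior_fit`.
#' @param diseases Diseases to evaluate (default all).
#' @return List with `ranks` (data.frame disease_id, gene_id, rank,
#'   n_candidates), `auc` per disease, `mean_auc`, and `skipped`.
#' @export
loocv_genes <- function(fit, diseases = rownames(fit$S)) {
  ranks <- list(); aucs <- c(); skipped <- character(0)
  for (d in diseases) {
    seeds_d <- fit$seeds[[d]]
    if (length(seeds_d) < 2L) {
      message("loocv_genes: skipping ", d, " (fewer than 2 known disease genes)")
      skipped <- c(skipped, d)
      next
    }
    never_seed <- default_negatives(fit, "gene", seeds_d)
    per_gene <- numeric(0)
    for (g in seeds_d) {
      S2 <- fit$S
      S2[d, ] <- rwr(fit$W, setdiff(seeds_d, g),
                     restart = fit$params$restart, tol = fit$params$tol,
                     max_iter = fit$params$max_iter)
      integ <- integrate_phenotype(S2, fit$P)
      cand <- c(g, never_seed)               # gene nodes not currently seeds
      sc <- integ[d, cand]
      rk <- rank(-sc, ties.method = "average")[1L]
      ranks[[length(ranks) + 1L]] <-
        data.frame(disease_id = d, gene_id = g, rank = unname(rk),
                   n_candidates = length(cand), stringsAsFactors = FALSE)
      sg <- sc[1L]; sn <- sc[-1L]
      per_gene <- c(per_gene,
                    (sum(sn < sg) + 0.5 * sum(sn == sg)) / length(sn))
    }
    aucs[d] <- mean(per_gene)
  }
  if (length(aucs) == 0L) stop("no disease had >= 2 seeds; LOOCV impossible")
  list(ranks = do.call(rbind, ranks), auc = aucs, mean_auc = mean(aucs),
       skipped = skipped)
}

# shuffle the off-diagonal of P as symmetric pairs, diagonal fixed:
# permuted matrices remain valid similarity matrices
permute_phenotype <- function(P) {
  n <- nrow(P)
  ut <- which(upper.tri(P))
  v <- P[ut]
  v <- v[sample.int(length(v))]
  Q <- diag(n)
  Q[ut] <- v
  Q <- Q + t(Q) - diag(diag(Q))
  diag(Q) <- diag(P)
  dimnames(Q) <- dimnames(P)
  Q
}

#' Phenotype-similarity ablations: exclude or permute
#'
#' `mode = "exclude"` replaces the phenotype matrix by the identity — no
#' cross-disease pooling — and reports the resulting per-disease AUCs.
#' `mode = "permute"` shuffles the off-diagonal similarities jointly over
#' symmetric positions (diagonal fixed) `n_reps` times, re-integrates the
#' unchanged walk scores and reports the AUC distribution; degraded permuted
#' performance shows the phenotype associations carry real signal.
#'
#' @param fit An `lncprior_fit`.
#' @param positives Named list of known positive node ids per disease.
#' @param mode `"exclude"` or `"permute"`.
#' @param n_reps Permutation repetitions (permute mode).
#' @param rng_seed Integer seed making the permutations reproducible.
#' @param type Node type evaluated.
#' @return For `exclude`: as [evaluate_roc()]. For `permute`: list with
#'   `auc` (reps-by-disease matrix), `mean_auc` per rep, and `mean_mean_auc`.
#' @export
ablate_phenotype <- function(fit, positives, mode = c("exclude", "permute"),
                             n_reps = 100L, rng_seed = 1L, type = "lncRNA") {
  mode <- match.arg(mode)
  if (mode == "exclude") {
    I <- diag(nrow(fit$P)); dimnames(I) <- dimnames(fit$P)
    return(evaluate_roc(fit, positives, type = type,
                        scores = integrate_phenotype(fit$S, I)))
  }
  stopifnot(n_reps >= 1L)
  withr::with_seed(rng_seed, {
    reps <- lapply(seq_len(n_reps), function(i) {
      Q <- permute_phenotype(fit$P)
      ev <- evaluate_roc(fit, positives, type = type,
                         scores = integrate_phenotype(fit$S, Q))
      vapply(ev$per_disease, `[[`, numeric(1), "auc")
    })
  })
  auc <- do.call(rbind, reps)
  list(auc = auc, mean_auc = rowMeans(auc), mean_mean_auc = mean(auc))
}

#' Random non-disease-gene seed control
#'
#' Replaces every disease's seed set with an equal-size uniform draw from a
#' pool of non-disease genes, reruns the full walk + integration, and
#' compares the true mean AUC with the null distribution. The empirical
#' p-value uses the +1 correction: p = (#{null >= true} + 1) / (n_reps + 1).
#'
#' @param fit An `lncprior_fit`.
#' @param positives Known positives per disease.
#' @param pool Candidate non-disease gene ids; must be disjoint from all true
#'   seeds and at least as large as the biggest seed set.
#' @param n_reps Repetitions (default 1000).
#' @param rng_seed Integer seed.
#' @param type Node type evaluated.
#' @return List with `true_auc`, `null_auc` (length `n_reps`), `p_value`.
#' @export
random_seed_control <- function(fit, positives, pool, n_reps = 1000L,
                                rng_seed = 1L, type = "lncRNA") {
  all_seeds <- unique(unlist(fit$seeds))
  if (length(intersect(pool, all_seeds)))
    warning("pool overlaps the true seed sets; the null is conservative")
  if (length(pool) < max(lengths(fit$seeds)))
    stop("pool smaller than the largest seed set")
  pool <- intersect(pool, names(fit$network$nodes))
  if (!all(fit$network$nodes[pool] == "gene"))
    stop("pool must contain gene-type network nodes only")

  true_auc <- evaluate_roc(fit, positives, type = type)$mean_auc
  withr::with_seed(rng_seed, {
    null_auc <- vapply(seq_len(n_reps), function(i) {
      S2 <- do.call(rbind, lapply(rownames(fit$S), function(d) {
        rs <- sample(pool, length(fit$seeds[[d]]))
        rwr(fit$W, rs, restart = fit$params$restart, tol = fit$params$tol,
            max_iter = fit$params$max_iter)
      }))
      rownames(S2) <- rownames(fit$S)
      evaluate_roc(fit, positives, type = type,
                   scores = integrate_phenotype(S2, fit$P))$mean_auc
    }, numeric(1))
  })
  p <- (sum(null_auc >= true_auc) + 1) / (n_reps + 1)
  list(true_auc = true_auc, null_auc = null_auc, p_value = p)
}

#' Prioritization performance as a function of the number of diseases
#'
#' For each subset size, repeatedly samples a disease subset that always
#' contains the evaluated disease, restricts the phenotype matrix and the
#' walk-score rows to the subset, re-integrates, and records the evaluated
#' disease's AUC. Rising mean AUC with subset size shows that pooling more
#' phenotypically related diseases helps.
#'
#' @param fit An `lncprior_fit`.
#' @param positives Known positives per disease.
#' @param sizes Integer subset sizes (each between 1 and the disease count).
#' @param n_reps Repetitions per size and disease.
#' @param rng_seed Integer seed.
#' @param type Node type evaluated.
#' @return List with `mean_auc` (named by size) and `auc` (size -> reps-by-
#'   disease matrix).
#' @export
subset_diseases <- function(fit, positives, sizes, n_reps = 20L,
                            rng_seed = 1L, type = "lncRNA") {
  ds <- rownames(fit$S)
  N <- length(ds)
  if (any(sizes < 1L)) stop("subset size must be >= 1")
  if (any(sizes > N)) stop("subset size exceeds number of diseases")
  eval_ds <- intersect(ds, names(positives))

  withr::with_seed(rng_seed, {
    per_size <- lapply(setNames(nm = as.character(sizes)), function(sz) {
      sz <- as.integer(sz)
      do.call(rbind, lapply(seq_len(n_reps), function(i) {
        vapply(setNames(nm = eval_ds), function(d) {
          others <- setdiff(ds, d)
          sub <- c(d, if (sz > 1L) sample(others, sz - 1L))
          sub <- ds[ds %in% sub]            # keep canonical disease order
          integ <- integrate_phenotype(fit$S[sub, , drop = FALSE],
                                       fit$P[sub, sub, drop = FALSE])
          pos <- intersect(positives[[d]], names(fit$network$nodes))
          roc_auc(integ[d, ], pos, default_negatives(fit, type, pos))$auc
        }, numeric(1))
      }))
    })
  })
  list(mean_auc = vapply(per_size, mean, numeric(1)), auc = per_size)
}

#' Leave-disease-out prediction
#'
#' Scores one disease's candidates using only the other diseases' propagated
#' scores, weighted by phenotype similarity: s_ik = sum_{j != i} P_ij s_jk.
#' This is the prediction setting for a disease with no usable seed
#' information of its own.
#'
#' @param fit An `lncprior_fit`.
#' @param positives Known positives per disease.
#' @param disease Disease id to hold out.
#' @param type Node type evaluated.
#' @return A `roc_result` for the held-out disease.
#' @export
leave_disease_out <- function(fit, positives, disease, type = "lncRNA") {
  ds <- rownames(fit$S)
  if (!disease %in% ds) stop("unknown disease_id: ", disease)
  if (length(ds) < 2L) stop("leave-disease-out needs >= 2 diseases")
  others <- setdiff(ds, disease)
  w <- fit$P[disease, others]
  if (all(w == 0))
    warning("disease ", disease, " has zero similarity to all others; scores are all zero")
  s <- as.numeric(w %*% fit$S[others, , drop = FALSE])
  names(s) <- colnames(fit$S)
  pos <- intersect(positives[[disease]], names(fit$network$nodes))
  if (length(pos) == 0L) stop("no positives in network for ", disease)
  roc_auc(s, pos, default_negatives(fit, type, pos), disease_id = disease)
}
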
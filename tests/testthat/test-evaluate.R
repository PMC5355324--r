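test_that("roc_auc equals exhaustive pair counting with ties at one half", {
  sc <- c(p1 = 0.9, n1 = 0.8, p2 = 0.7, n2 = 0.1)
  r <- roc_auc(sc, c("p1", "p2"), c("n1", "n2"))
  expect_equal(r$auc, 0.75)   # 3 of 4 positive-over-negative pairs

  # perfect separation and all-tied scores
  sc2 <- c(a = 3, b = 2, c = 1, d = 0)
  expect_equal(roc_auc(sc2, c("a", "b"), c("c", "d"))$auc, 1)
  expect_equal(roc_auc(rep(1, 4) |> setNames(letters[1:4]),
                       c("a", "b"), c("c", "d"))$auc, 0.5)

  expect_error(roc_auc(sc, character(0), "n1"), "nonempty")
  expect_error(roc_auc(sc, c("p1", "n1"), c("n1", "n2")), "disjoint")
  expect_error(roc_auc(sc, "ghost", "n1"), "unscored")
})

test_that("the ROC curve runs from (0,0) to (1,1) with trapezoid area = AUC", {
  withr::with_seed(5, {
    for (i in 1:25) {
      n <- sample(5:40, 1)
      sc <- setNames(sample(seq(0, 1, 0.05), n, replace = TRUE),
                     sprintf("x%02d", 1:n))
      pos <- sample(names(sc), sample(2:(n - 2), 1))
      neg <- setdiff(names(sc), pos)
      r <- roc_auc(sc, pos, neg)
      expect_equal(r$auc, auc_pairs(sc, pos, neg))
      expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
      expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
      trap <- sum(diff(r$curve$fpr) *
                    (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
      expect_equal(trap, r$auc, tolerance = 1e-12)
    }
  })
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    for (i in 1:10) {
      sc <- setNames(round(runif(30), 2), sprintf("x%02d", 1:30))
      pos <- sample(names(sc), 10)
      neg <- setdiff(names(sc), pos)
      ref <- pROC::auc(pROC::roc(
        response = as.integer(names(sc) %in% pos), predictor = unname(sc),
        direction = "<", quiet = TRUE))
      expect_equal(roc_auc(sc, pos, neg)$auc, as.numeric(ref))
    }
  })
})

test_that("complementing scores complements the AUC when tie-free", {
  withr::with_seed(13, {
    sc <- setNames(runif(20), sprintf("x%02d", 1:20))
    pos <- sample(names(sc), 8)
    neg <- setdiff(names(sc), pos)
    expect_equal(roc_auc(sc, pos, neg)$auc + roc_auc(-sc, pos, neg)$auc, 1)
  })
})

test_that("LOOCV holds out each seed, recomputes honestly and skips tiny seed sets", {
  # g2 held out is the sole neighbor of the remaining seed g1 -> rank 1
  net <- make_glcpn(
    setNames(rep("gene", 4), c("g1", "g2", "g3", "g4")),
    data.frame(a = c("g1", "g3"), b = c("g2", "g4"), weight = c(1, 0.5)))
  P <- matrix(1, 1, 1, dimnames = list("d1", "d1"))
  fit <- lnc_prioritize(net, list(d1 = c("g1", "g2")), P)
  lo <- loocv_genes(fit)
  expect_identical(nrow(lo$ranks), 2L)       # one evaluation per seed
  expect_equal(lo$ranks$rank, c(1, 1))
  expect_equal(lo$mean_auc, 1)

  # fewer than two seeds: skipped with a message, error if nothing remains
  fit1 <- lnc_prioritize(net, list(d1 = "g1"), P)
  expect_message(expect_error(loocv_genes(fit1), "no disease"), "skipping")
})

test_that("LOOCV ranks match a per-gene direct-solve oracle on the benchmark", {
  fx <- small_fit()
  fit <- fx$fit
  d <- "D1"
  lo <- loocv_genes(fit, diseases = d)
  W <- fit$W
  never_seed <- setdiff(names(fit$network$nodes)[fit$network$nodes == "gene"],
                        fit$seeds[[d]])
  for (g in fit$seeds[[d]]) {
    S2 <- fit$S
    S2[d, ] <- rwr_direct(W, setdiff(fit$seeds[[d]], g), 0.7, normalize = TRUE)
    integ <- fit$P %*% S2
    sc <- integ[d, c(g, never_seed)]
    oracle_rank <- rank(-sc, ties.method = "average")[1]
    expect_equal(lo$ranks$rank[lo$ranks$gene_id == g], unname(oracle_rank),
                 tolerance = 1e-6)
  }
})

test_that("excluding the phenotype matrix equals no integration at all", {
  fx <- small_fit()
  excl <- ablate_phenotype(fx$fit, fx$bench$positives, mode = "exclude")
  raw <- evaluate_roc(fx$fit, fx$bench$positives, scores = fx$fit$S)
  expect_equal(excl$mean_auc, raw$mean_auc)
})

test_that("phenotype permutation preserves symmetry, diagonal, and is seed-reproducible", {
  fx <- small_fit()
  a <- ablate_phenotype(fx$fit, fx$bench$positives, mode = "permute",
                        n_reps = 5, rng_seed = 99)
  b <- ablate_phenotype(fx$fit, fx$bench$positives, mode = "permute",
                        n_reps = 5, rng_seed = 99)
  expect_identical(a, b)

  # a 2-disease matrix has one symmetric off-diagonal pair: permutation is
  # the identity and the AUC distribution is degenerate at the intact value
  bench2 <- generate_benchmark(synthetic_spec(
    n_diseases = 2, n_genes = 80, n_lncrnas = 40, samples_per_disease = 30,
    disease_blocks = list(1:2), module_size = 16, seeds_per_disease = 5,
    planted_lnc_per_disease = 6, ppi_background = 40, rng_seed = 3))
  net2 <- build_glcpn(bench2$expr, bench2$node_types, bench2$ppi)
  fit2 <- lnc_prioritize(net2, bench2$seeds, bench2$P)
  perm2 <- ablate_phenotype(fit2, bench2$positives, mode = "permute",
                            n_reps = 4, rng_seed = 1)
  intact2 <- evaluate_roc(fit2, bench2$positives)$mean_auc
  expect_true(all(abs(perm2$mean_auc - intact2) < 1e-12))
})

test_that("permuting an exchangeable similarity matrix reproduces the intact AUC", {
  fx <- small_fit()
  fit <- fx$fit
  Pflat <- matrix(0.4, nrow(fit$P), ncol(fit$P), dimnames = dimnames(fit$P))
  diag(Pflat) <- 1
  fit$P <- Pflat
  fit$integrated <- integrate_phenotype(fit$S, Pflat)
  intact <- evaluate_roc(fit, fx$bench$positives)$mean_auc
  perm <- ablate_phenotype(fit, fx$bench$positives, mode = "permute",
                           n_reps = 5, rng_seed = 2)
  expect_true(all(abs(perm$mean_auc - intact) < 1e-12))
})

test_that("random-seed control bounds its p-value and collapses on a seed-sized pool", {
  fx <- small_fit()
  fit <- fx$fit
  pool <- setdiff(names(fit$network$nodes)[fit$network$nodes == "gene"],
                  unique(unlist(fit$seeds)))
  rs <- random_seed_control(fit, fx$bench$positives, pool, n_reps = 10,
                            rng_seed = 4)
  expect_gte(rs$p_value, 1 / 11)
  expect_lte(rs$p_value, 1)
  rs2 <- random_seed_control(fit, fx$bench$positives, pool, n_reps = 10,
                             rng_seed = 4)
  expect_identical(rs, rs2)   # bit-reproducible given the seed

  # pool identical to one disease's seed set: every draw is the true set
  net <- make_glcpn(
    setNames(c(rep("gene", 3), "lncRNA", "lncRNA"),
             c("g1", "g2", "g3", "l1", "l2")),
    data.frame(a = c("g1", "g2"), b = c("g2", "l1"), weight = 1))
  P1 <- matrix(1, 1, 1, dimnames = list("d1", "d1"))
  f1 <- lnc_prioritize(net, list(d1 = c("g1", "g2")), P1)
  expect_warning(
    col <- random_seed_control(f1, list(d1 = "l1"), c("g1", "g2"),
                               n_reps = 5, rng_seed = 1),
    "overlaps")
  expect_true(all(col$null_auc == col$true_auc))

  expect_error(random_seed_control(f1, list(d1 = "l1"), "g3", n_reps = 2),
               "smaller")
})

test_that("disease-subset restriction degenerates correctly at the extremes", {
  fx <- small_fit()
  fit <- fx$fit
  N <- nrow(fit$S)
  full <- subset_diseases(fit, fx$bench$positives, sizes = N, n_reps = 2,
                          rng_seed = 1)
  intact <- evaluate_roc(fit, fx$bench$positives)$mean_auc
  expect_equal(unname(full$mean_auc), intact)

  one <- subset_diseases(fit, fx$bench$positives, sizes = 1, n_reps = 2,
                         rng_seed = 1)
  excl <- ablate_phenotype(fit, fx$bench$positives, mode = "exclude")
  expect_equal(unname(one$mean_auc), excl$mean_auc)

  expect_error(subset_diseases(fit, fx$bench$positives, sizes = 0), ">= 1")
  expect_error(subset_diseases(fit, fx$bench$positives, sizes = N + 1),
               "exceeds")
})

test_that("leave-disease-out uses only the other diseases' scores", {
  net <- make_glcpn(
    setNames(c(rep("gene", 2), rep("lncRNA", 2)), c("g1", "g2", "l1", "l2")),
    data.frame(a = c("g1", "g2"), b = c("l1", "l2"), weight = 1))
  mkP <- function(s) matrix(c(1, s, s, 1), 2,
                            dimnames = list(c("d1", "d2"), c("d1", "d2")))
  seeds <- list(d1 = "g1", d2 = "g2")
  pos <- list(d1 = "l1", d2 = "l2")

  # zero similarity: all-zero scores, warned
  f0 <- lnc_prioritize(net, seeds, mkP(0))
  expect_warning(r0 <- leave_disease_out(f0, pos, "d1"), "zero similarity")
  expect_equal(r0$auc, 0.5)   # all-tied zero scores

  # unit similarity: held-out scores equal the other disease's predictions
  f1 <- lnc_prioritize(net, seeds, mkP(1))
  r1 <- leave_disease_out(f1, pos, "d1")
  direct <- roc_auc(f1$S["d2", ], "l1", "l2")
  expect_equal(r1$auc, direct$auc)

  # benchmark: block partner carries real signal for the held-out disease
  fx <- small_fit()
  aucs <- vapply(rownames(fx$fit$S), function(d)
    leave_disease_out(fx$fit, fx$bench$positives, d)$auc, numeric(1))
  expect_true(all(aucs > 0.5))
})
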
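# shared fixtures and independent oracles, built in code

# hand-assembled pan-cancer network (bypasses construction code on purpose)
make_glcpn <- function(nodes, edges, n_diseases = 1L) {
  if (nrow(edges) && is.null(edges$n_coexpr)) edges$n_coexpr <- 0L
  if (nrow(edges) && is.null(edges$ppi_score)) edges$ppi_score <- NA_real_
  structure(list(nodes = nodes, edges = edges, n_diseases = n_diseases),
            class = "glcpn")
}

# direct linear-solve oracle for the restart walk:
# p = r (I - (1-r) W)^-1 p0  (exact when no column is dangling; with
# dangling columns the redistributed fixed point is this solution rescaled
# to unit mass, so normalize = TRUE extends the oracle to those graphs)
rwr_direct <- function(W, seeds, restart, normalize = FALSE) {
  Wd <- as.matrix(W)
  n <- nrow(Wd)
  p0 <- numeric(n); names(p0) <- rownames(Wd)
  p0[seeds] <- 1 / length(seeds)
  p <- restart * solve(diag(n) - (1 - restart) * Wd, p0)
  names(p) <- rownames(Wd)
  if (normalize) p / sum(p) else p
}

# exhaustive positive-over-negative pair enumeration (ties count 1/2)
auc_pairs <- function(scores, positives, negatives) {
  tot <- 0
  for (p in positives) for (n in negatives) {
    tot <- tot + (scores[[p]] > scores[[n]]) + 0.5 * (scores[[p]] == scores[[n]])
  }
  tot / (length(positives) * length(negatives))
}

# random connected-ish weighted graph: spanning path + extra random edges,
# so no node is isolated and the solve oracle applies
random_graph <- function(n_nodes, extra = n_nodes) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  path <- data.frame(a = ids[-n_nodes], b = ids[-1L], stringsAsFactors = FALSE)
  ai <- sample.int(n_nodes, extra, replace = TRUE)
  bi <- sample.int(n_nodes, extra, replace = TRUE)
  keep <- ai != bi
  e <- rbind(path, data.frame(a = ids[pmin(ai, bi)[keep]],
                              b = ids[pmax(ai, bi)[keep]]))
  e <- unique(e)
  e$weight <- runif(nrow(e), 0.05, 1)
  make_glcpn(setNames(rep("gene", n_nodes), ids), e)
}

# features with exact pairwise correlation: b = rho * z(a) + sqrt(1-rho^2) * z(e),
# e orthogonalized against a, both standardized
make_corr_feature <- function(a, rho, e = seq_along(a)^2) {
  za <- as.numeric(scale(a))
  e <- e - mean(e)
  e <- e - sum(e * za) / sum(za * za) * za
  ze <- e / sqrt(sum(e^2) / (length(e) - 1))
  rho * za + sqrt(1 - rho^2) * ze
}

# small, fast benchmark for module-level tests (not the acceptance benchmark)
small_bench <- function(rng_seed = 7L) {
  generate_benchmark(synthetic_spec(
    n_diseases = 4L, n_genes = 120L, n_lncrnas = 60L,
    samples_per_disease = 40L, n_modules = 2L, module_size = 16L,
    disease_blocks = list(1:2, 3:4), seeds_per_disease = 5L,
    planted_lnc_per_disease = 6L, ppi_background = 60L, rng_seed = rng_seed))
}

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bench <- small_bench()
      net <- build_glcpn(bench$expr, bench$node_types, bench$ppi)
      cache <<- list(bench = bench,
                     fit = lnc_prioritize(net, bench$seeds, bench$P))
    }
    cache
  }
})
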
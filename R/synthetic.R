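#' Specification of the synthetic pan-cancer benchmark
#'
#' Describes a fully synthetic multi-disease study with planted structure:
#' diseases fall into phenotype-similarity blocks; each block owns
#' `n_modules` co-expression modules whose members (seed genes, "true risk"
#' lncRNAs and filler genes) are driven by a shared latent factor,
#' x = sqrt(rho) z + sqrt(1 - rho) eps, giving expected pairwise correlation
#' rho = `within_module_corr`. Within a block, each disease's seed genes are
#' drawn from a *different* module while its true positives span all the
#' block's modules, so pooling scores across phenotypically similar diseases
#' is genuinely informative — exactly the mechanism the prioritization method
#' relies on. Everything outside the modules is independent Gaussian noise.
#'
#' @param n_diseases Number of disease types.
#' @param n_genes,n_lncrnas Feature counts.
#' @param samples_per_disease Samples per disease expression matrix.
#' @param n_modules Planted modules per disease block.
#' @param module_size Members per module (genes + lncRNAs).
#' @param within_module_corr Expected pairwise correlation rho inside a
#'   module, in (0,1).
#' @param noise_sd Standard deviation of background features.
#' @param disease_blocks Partition of `1:n_diseases` into similarity blocks
#'   (list of integer vectors).
#' @param within_block_sim,between_block_sim Phenotype similarity inside /
#'   across blocks, in \[0,1\].
#' @param seeds_per_disease Known disease genes per disease.
#' @param planted_lnc_per_disease True risk lncRNAs per disease (split evenly
#'   over the block's modules).
#' @param ppi_module_frac Fraction of same-module gene pairs given a
#'   high-confidence PPI edge (score ~ U(0.7, 1)).
#' @param ppi_background Number of random background gene pairs given a
#'   low-confidence PPI edge (score ~ U(0.1, 0.4)), exercising the merge-max
#'   rule.
#' @param rng_seed Integer seed; all generated output is byte-reproducible
#'   given it.
#' @return Object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_diseases = 6L, n_genes = 500L, n_lncrnas = 200L,
                           samples_per_disease = 60L, n_modules = 2L,
                           module_size = 30L, within_module_corr = 0.9,
                           noise_sd = 1,
                           disease_blocks = list(1:2, 3:4, 5:6),
                           within_block_sim = 0.8, between_block_sim = 0.2,
                           seeds_per_disease = 10L,
                           planted_lnc_per_disease = 12L,
                           ppi_module_frac = 0.3, ppi_background = 200L,
                           rng_seed = 42L) {
  spec <- list(n_diseases = as.integer(n_diseases), n_genes = as.integer(n_genes),
               n_lncrnas = as.integer(n_lncrnas),
               samples_per_disease = as.integer(samples_per_disease),
               n_modules = as.integer(n_modules), module_size = as.integer(module_size),
               within_module_corr = within_module_corr, noise_sd = noise_sd,
               disease_blocks = lapply(disease_blocks, as.integer),
               within_block_sim = within_block_sim,
               between_block_sim = between_block_sim,
               seeds_per_disease = as.integer(seeds_per_disease),
               planted_lnc_per_disease = as.integer(planted_lnc_per_disease),
               ppi_module_frac = ppi_module_frac,
               ppi_background = as.integer(ppi_background),
               rng_seed = as.integer(rng_seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(s) {
  with(s, {
    if (!identical(sort(unlist(disease_blocks)), seq_len(n_diseases)))
      stop("disease_blocks must partition 1:n_diseases")
    if (within_module_corr < 0 || within_module_corr > 1)
      stop("within_module_corr must lie in [0,1]")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (module_size < seeds_per_disease + planted_lnc_per_disease)
      stop("module_size must be >= seeds_per_disease + planted_lnc_per_disease")
    if (planted_lnc_per_disease %% n_modules != 0L)
      stop("planted_lnc_per_disease must be divisible by n_modules")
    lnc_per_module <- planted_lnc_per_disease %/% n_modules
    genes_per_module <- module_size - lnc_per_module
    n_blocks <- length(disease_blocks)
    if (n_blocks * n_modules * genes_per_module > n_genes)
      stop("not enough genes for the requested modules")
    if (n_blocks * n_modules * lnc_per_module > n_lncrnas)
      stop("not enough lncRNAs for the requested modules")
    if (seeds_per_disease > genes_per_module)
      stop("seeds_per_disease exceeds genes per module")
    if (within_block_sim < 0 || within_block_sim > 1 ||
        between_block_sim < 0 || between_block_sim > 1)
      stop("block similarities must lie in [0,1]")
    if (ppi_module_frac < 0 || ppi_module_frac > 1)
      stop("ppi_module_frac must lie in [0,1]")
  })
  invisible(s)
}

feature_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Generate the synthetic pan-cancer benchmark
#'
#' Emits, from a [synthetic_spec()], everything the pipeline consumes:
#' per-disease expression matrices, node types, a PPI edge list, per-disease
#' seed genes, the block-structured phenotype similarity matrix, the
#' ground-truth positive lncRNA lists, and a truth manifest echoing the
#' planted structure. All randomness flows from `spec$rng_seed`; two calls
#' with the same spec produce identical output.
#'
#' @param spec A `synthetic_spec`.
#' @return List with elements `expr` (named list of feature-by-sample
#'   matrices), `node_types`, `ppi`, `seeds`, `P`, `positives`, `truth`.
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  s <- spec
  gene_ids <- feature_ids("g", s$n_genes)
  lnc_ids <- feature_ids("l", s$n_lncrnas)
  ids <- c(gene_ids, lnc_ids)
  node_types <- setNames(rep(c("gene", "lncRNA"), c(s$n_genes, s$n_lncrnas)), ids)
  diseases <- sprintf("D%d", seq_len(s$n_diseases))
  n_blocks <- length(s$disease_blocks)
  lnc_per_module <- s$planted_lnc_per_disease %/% s$n_modules
  genes_per_module <- s$module_size - lnc_per_module

  # deterministic module membership: consecutive id ranges per block/module
  modules <- list(); gi <- 0L; li <- 0L
  for (b in seq_len(n_blocks)) for (m in seq_len(s$n_modules)) {
    modules[[length(modules) + 1L]] <- list(
      block = b, module = m,
      genes = gene_ids[gi + seq_len(genes_per_module)],
      lncrnas = lnc_ids[li + seq_len(lnc_per_module)])
    gi <- gi + genes_per_module; li <- li + lnc_per_module
  }
  block_modules <- split(seq_along(modules),
                         vapply(modules, `[[`, integer(1), "block"))

  withr::with_seed(s$rng_seed, {
    expr <- list()
    for (di in seq_len(s$n_diseases)) {
      d <- diseases[di]
      b <- which(vapply(s$disease_blocks, function(bl) di %in% bl, logical(1)))
      m <- matrix(rnorm(length(ids) * s$samples_per_disease, sd = s$noise_sd),
                  nrow = length(ids), dimnames = list(
                    ids, sprintf("%s_S%02d", d, seq_len(s$samples_per_disease))))
      for (mi in block_modules[[as.character(b)]]) {
        mod <- modules[[mi]]
        members <- c(mod$genes, mod$lncrnas)
        z <- rnorm(s$samples_per_disease)
        eps <- matrix(rnorm(length(members) * s$samples_per_disease),
                      nrow = length(members))
        m[members, ] <- sqrt(s$within_module_corr) * rep(z, each = length(members)) +
          sqrt(1 - s$within_module_corr) * eps
      }
      expr[[d]] <- m
    }

    # seeds: disease k of its block draws from the block's ((k-1) mod n_modules)+1 -th module
    seeds <- list()
    for (di in seq_len(s$n_diseases)) {
      b <- which(vapply(s$disease_blocks, function(bl) di %in% bl, logical(1)))
      pos_in_block <- match(di, s$disease_blocks[[b]])
      mi <- block_modules[[as.character(b)]][(pos_in_block - 1L) %% s$n_modules + 1L]
      seeds[[diseases[di]]] <- sort(sample(modules[[mi]]$genes, s$seeds_per_disease))
    }

    # positives: all lncRNAs planted in the disease's block
    positives <- list()
    for (di in seq_len(s$n_diseases)) {
      b <- which(vapply(s$disease_blocks, function(bl) di %in% bl, logical(1)))
      positives[[diseases[di]]] <-
        sort(unlist(lapply(modules[block_modules[[as.character(b)]]], `[[`, "lncrnas")))
    }

    # PPI: high-confidence same-module gene pairs + low-confidence background
    ppi <- list()
    for (mod in modules) {
      prs <- utils::combn(mod$genes, 2L)
      k <- as.integer(round(s$ppi_module_frac * ncol(prs)))
      if (k == 0L) next
      pick <- sort(sample.int(ncol(prs), k))
      ppi[[length(ppi) + 1L]] <- data.frame(
        a = prs[1L, pick], b = prs[2L, pick],
        score = runif(k, 0.7, 1), stringsAsFactors = FALSE)
    }
    if (s$ppi_background > 0L) {
      a <- sample(gene_ids, s$ppi_background, replace = TRUE)
      b <- sample(gene_ids, s$ppi_background, replace = TRUE)
      keep <- a != b
      ppi[[length(ppi) + 1L]] <- data.frame(
        a = a[keep], b = b[keep],
        score = runif(sum(keep), 0.1, 0.4), stringsAsFactors = FALSE)
    }
    ppi <- do.call(rbind, ppi)
  })

  # block-structured phenotype similarity, unit diagonal
  block_of <- integer(s$n_diseases)
  for (b in seq_len(n_blocks)) block_of[s$disease_blocks[[b]]] <- b
  P <- matrix(s$between_block_sim, s$n_diseases, s$n_diseases,
              dimnames = list(diseases, diseases))
  P[outer(block_of, block_of, "==")] <- s$within_block_sim
  diag(P) <- 1

  truth <- list(
    spec = unclass(s),
    diseases = diseases,
    modules = lapply(modules, function(m)
      list(block = m$block, module = m$module, genes = m$genes,
           lncrnas = m$lncrnas)),
    seeds = seeds,
    positives = positives)

  list(expr = expr, node_types = node_types, ppi = ppi, seeds = seeds,
       P = P, positives = positives, truth = truth)
}

#' Write a generated benchmark to a directory
#'
#' Emits exactly the file formats the pipeline stages consume: one
#' expression TSV per disease under `expr/`, `node_types.tsv`, `ppi.tsv`,
#' `seeds.tsv`, `phenotype.tsv`, `positives.tsv` and `truth.json`.
#'
#' @param bench Output of [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(file.path(dir, "expr"), recursive = TRUE, showWarnings = FALSE)
  for (d in names(bench$expr))
    write_expression_tsv(bench$expr[[d]], file.path(dir, "expr", paste0(d, ".tsv")))
  write_node_types(bench$node_types, file.path(dir, "node_types.tsv"))
  write.table(bench$ppi, file.path(dir, "ppi.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_seeds_tsv(bench$seeds, file.path(dir, "seeds.tsv"))
  write_phenotype_tsv(bench$P, file.path(dir, "phenotype.tsv"))
  write_seeds_tsv(bench$positives, file.path(dir, "positives.tsv"))
  write_truth(bench$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Write / read the ground-truth manifest
#'
#' The manifest records the planted structure (spec echo, module membership,
#' seeds, positives) as JSON; write -> read is the identity on this
#' structure, and reading validates the schema, naming any missing field.
#'
#' @param truth Truth list from [generate_benchmark()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
  for (f in c("spec", "diseases", "modules", "seeds", "positives"))
    if (is.null(truth[[f]])) stop("truth manifest missing field: ", f)
  for (f in c("n_diseases", "rng_seed", "within_module_corr"))
    if (is.null(truth$spec[[f]])) stop("truth manifest missing field: spec$", f)
  truth$spec$disease_blocks <- lapply(truth$spec$disease_blocks, as.integer)
  truth$seeds <- lapply(truth$seeds, as.character)
  truth$positives <- lapply(truth$positives, as.character)
  truth
}
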
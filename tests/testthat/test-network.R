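test_that("co-expression edges respect per-kind thresholds strictly", {
  a <- c(1, 2, 3, 4, 2, 6)
  vals <- rbind(gA = a,
                gB = make_corr_feature(a, 0.85),
                gC = make_corr_feature(a, 0.75),
                lA = make_corr_feature(a, 0.75),
                lB = make_corr_feature(a, 0.65))
  types <- c(gA = "gene", gB = "gene", gC = "gene", lA = "lncRNA", lB = "lncRNA")
  # sanity: constructed correlations are exact
  expect_equal(cor(vals["gA", ], vals["gB", ]), 0.85)

  es <- compute_coexpression(vals, types, "d1")
  key <- paste(es$edges$a, es$edges$b)
  expect_true("gA gB" %in% key)       # gene-gene 0.85 > 0.8
  expect_false("gA gC" %in% key)      # gene-gene 0.75 <= 0.8 dropped
  expect_true("gA lA" %in% key)       # gene-lncRNA 0.75 > 0.7
  expect_false("gA lB" %in% key)      # gene-lncRNA 0.65 <= 0.7
  expect_false(any(es$edges$a == es$edges$b))              # no self loops
  lnc <- names(types)[types == "lncRNA"]
  expect_false(any(es$edges$a %in% lnc & es$edges$b %in% lnc))  # no lnc-lnc
})

test_that("perfect linear dependence always passes; signed mode drops anticorrelation", {
  vals <- rbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8), z = -c(1, 2, 3, 4))
  types <- c(x = "gene", y = "gene", z = "gene")
  es <- compute_coexpression(vals, types, "d1")
  key <- paste(es$edges$a, es$edges$b)
  expect_setequal(key, c("x y", "x z", "y z"))   # |r| = 1 everywhere
  es2 <- compute_coexpression(vals, types, "d1", signed = TRUE)
  expect_setequal(paste(es2$edges$a, es2$edges$b), "x y")
})

test_that("zero-variance features are skipped with a warning", {
  vals <- rbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8), flat = c(5, 5, 5, 5))
  types <- c(x = "gene", y = "gene", flat = "gene")
  expect_warning(es <- compute_coexpression(vals, types, "d1"), "zero-variance")
  expect_false("flat" %in% c(es$edges$a, es$edges$b))
  expect_true("flat" %in% names(es$node_types))  # node survives as isolated
})

test_that("edges are independent of the correlation block size", {
  withr::with_seed(3, {
    vals <- matrix(rnorm(30 * 10), 30, 10,
                   dimnames = list(sprintf("f%02d", 1:30), NULL))
    types <- setNames(rep(c("gene", "lncRNA"), c(20, 10)), rownames(vals))
    ref <- compute_coexpression(vals, types, "d", gg_threshold = 0.5,
                                gl_threshold = 0.4)
    for (bs in c(1L, 7L, 1000L)) {
      got <- compute_coexpression(vals, types, "d", gg_threshold = 0.5,
                                  gl_threshold = 0.4, block_size = bs)
      expect_identical(got$edges, ref$edges)
    }
  })
})

test_that("pan-cancer integration weights edges by disease frequency", {
  mk <- function(d, pairs) structure(
    list(disease_id = d,
         edges = data.frame(a = pairs[[1]], b = pairs[[2]],
                            stringsAsFactors = FALSE),
         node_types = c(A = "gene", B = "gene", C = "gene", L = "lncRNA")),
    class = "coexpression_edges")
  sets <- list(mk("d1", list(c("A", "A"), c("B", "L"))),
               mk("d2", list("A", "B")),
               mk("d3", list(c("A", "B"), c("B", "C"))),
               mk("d4", list("B", "C")))
  net <- integrate_pan_cancer(sets)
  e <- net$edges
  expect_equal(e$weight[e$a == "A" & e$b == "B"], 3 / 4)
  expect_equal(e$weight[e$a == "B" & e$b == "C"], 2 / 4)
  expect_equal(e$weight[e$a == "A" & e$b == "L"], 1 / 4)
  expect_equal(e$n_coexpr, as.integer(e$weight * 4))
  expect_true(all(e$weight %in% ((1:4) / 4)))

  # single disease: all weights 1, network equals that edge set
  net1 <- integrate_pan_cancer(sets[1])
  expect_true(all(net1$edges$weight == 1))
  expect_setequal(paste(net1$edges$a, net1$edges$b), c("A B", "A L"))

  expect_error(integrate_pan_cancer(list(sets[[1]], sets[[1]])), "duplicate")
})

test_that("PPI merge adds edges, takes the max for shared pairs, never weakens", {
  nodes <- c(A = "gene", B = "gene", C = "gene", D = "gene")
  net <- make_glcpn(nodes, data.frame(
    a = c("A", "A"), b = c("B", "C"), weight = c(0.5, 0.5),
    n_coexpr = c(2L, 2L), ppi_score = NA_real_), n_diseases = 4L)
  ppi <- data.frame(a = c("A", "A", "C"), b = c("B", "C", "D"),
                    score = c(0.9, 0.2, 0.9))
  got <- merge_ppi(net, ppi)
  e <- got$edges
  expect_equal(e$weight[e$a == "A" & e$b == "B"], 0.9)  # ppi wins
  expect_equal(e$weight[e$a == "A" & e$b == "C"], 0.5)  # coexpression wins
  expect_equal(e$weight[e$a == "C" & e$b == "D"], 0.9)  # ppi-only edge added
  expect_equal(e$ppi_score[e$a == "A" & e$b == "C"], 0.2)  # provenance kept
  expect_equal(e$n_coexpr[e$a == "C" & e$b == "D"], 0L)

  # weights never drop, edges never disappear
  old_key <- paste(net$edges$a, net$edges$b)
  new_key <- paste(e$a, e$b)
  expect_true(all(old_key %in% new_key))
  expect_true(all(e$weight[match(old_key, new_key)] >= net$edges$weight))

  expect_error(merge_ppi(net, data.frame(a = "A", b = "D", score = 1.2)),
               "\\[0,1\\]")
})

test_that("full construction matches an exhaustive pair-by-pair oracle on a toy", {
  # 5 nodes, 2 diseases, hand-built expression
  withr::with_seed(11, {
    ids <- c("g1", "g2", "g3", "l1", "l2")
    types <- setNames(c("gene", "gene", "gene", "lncRNA", "lncRNA"), ids)
    expr <- lapply(c(d1 = 1, d2 = 2), function(i) {
      m <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(ids, NULL))
      m["g2", ] <- make_corr_feature(m["g1", ], 0.95)   # strong gene-gene
      m["l1", ] <- make_corr_feature(m["g3", ], 0.85)   # strong gene-lnc
      m
    })
    ppi <- data.frame(a = c("g1", "g2"), b = c("g3", "g3"), score = c(0.95, 0.3))
    net <- build_glcpn(expr, types, ppi)

    # oracle: enumerate every pair in every disease, then integrate by hand
    freq <- new.env()
    for (d in names(expr)) {
      for (i in 1:4) for (j in (i + 1):5) {
        ti <- types[ids[i]]; tj <- types[ids[j]]
        if (ti == "lncRNA" && tj == "lncRNA") next
        thr <- if (ti == "gene" && tj == "gene") 0.8 else 0.7
        if (abs(cor(expr[[d]][ids[i], ], expr[[d]][ids[j], ])) > thr) {
          k <- paste(ids[i], ids[j])
          freq[[k]] <- (if (is.null(freq[[k]])) 0 else freq[[k]]) + 1
        }
      }
    }
    expected <- new.env()
    for (k in ls(freq)) expected[[k]] <- freq[[k]] / 2
    for (r in seq_len(nrow(ppi))) {
      k <- paste(ppi$a[r], ppi$b[r])
      expected[[k]] <- max(if (is.null(expected[[k]])) 0 else expected[[k]],
                           ppi$score[r])
    }
    got <- setNames(net$edges$weight, paste(net$edges$a, net$edges$b))
    expect_setequal(names(got), ls(expected))
    for (k in ls(expected)) expect_equal(got[[k]], expected[[k]])
  })
})

test_that("networks round-trip through edge-list and node-type TSVs", {
  fx <- small_fit()
  net <- fx$fit$network
  dir <- withr::local_tempdir()
  write_glcpn(net, file.path(dir, "e.tsv"), file.path(dir, "n.tsv"))
  back <- read_glcpn(file.path(dir, "e.tsv"), file.path(dir, "n.tsv"),
                     n_diseases = net$n_diseases)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
})
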
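make_tm <- function(mat, conditions) {
  cm <- toy_counts(mat, condition = conditions)
  transform_counts(cm, size_factors = rep(1, ncol(mat)))
}

test_that("gene scores are condition-mean contrasts with a flat-gene rule", {
  conds <- rep(c("control", "stimulus"), each = 3)
  base <- matrix(2L, 4, 6, dimnames = list(paste0("g", 1:4), NULL))
  shifted <- base
  shifted[, 4:6] <- 6L                 # same shift for every gene
  x_rna <- make_tm(shifted, conds)
  x_rip <- make_tm(shifted, conds)
  sc <- gene_scores(x_rna, x_rip, c("control", "stimulus"))
  expect_true(all(sc$rna_z > 0))
  expect_equal(length(unique(round(sc$rna_z, 12))), 1)  # all equal

  # a gene identical across all samples scores (0, 0) and is flagged
  flat <- shifted
  flat[2, ] <- 3L
  sc2 <- gene_scores(make_tm(flat, conds), make_tm(flat, conds),
                     c("control", "stimulus"))
  expect_equal(sc2$rna_z[2], 0)
  expect_equal(sc2$rip_z[2], 0)
  expect_true(sc2$rna_flat[2] && sc2$rip_flat[2])
})

test_that("score signs track the true induction direction", {
  exp <- cached_experiment(seed = 101)
  an <- run_coupling_analysis(exp)
  resp <- exp$truth$responsive
  agree <- sign(an$pairs_lps$rna_z[resp]) == sign(exp$truth$beta[resp])
  expect_gte(mean(agree), 0.9)
})

test_that("coupling correlation matches exact cases and guards input", {
  pairs <- data.frame(gene = paste0("g", 1:5), rna_z = 1:5, rip_z = 2 * (1:5))
  expect_equal(coupling_correlation(pairs)$r, 1)
  pairs$rip_z <- -pairs$rna_z
  expect_equal(coupling_correlation(pairs)$r, -1)
  expect_equal(coupling_correlation(pairs)$n, 5)
  expect_error(coupling_correlation(pairs, subset = c("g1", "g2")), ">= 3")
  pairs$rip_z <- 1
  expect_error(coupling_correlation(pairs), "zero variance")
})

test_that("the hand-enumerated 10-gene cascade yields sizes (6, 5, 4, 2)", {
  genes <- paste0("g", 1:10)
  # rna up (padj<.05 & lfc>1): lps g1..g7 minus g7 (padj); drug g1..g6 minus g6
  rna_lps <- toy_diff(genes, lfc = c(2, 2, 2, 2, 2, 2, 2, 0.5, -2, 0),
                      padj = c(rep(0.01, 6), 0.2, 0.01, 0.01, 0.9))
  rip_lps <- toy_diff(genes, lfc = c(4, 4, 4, 4, 4, 4, 4, 4, 4, 2),
                      padj = rep(0.01, 10))
  # S_lps = g1..g6 (g7 fails rna padj)                       -> 6
  rna_drug <- toy_diff(genes, lfc = c(2, 2, 2, 2, 2, 0.2, 2, 2, 2, 2),
                       padj = rep(0.01, 10))
  rip_drug <- toy_diff(genes, lfc = c(4, 4, 4, 4, 4, 4, 4, 2, 2, 4),
                       padj = c(rep(0.01, 4), 0.3, rep(0.01, 4), 0.3))
  # S_drug = {g1..g4, g7} (g5 fails rip padj, g6 fails rna)  -> 5
  # S_common = {g1..g4}                                      -> 4
  rip_dvl <- toy_diff(genes, lfc = c(-2, -2, 2, -2, -2, -2, -2, -2, -2, -2),
                      padj = c(0.01, 0.01, 0.01, 0.2, rep(0.01, 6)))
  # displaced within common: g1, g2 (g3 lfc>0, g4 padj)      -> 2
  res <- cascade_filter(rna_lps, rna_drug, rip_lps, rip_drug, rip_dvl)
  expect_identical(unname(res$sizes), c(6L, 5L, 4L, 2L))
  expect_setequal(res$sets$S_displaced, c("g1", "g2"))
})

test_that("cascade sets obey the subset algebra on random inputs", {
  set.seed(8)
  genes <- paste0("g", 1:80)
  rand_tab <- function() toy_diff(genes, lfc = rnorm(80, 1, 2),
                                  padj = runif(80))
  for (i in 1:10) {
    res <- cascade_filter(rand_tab(), rand_tab(), rand_tab(), rand_tab(),
                          rand_tab())
    expect_true(all(res$sets$S_common %in% res$sets$S_lps))
    expect_true(all(res$sets$S_common %in% res$sets$S_drug))
    expect_true(all(res$sets$S_displaced %in% res$sets$S_common))
  }
})

test_that("the cascade is insensitive to row order and idempotent", {
  set.seed(9)
  genes <- paste0("g", 1:40)
  tabs <- replicate(5, toy_diff(genes, rnorm(40, 1, 2), runif(40)),
                    simplify = FALSE)
  res1 <- do.call(cascade_filter, tabs)
  shuf <- lapply(tabs, function(t) t[sample(nrow(t)), ])
  res2 <- do.call(cascade_filter, shuf)
  expect_identical(res1$sets, res2$sets)
  res3 <- do.call(cascade_filter, tabs)
  expect_identical(res1$sets, res3$sets)

  tabs[[3]] <- toy_diff(paste0("h", 1:40), rnorm(40), runif(40))
  expect_error(do.call(cascade_filter, tabs), "symmetric difference")
})

test_that("empty significance gives empty sets and absent correlations", {
  genes <- paste0("g", 1:10)
  ns <- toy_diff(genes, lfc = rep(0, 10), padj = rep(1, 10))
  pairs <- data.frame(gene = genes, rna_z = rnorm(10), rip_z = rnorm(10))
  res <- cascade_filter(ns, ns, ns, ns, ns, pairs_lps = pairs,
                        pairs_drug = pairs)
  expect_true(all(res$sizes == 0))
  expect_true(is.na(res$r_lps$r))
  expect_identical(res$r_lps$n, 0L)
})

test_that("overlap regions partition the union", {
  ov <- set_overlaps(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(unname(ov[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  expect_equal(sum(ov), 3L)

  dis <- set_overlaps(list(A = c("a", "b"), B = c("c")))
  expect_equal(unname(dis["A&B"]), 0L)

  same <- set_overlaps(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(unname(same["A&B"]), 2L)
  expect_equal(sum(same), 2L)

  three <- set_overlaps(list(A = c("1", "2"), B = c("2", "3"), C = c("2")))
  expect_equal(unname(three["A&B&C"]), 1L)
  expect_equal(sum(three), 3L)
  expect_error(set_overlaps(list(1:2, 1:2, 1:2, 1:2)), "2 or 3")
})

test_that("density differences vanish for identical scatters and negate on swap", {
  set.seed(10)
  pa <- data.frame(gene = paste0("g", 1:200),
                   rna_z = rnorm(200), rip_z = rnorm(200))
  pb <- data.frame(gene = paste0("h", 1:200),
                   rna_z = rnorm(200, 1), rip_z = rnorm(200, -0.5))
  same <- density_difference(pa, pa, grid_n = 32)
  expect_true(all(same$difference == 0))

  ab <- density_difference(pa, pb, grid_n = 32)
  ba <- density_difference(pb, pa, grid_n = 32)
  expect_equal(ab$difference, -ba$difference, tolerance = 1e-12)

  # each density integrates to 1 over the grid (trapezoid rule)
  gx <- unique(ab$grid$x); gy <- unique(ab$grid$y)
  wx <- c(diff(gx), 0) / 2 + c(0, diff(gx)) / 2
  wy <- c(diff(gy), 0) / 2 + c(0, diff(gy)) / 2
  w <- as.vector(outer(wx, wy))
  expect_equal(sum(w * ab$density_a), 1, tolerance = 1e-6)
  expect_equal(sum(w * ab$density_b), 1, tolerance = 1e-6)

  # triangulation covers the grid: 2 (n-1)^2 triangles, indices in range
  expect_equal(nrow(ab$triangles), 2 * 31^2)
  expect_true(all(ab$triangles >= 1 & ab$triangles <= 32^2))

  expect_error(density_difference(pa[1:5, ], pb), ">= 10")
  col <- data.frame(gene = paste0("c", 1:20), rna_z = 1:20, rip_z = 2 * (1:20))
  expect_error(density_difference(col, pb), "collinear")
})

test_that("over-representation p-values are hypergeometric", {
  universe <- paste0("g", 1:20)
  coll <- structure(list(inflam = paste0("g", 1:5)),
                    descriptions = c(inflam = "d"),
                    class = "gene_set_collection")
  res <- ora_test(hits = paste0("g", 1:5), universe, coll)
  expect_equal(res$pvalue, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$padj, res$pvalue)           # single-set collection

  res0 <- ora_test(hits = paste0("g", 6:10), universe,
                   structure(list(s = paste0("g", 1:5)), class = "gene_set_collection"))
  expect_equal(res0$pvalue, 1)                  # zero overlap, upper tail

  expect_error(ora_test("x1", character(0), coll), "empty universe")
  expect_error(ora_test("zz", universe, coll), "outside the universe")
})

test_that("hypergeometric tail matches exhaustive enumeration on small universes", {
  set.seed(11)
  for (i in 1:5) {
    n_u <- sample(8:14, 1)
    universe <- paste0("g", seq_len(n_u))
    m <- sample(2:5, 1)
    n_h <- sample(2:5, 1)
    coll <- structure(list(s = paste0("g", seq_len(m))),
                      class = "gene_set_collection")
    hits <- sample(universe, n_h)
    res <- ora_test(hits, universe, coll)
    expect_equal(res$pvalue,
                 hyper_enum_oracle(res$overlap, m, n_u, n_h),
                 tolerance = 1e-12)
  }
})
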
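test_that("median-of-ratios size factors match the closed form", {
  k1 <- c(10L, 20L, 30L, 40L)
  cm <- toy_counts(cbind(S1 = k1, S2 = 2L * k1))
  s <- estimate_size_factors(cm)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)))
  expect_equal(exp(mean(log(s))), 1)

  same <- toy_counts(cbind(S1 = k1, S2 = k1, S3 = k1))
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))

  zero <- toy_counts(matrix(0L, 3, 2))
  expect_error(estimate_size_factors(zero), "filter")
})

test_that("size factors are idempotent and scaling-equivariant", {
  set.seed(1)
  k <- matrix(rnbinom(200 * 4, mu = 80, size = 10) + 1L, 200)
  rownames(k) <- paste0("g", 1:200)
  s <- estimate_size_factors(k)
  renorm <- round(sweep(k, 2, s, "/"))
  expect_true(all(abs(estimate_size_factors(renorm) - 1) < 0.05))

  # multiplying one sample by c multiplies its factor by c (up to the
  # geometric-mean rescaling, which cancels in factor ratios)
  k2 <- k
  k2[, 2] <- k2[, 2] * 3L
  r1 <- estimate_size_factors(k)
  r2 <- estimate_size_factors(k2)
  expect_equal(unname((r2[2] / r2[1]) / (r1[2] / r1[1])), 3, tolerance = 1e-9)
})

test_that("the log transform hits its anchor points", {
  cm <- toy_counts(matrix(c(0L, 2L, 3L, 0L, 2L, 3L), ncol = 2))
  tm <- transform_counts(cm, size_factors = c(1, 2))
  expect_equal(tm$x[1, 1], 0)        # K = 0 -> 0
  expect_equal(tm$x[2, 2], 1)        # K = s_j -> log2(2) = 1
  expect_equal(tm$x[3, 1], 2)        # K = 3, s = 1 -> log2(4) = 2
  expect_error(transform_counts(cm, size_factors = c(1, 2, 3)), "match")
  expect_error(transform_counts(cm, size_factors = c(1, -1)), "positive")
})

test_that("the NB Wald test recovers a planted fold change", {
  set.seed(42)
  ng <- 600
  mu_a <- 100
  k <- cbind(matrix(rnbinom(ng * 4, mu = mu_a, size = 20), ng),
             matrix(rnbinom(ng * 4, mu = mu_a * 8, size = 20), ng))
  rownames(k) <- paste0("g", seq_len(ng))
  tab <- nb_differential(k, 1:4, 5:8, size_factors = rep(1, 8))
  expect_lt(abs(median(tab$log2FoldChange) - 3), 0.3)
})

test_that("all-zero genes follow the stated convention", {
  set.seed(7)
  k <- matrix(rnbinom(50 * 6, mu = 50, size = 10) + 1L, 50)
  k[7, ] <- 0L
  rownames(k) <- paste0("g", 1:50)
  tab <- nb_differential(k, 1:3, 4:6)
  expect_equal(tab$log2FoldChange[7], 0)
  expect_equal(tab$pvalue[7], 1)
  expect_error(nb_differential(k, 1, 2:6), "singleton|>= 2 samples")
  expect_error(nb_differential(k, 1:3, 3:6), "disjoint")
})

test_that("contrasts across assays are refused", {
  exp <- generate_experiment(sim_config(n_genes = 50, seed = 2))
  expect_error(nb_differential(exp$counts, "control", "stimulus"), "assay")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  set.seed(3)
  p <- runif(100)
  expect_true(all(adjust_bh(p) >= p))
  expect_equal(adjust_bh(p), bh_oracle(p))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG classification uses strict inequalities", {
  tab <- toy_diff(paste0("g", 1:4),
                  lfc = c(1.5, 1.5, -1.0, -1.2),
                  padj = c(0.01, 0.2, 0.001, 0.001))
  tab <- classify_degs(tab)
  expect_identical(tab$class, c("up", "nd", "nd", "down"))
})

test_that("PCA fractions behave on anchor cases", {
  m <- matrix(0, 20, 6)
  m[1, ] <- c(0, 1, 2, 3, 4, 5)      # samples differ along one gene only
  rownames(m) <- paste0("g", 1:20)
  pc <- pca_summary(m)
  expect_equal(pc$variance_fraction[1], 1)

  set.seed(4)
  m2 <- matrix(rnorm(50 * 6), 50)
  pc2 <- pca_summary(m2)
  expect_equal(sum(pc2$variance_fraction), 1, tolerance = 1e-9)

  # duplicated samples get identical scores
  m3 <- cbind(m2, m2[, 6])
  pc3 <- pca_summary(m3)
  expect_equal(unname(pc3$scores[6, ]), unname(pc3$scores[7, ]))

  expect_error(pca_summary(matrix(5, 10, 4)), "constant")
})

test_that("average-linkage clustering matches a brute-force UPGMA oracle", {
  set.seed(5)
  m <- matrix(rnorm(5 * 12), 5)
  rownames(m) <- paste0("g", 1:5)
  hc <- hierarchical_cluster(m, axis = "genes")
  d <- 1 - cor(t(m))
  expect_equal(sort(hc$height), upgma_heights_oracle(d), tolerance = 1e-12)

  # identical items merge at height 0; anti-correlated items at distance 2
  m2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = -c(1, 2, 3, 4))
  hc2 <- hierarchical_cluster(m2, axis = "genes")
  expect_equal(min(hc2$height), 0)
  expect_equal(max(1 - cor(t(m2))), 2)

  m2["b", ] <- 5  # zero variance
  expect_error(hierarchical_cluster(m2, axis = "genes"), "b")
})
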
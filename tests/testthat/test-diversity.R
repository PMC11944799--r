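test_that("alpha diversity follows the Shannon/Pielou conventions", {
  t <- tiny_otu(matrix(c(5, 5, 10, 0), 2, byrow = TRUE))
  ad <- alpha_diversity(t)
  expect_equal(ad$richness, c(2L, 1L))
  expect_equal(ad$shannon, c(log(2), 0))
  expect_equal(ad$pielou, c(1, 0))
})

test_that("pielou stays within [0,1] and Shannon peaks at evenness", {
  for (seed in 1:25) {
    t <- random_otu(seed, n_samples = 4, n_otus = 12)
    ad <- alpha_diversity(t)
    expect_true(all(ad$pielou >= 0 & ad$pielou <= 1))
    expect_true(all(ad$shannon <= log(ad$richness) + 1e-12))
  }
  even <- tiny_otu(matrix(rep(10, 8), 1))
  expect_equal(alpha_diversity(even)$shannon, log(8))
})

test_that("Bray-Curtis matches its definition on relative abundances", {
  t <- tiny_otu(matrix(c(3, 6, 3, 6), 2, byrow = TRUE))
  expect_equal(unname(bray_curtis(t)[1, 2]), 0)
  t2 <- tiny_otu(matrix(c(5, 0, 0, 9), 2, byrow = TRUE))
  expect_equal(unname(bray_curtis(t2)[1, 2]), 1)
  t3 <- tiny_otu(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
  expect_equal(unname(bray_curtis(t3)[1, 2]), 1 / 3)
  t4 <- random_otu(8, n_samples = 6, n_otus = 15)
  d <- bray_curtis(t4)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 6))
})

test_that("NMDS recovers exactly embeddable configurations", {
  x <- matrix(c(0, 1, 2.2, 3.9), 4, 1)
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  fit <- run_nmds(d, k = 2, seed = 3)
  expect_lt(fit$stress, 0.01)
  # n = k + 1 equidistant points embed as a simplex
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  rownames(d3) <- colnames(d3) <- paste0("s", 1:3)
  expect_lt(run_nmds(d3, k = 2, seed = 3)$stress, 1e-4)
})

test_that("NMDS is equivariant under sample relabelling", {
  t <- random_otu(21, n_samples = 8, n_otus = 30)
  d <- bray_curtis(t)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  f1 <- run_nmds(d, seed = 11)
  f2 <- run_nmds(d[perm, perm], seed = 11)
  expect_equal(f2$stress, f1$stress, tolerance = 1e-6)
  # embedded inter-point geometry matches after permutation
  d1 <- as.matrix(dist(f1$points))[perm, perm]
  d2 <- as.matrix(dist(f2$points))
  expect_equal(unname(d2), unname(d1), tolerance = 1e-4)
})

test_that("PERMANOVA pseudo-F matches the distance-based formula", {
  t <- random_otu(31, n_samples = 6, n_otus = 12)
  d <- bray_curtis(t)
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(d, g, n_perm = 199, seed = 5)
  # brute force from the pairwise-distance partitioning
  n <- 6; a <- 2
  ss_tot <- sum(d[upper.tri(d)]^2) / n
  ss_w <- 0
  for (gr in unique(g)) {
    idx <- which(g == gr)
    dd <- d[idx, idx]
    ss_w <- ss_w + sum(dd[upper.tri(dd)]^2) / length(idx)
  }
  f_expect <- ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
  expect_equal(res$statistic, f_expect, tolerance = 1e-10)
  expect_equal(res$effect, (ss_tot - ss_w) / ss_tot, tolerance = 1e-10)
  # conservation: R2 + within-fraction = 1
  expect_equal(res$effect + ss_w / ss_tot, 1, tolerance = 1e-10)
})

test_that("PERMANOVA saturates in the fully separated limit", {
  x <- rbind(matrix(rnorm(8, 0, 1e-3), 4), matrix(rnorm(8, 50, 1e-3), 4))
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("s", 1:8)
  res <- permanova(d, rep(c("a", "b"), each = 4), n_perm = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$effect, 0.99)
  expect_error(permanova(d, c("a", rep("b", 7)), seed = 1), "at least 2")
})

test_that("Mantel statistic behaves under identity and affine maps", {
  t <- random_otu(41, n_samples = 7, n_otus = 20)
  d <- bray_curtis(t)
  expect_equal(mantel_test(d, d, n_perm = 99, seed = 1)$statistic, 1)
  expect_equal(mantel_test(d, 0.3 + 2 * d, n_perm = 99,
                           seed = 1)$statistic, 1)
  expect_error(mantel_test(d, d[1:5, 1:5]), "size")
})

test_that("Kruskal-Wallis reproduces the textbook rank computation", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 3.857, tolerance = 1e-3)
  expect_error(kruskal_wallis(c(1, 2), c("a", "b")), "insufficient")
  flat <- kruskal_wallis(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("Duncan's test groups means into connected letters", {
  v <- c(10.1, 9.9, 10.0, 10.05, 9.95, 10.02)
  g <- rep(c("a", "b", "c"), each = 2)
  same <- anova_duncan(v, g)
  expect_true(all(same$letters == "a"))

  set.seed(2)
  v2 <- c(rnorm(6, 0, 0.1), rnorm(6, 50, 0.1))
  d2 <- anova_duncan(v2, rep(c("lo", "hi"), each = 6))
  expect_equal(d2$letters, c("a", "b"))
  expect_equal(d2$group, c("hi", "lo"))

  # 4-group fixture: two tight clusters far apart, close pair within
  set.seed(1)
  v4 <- c(rnorm(5, 10, 1), rnorm(5, 10.2, 1), rnorm(5, 15, 1),
          rnorm(5, 20, 1))
  g4 <- rep(c("g1", "g2", "g3", "g4"), each = 5)
  d4 <- anova_duncan(v4, g4)
  expect_equal(d4$group, c("g4", "g3", "g2", "g1"))
  expect_equal(d4$letters, c("a", "b", "c", "c"))
})

test_that("Duncan letters agree with a direct stepwise-range check", {
  set.seed(7)
  v <- c(rnorm(4, 5), rnorm(4, 8), rnorm(4, 11))
  g <- rep(c("x", "y", "z"), each = 4)
  res <- anova_duncan(v, g)
  an <- anova(aov(v ~ factor(g)))
  mse <- an$`Mean Sq`[2]; dfe <- an$Df[2]
  m <- sort(tapply(v, g, mean), decreasing = TRUE)
  lsr2 <- qtukey(0.95, 2, dfe) * sqrt(mse / 4)
  lsr3 <- qtukey(0.95^2, 3, dfe) * sqrt(mse / 4)
  sep12 <- (m[1] - m[2]) > lsr2
  sep23 <- (m[2] - m[3]) > lsr2
  sep13 <- (m[1] - m[3]) > lsr3
  expected <- if (sep12 && sep23 && sep13) c("a", "b", "c") else NULL
  if (!is.null(expected)) expect_equal(res$letters, expected)
  expect_equal(attr(res, "MSE"), mse)
})

test_that("correlation screens handle linear, monotone and rank cases", {
  x <- data.frame(x = 1:8)
  expect_equal(correlation_screen(x, data.frame(y = 2 * (1:8) + 1))$r, 1)
  expect_equal(correlation_screen(x, data.frame(y = exp(1:8)),
                                  method = "spearman")$r, 1)
  # n = 5 tie-free fixture against the rank-difference formula
  xv <- c(3, 1, 4, 2, 5); yv <- c(2, 1, 5, 3, 4)
  d2 <- sum((rank(xv) - rank(yv))^2)
  r_expect <- 1 - 6 * d2 / (5 * (25 - 1))
  sc <- correlation_screen(data.frame(a = xv), data.frame(b = yv),
                           method = "spearman")
  expect_equal(sc$r, r_expect)
  expect_warning(
    out <- correlation_screen(data.frame(c = rep(1, 5)),
                              data.frame(b = yv)), "constant")
  expect_true(is.na(out$r))
})
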
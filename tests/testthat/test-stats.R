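test_that("KS statistic is tiny for a sample placed at the fitted normal quantiles", {
  # plotting positions (i - 0.5)/n of a standard normal, n = 10
  n <- 10
  x <- qnorm((seq_len(n) - 0.5) / n)
  res <- ks_normality(x)
  # mean/sd re-estimation shifts quantiles slightly; D stays near 1/(2n)
  expect_lt(res$statistic, 1 / (2 * n) + 0.05)
  expect_error(ks_normality(rep(1, 10)), "degenerate")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("KS statistic is invariant under affine transforms and matches a brute-force sup", {
  set.seed(51)
  x <- runif(100)
  a <- ks_normality(x)
  b <- ks_normality(3 + 7 * x)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  # brute-force sup over the empirical CDF at all sample points
  z <- (x - mean(x)) / sd(x)
  Fhat <- ecdf(z)
  eps <- 1e-9
  D_brute <- max(vapply(z, function(t)
    max(abs(Fhat(t) - pnorm(t)), abs(Fhat(t - eps) - pnorm(t))), 0))
  expect_equal(a$statistic, D_brute, tolerance = 1e-6)
  # cross-check against the stats implementation of the same statistic
  expect_equal(a$statistic, unname(ks.test(z, "pnorm")$statistic),
               tolerance = 1e-9)
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  g <- list(c(4, 5, 6), c(6, 7, 8), c(8, 9, 10))
  res <- one_way_anova(g)
  expect_equal(res$F, 12)                       # SSB 24 / SSW 6, df (2, 6)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(res$p_value, pf(12, 2, 6, lower.tail = FALSE))
  # identical groups: F = 0, p = 1
  res0 <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res0$F, 0)
  expect_equal(res0$p_value, 1)
  # near-separation: p -> 0 as the jitter vanishes
  p_big <- one_way_anova(list(c(0, 0.1), c(1, 1.1)))$p_value
  p_small <- one_way_anova(list(c(0, 0.001), c(1, 1.001)))$p_value
  expect_lt(p_small, p_big)
  expect_lt(p_small, 1e-4)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  # order invariance
  expect_equal(one_way_anova(rev(g))$F, res$F)
  # cross-check against the built-in linear-model route
  y <- unlist(g); f <- factor(rep(1:3, each = 3))
  expect_equal(res$F, unname(summary(aov(y ~ f))[[1]]$`F value`[1]),
               tolerance = 1e-9)
})

test_that("Duncan's two-group decision coincides with the pooled t-test", {
  set.seed(52)
  for (i in 1:60) {
    g <- list(rnorm(8), rnorm(8, runif(1, 0, 1.5)))
    d <- duncan_posthoc(g)
    tt <- t.test(g[[1]], g[[2]], var.equal = TRUE)
    expect_identical(unname(d$pairwise_decisions[1, 2]),
                     tt$p.value < 0.05)
  }
})

test_that("Duncan separates a far group and keeps close groups together", {
  set.seed(53)
  g <- list(A = rnorm(14, 0, 1), B = rnorm(14, 0.1, 1), C = rnorm(14, 10, 1))
  d <- duncan_posthoc(g)
  expect_true(d$pairwise_decisions["A", "C"])
  expect_true(d$pairwise_decisions["B", "C"])
  expect_false(d$pairwise_decisions["A", "B"])
  subs <- lapply(d$homogeneous_subsets, sort)
  expect_true(any(vapply(subs, identical, TRUE, y = c("A", "B"))))
  expect_true(any(vapply(subs, identical, TRUE, y = "C")))
  # all-identical-mean groups: one subset, no significant pair
  g2 <- list(rnorm(10), rnorm(10), rnorm(10))
  d2 <- duncan_posthoc(g2)
  if (!any(d2$pairwise_decisions))
    expect_length(d2$homogeneous_subsets, 1)
  # decisions and subsets are mutually consistent
  for (s in d$homogeneous_subsets)
    if (length(s) > 1)
      expect_false(any(d$pairwise_decisions[s, s]))
})

test_that("exact rank-sum enumeration reproduces closed-form cases", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_identical(r$mode, "exact")
  # identical samples: p = 1 by symmetry with midranks
  r2 <- rank_sum_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r2$p_value, 1)
  # null probabilities over all assignments sum to 1
  x <- c(1.2, 3.4, 2.2); y <- c(0.5, 4.1, 2.9)
  rks <- rank(c(x, y))
  sums <- colSums(matrix(rks[combn(6, 3)], nrow = 3))
  tab <- table(sums) / choose(6, 3)
  expect_equal(sum(tab), 1)
})

test_that("normal approximation agrees with exact enumeration at moderate n", {
  set.seed(54)
  x <- rnorm(6); y <- rnorm(6, 0.8)
  pe <- rank_sum_test(x, y, mode = "exact")$p_value
  pa <- rank_sum_test(x, y, mode = "approx")$p_value
  expect_lt(abs(pe - pa), 0.03)
  # larger samples take the approximate path automatically
  r <- rank_sum_test(rnorm(20), rnorm(20, 0.5))
  expect_identical(r$mode, "approx")
  # and agree with the built-in implementation
  x2 <- rnorm(15); y2 <- rnorm(15, 0.4)
  p_pkg <- rank_sum_test(x2, y2, mode = "approx")$p_value
  p_ref <- wilcox.test(x2, y2, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-9)
})

test_that("tests are invariant to the order of group input", {
  set.seed(55)
  x <- rnorm(10); y <- rnorm(12, 0.3)
  expect_equal(rank_sum_test(x, y)$p_value, rank_sum_test(y, x)$p_value,
               tolerance = 1e-12)
})
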
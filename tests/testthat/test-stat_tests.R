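test_that("chi-square GOF matches the direct formula and base R", {
  res <- chi2_gof(c(8, 2), c(5, 5))
  expect_equal(res$statistic, 3.6)
  expect_equal(res$df, 1)
  expect_equal(res$p_raw, stats::pchisq(3.6, 1, lower.tail = FALSE))

  eq <- chi2_gof(c(5, 5, 5), c(5, 5, 5))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_raw, 1)

  expect_error(chi2_gof(c(1, 2), c(1, 0)), "> 0")
  expect_error(chi2_gof(5, 5), "2 categories")

  # independent cross-check against stats::chisq.test
  set.seed(14)
  for (i in 1:10) {
    o <- rpois(6, 30)
    ref <- stats::chisq.test(o, p = rep(1 / 6, 6))
    mine <- chi2_gof(o, rep(sum(o) / 6, 6))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis follows the printed rank formula with ties handled", {
  res <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(res$statistic, 7.2)  # hand ranks R = {6, 15, 24}
  expect_equal(res$df, 2)

  # rank invariance under strictly increasing transforms
  x <- c(3.2, 1.1, 8.8, 2.5, 9.1, 4.4, 0.3, 7.7, 5.5)
  g <- rep(c("a", "b", "c"), 3)
  expect_equal(kruskal_wallis(x, g)$statistic,
               kruskal_wallis(exp(x), g)$statistic, tolerance = 1e-12)

  # all identical values: statistic 0, p = 1
  same <- kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)

  # tie-corrected statistic matches stats::kruskal.test
  set.seed(15)
  for (i in 1:10) {
    v <- sample(1:5, 30, replace = TRUE)  # heavy ties
    g <- rep(c("a", "b", "c"), 10)
    ref <- stats::kruskal.test(v, factor(g))
    mine <- kruskal_wallis(v, g)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U statistic, complements and p-values", {
  sep <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(sep$statistic, 0)

  # U + U' = nm
  set.seed(16)
  x <- rnorm(12)
  y <- rnorm(9)
  u1 <- mann_whitney_u(x, y)$statistic
  u2 <- mann_whitney_u(y, x)$statistic
  expect_equal(u1 + u2, 12 * 9)

  # identical samples: U = nm/2, p near 1
  same <- mann_whitney_u(1:5, 1:5)
  expect_equal(same$statistic, 25 / 2)
  expect_gt(same$p_raw, 0.9)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")

  # agreement with stats::wilcox.test (W is the same U statistic)
  for (i in 1:10) {
    x <- rnorm(25)
    y <- rnorm(30, 0.3)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    mine <- mann_whitney_u(x, y)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-10)
  }

  # exact mode agrees with the exact wilcox.test on small untied samples
  x <- c(1.2, 3.4, 5.1, 7.8)
  y <- c(2.2, 4.9, 6.3, 8.8, 9.9)
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  mine <- mann_whitney_u(x, y, exact = TRUE)
  expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-12)
  expect_error(mann_whitney_u(c(1, 1), c(1, 2), exact = TRUE), "untied")

  # Bonferroni wiring
  adj <- mann_whitney_u(x, y, n_tests = 3)
  expect_equal(adj$p_adjusted, min(1, 3 * adj$p_raw))
})

test_that("KW equals the squared standardized MWU for two untied groups", {
  set.seed(17)
  x <- rnorm(20)
  y <- rnorm(25, 0.5)
  kw <- kruskal_wallis(c(x, y), rep(c("a", "b"), c(20, 25)))
  mw <- mann_whitney_u(x, y, continuity = FALSE)
  n <- 20; m <- 25; N <- n + m
  z <- (mw$statistic - n * m / 2) / sqrt(n * m * (N + 1) / 12)
  expect_equal(kw$statistic, z^2, tolerance = 1e-10)
})

test_that("Shapiro-Wilk reproduces base R and behaves under transforms", {
  # near-normal construction: expected normal order statistics
  x <- stats::qnorm((1:50 - 0.375) / 50.25)
  res <- shapiro_wilk(x)
  expect_gt(res$statistic, 0.99)

  # heavy bimodal sample rejects
  set.seed(18)
  bim <- c(rnorm(50, -4, 0.3), rnorm(50, 4, 0.3))
  expect_lt(shapiro_wilk(bim)$p_raw, 0.05)

  # location-scale invariance
  y <- rnorm(40)
  expect_equal(shapiro_wilk(y)$statistic,
               shapiro_wilk(5 + 3 * y)$statistic, tolerance = 1e-10)

  # cross-check W and p against stats::shapiro.test over a size range
  for (n in c(5, 11, 12, 30, 200)) {
    z <- rnorm(n)
    ref <- stats::shapiro.test(z)
    mine <- shapiro_wilk(z)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-4)
  }

  expect_error(shapiro_wilk(rep(1, 10)), "variance")
  expect_error(shapiro_wilk(1:2), "sample size")
})

test_that("p-values stay in [0,1] and statistics ignore input order", {
  set.seed(19)
  x <- rnorm(30)
  g <- sample(rep(c("a", "b", "c"), 10))
  perm <- sample(30)
  expect_equal(kruskal_wallis(x, g)$statistic,
               kruskal_wallis(x[perm], g[perm])$statistic)
  expect_equal(mann_whitney_u(x[g == "a"], x[g == "b"])$p_raw,
               mann_whitney_u(sample(x[g == "a"]), x[g == "b"])$p_raw)
  for (p in c(kruskal_wallis(x, g)$p_raw,
              mann_whitney_u(x[g == "a"], x[g == "b"])$p_raw,
              shapiro_wilk(x)$p_raw)) {
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
  expect_equal(bonferroni(0.4, 3), 1)
  expect_equal(bonferroni(0.01, 3), 0.03)
})
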
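test_that("partial correlation reduces to plain Pearson without controls", {
  set.seed(31)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  expect_equal(partial_correlation(x, y)$df, 38)
})

test_that("partial correlation matches the precision-matrix oracle", {
  set.seed(32)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    k <- sample(1:3, 1)
    Z <- matrix(rnorm(n * k), n)
    x <- rnorm(n) + Z %*% runif(k, -1, 1)
    y <- rnorm(n) + Z %*% runif(k, -1, 1)
    res <- partial_correlation(as.numeric(x), as.numeric(y), Z)
    expect_equal(res$r, precision_partial_r(as.numeric(x), as.numeric(y), Z),
                 tolerance = 1e-10)
    expect_equal(res$df, n - 2 - k)
  }
})

test_that("controlling for a shared driver removes its induced correlation", {
  set.seed(33)
  z <- rnorm(200)
  x <- z + rnorm(200, 0, 0.05)
  y <- z + rnorm(200, 0, 0.05)
  expect_gt(cor(x, y), 0.9)
  expect_lt(abs(partial_correlation(x, y, controls = z)$r), 0.1)
})

test_that("partial correlation tails and guards behave", {
  set.seed(34)
  x <- rnorm(30); y <- x + rnorm(30)
  p2 <- partial_correlation(x, y)$p
  pg <- partial_correlation(x, y, tail = "greater")$p
  pl <- partial_correlation(x, y, tail = "less")$p
  expect_equal(pg + pl, 1, tolerance = 1e-12)
  expect_equal(p2, 2 * min(pg, pl), tolerance = 1e-12)
  expect_error(partial_correlation(x, y, controls = cbind(a = x, b = 2 * x)),
               "collinear")
})

test_that("independent correlation comparison matches the closed form", {
  eq <- compare_correlations_independent(0.4, 30, 0.4, 50)
  expect_equal(eq$Z, 0)
  expect_equal(eq$p, 1)
  z <- compare_correlations_independent(0.5, 28, 0, 28)
  # closed form: atanh(0.5) / sqrt(1/25 + 1/25) = 1.94209...
  expect_equal(z$Z, atanh(0.5) / sqrt(2 / 25), tolerance = 1e-9)
  expect_equal(round(z$Z, 3), 1.942)
  zneg <- compare_correlations_independent(-0.5, 28, 0, 28)
  expect_equal(zneg$Z, -z$Z)
  expect_error(compare_correlations_independent(0.5, 3, 0, 28), "exceed 3")
})

test_that("dependent overlapping comparison: identity, PD guard, monotonicity", {
  expect_equal(compare_correlations_dependent(0.4, 0.4, 0.3, 40)$Z, 0)
  expect_error(compare_correlations_dependent(0.9, -0.9, 0.9, 40),
               "positive definite")
  zs <- sapply(c(0.1, 0.4, 0.7, 0.9),
               function(ryz) compare_correlations_dependent(0.5, 0.2, ryz, 40)$Z)
  expect_true(all(diff(abs(zs)) > 0))
})

test_that("dependent overlapping Z agrees with a resampling oracle", {
  # MVN populations with known correlation triplets; the empirical sd of
  # (z_xy - z_xz) across resamples yields an oracle z statistic
  for (case in list(c(0.6, 0.1, 0.2), c(0.5, 0.3, 0.6))) {
    n <- 40
    R <- matrix(c(1, case[1], case[2],
                  case[1], 1, case[3],
                  case[2], case[3], 1), 3, 3)
    L <- chol(R)
    set.seed(35)
    diffs <- replicate(4000, {
      M <- matrix(rnorm(n * 3), n) %*% L
      atanh(cor(M[, 1], M[, 2])) - atanh(cor(M[, 1], M[, 3]))
    })
    oracle_z <- (atanh(case[1]) - atanh(case[2])) / sd(diffs)
    got <- compare_correlations_dependent(case[1], case[2], case[3], n)$Z
    expect_lt(abs(got - oracle_z), 0.1)
  }
})

test_that("coupling change is zero for identical pairs and detects planted shifts", {
  set.seed(36)
  g <- rnorm(30); b <- 0.4 * g + rnorm(30)
  same <- coupling_change(g, b, g, b)
  expect_equal(same$Z, 0)
  expect_equal(same$r_pre, same$r_post)
  expect_error(coupling_change(g[1:4], b[1:4], g[1:4], b[1:4]), "at least 5")
  # light-weight power check: strong planted shift is usually detected
  hits <- 0
  for (s in 1:30) {
    set.seed(400 + s)
    n <- 36
    pre_g <- rnorm(n); pre_b <- 0.18 * pre_g + sqrt(1 - 0.18^2) * rnorm(n)
    pg <- rnorm(n); pb <- 0.8 * pg + 0.6 * rnorm(n)
    hits <- hits + (coupling_change(pre_g, pre_b, pg, pb)$p < 0.05)
  }
  expect_gt(hits, 20)
})

test_that("bh_fdr reproduces the step-up procedure and reference implementation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(37)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  # families are corrected independently
  p <- c(0.01, 0.04, 0.01, 0.04)
  fam <- c("a", "a", "b", "b")
  expect_equal(bh_fdr(p, fam), c(p.adjust(p[1:2], "BH"), p.adjust(p[3:4], "BH")))
  expect_error(bh_fdr(c(0.5, 1.2)), "lie in")
  expect_true(all(bh_fdr(runif(20)) >= runif(0)))
})

test_that("IQR outlier rule uses 3x fences with interpolated quartiles", {
  v <- c(1:9, 100)
  # Q1 = 3.25, Q3 = 6.75, IQR = 3.5 -> upper fence 17.25
  expect_identical(which(iqr_outliers(v)), 10L)
  expect_false(any(iqr_outliers(rep(5, 10))))
  set.seed(38)
  x <- rnorm(100)
  expect_identical(iqr_outliers(-x), iqr_outliers(x))  # symmetric fences
  expect_error(iqr_outliers(c(1, 2, 3)), "at least 4")
})

test_that("time-by-group mixed model guards and detects a planted interaction", {
  d <- lmm_null_data(41)
  d$conc_corrected <- 5
  expect_error(fit_time_group_lmm(d), "constant")
  d2 <- lmm_null_data(42, interaction = 0.6)
  f <- suppressWarnings(fit_time_group_lmm(d2))
  expect_lt(f$anova[f$anova$term == "time:group", "Pr(>F)"], 0.01)
  expect_true(all(f$posthoc$q >= f$posthoc$p - 1e-12))
  expect_equal(nrow(f$posthoc), choose(6, 2))
})
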
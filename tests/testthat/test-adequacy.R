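# oracle constants for the 4-point toy pair, computed once from the
# decomposition formulas with population SDs (recorded before the build)
toy_expected <- list(
  mb = 0, msep = 6.5, rmsep = 2.5495097567963922,
  pct_mean_bias = 0, pct_slope_bias = 5.200433369447509,
  pct_random = 94.79956663055178,
  r = 0.975040627539239, ccc = 0.9719222462203027,
  cb = 0.9968017934526416, aic_p1 = 11.487208707606365,
  mse_p1 = 8.666666666666666, r2_adj_p1 = 0.9260563380281697)

test_that("the toy observed/predicted pair reproduces its recorded oracle", {
  toys <- make_toy_tables()
  r <- adequacy(toys$adequacy$observed, toys$adequacy$predicted, p = 1)
  expect_equal(r$mb, toy_expected$mb, tolerance = 1e-12)
  expect_equal(r$msep, toy_expected$msep, tolerance = 1e-12)
  expect_equal(r$rmsep, toy_expected$rmsep, tolerance = 1e-12)
  expect_equal(r$pct_mean_bias, toy_expected$pct_mean_bias, tolerance = 1e-9)
  expect_equal(r$pct_slope_bias, toy_expected$pct_slope_bias, tolerance = 1e-9)
  expect_equal(r$pct_random, toy_expected$pct_random, tolerance = 1e-9)
  expect_equal(r$ccc, toy_expected$ccc, tolerance = 1e-12)
  expect_equal(r$cb, toy_expected$cb, tolerance = 1e-12)
  expect_equal(r$aic, toy_expected$aic_p1, tolerance = 1e-12)
  expect_equal(r$mse, toy_expected$mse_p1, tolerance = 1e-12)
  expect_equal(r$r2_adj, toy_expected$r2_adj_p1, tolerance = 1e-12)
})

test_that("perfect agreement and pure shift follow the stated conventions", {
  o <- c(3, 7, 12, 20, 31)
  perfect <- adequacy(o, o, p = 1)
  expect_equal(perfect$msep, 0)
  expect_equal(perfect$ccc, 1)
  expect_equal(perfect$cb, 1)
  expect_equal(c(perfect$pct_mean_bias, perfect$pct_slope_bias,
                 perfect$pct_random), c(0, 0, 100))

  shift <- adequacy(o, o + 5, p = 1)
  expect_equal(shift$mb, -5)                 # obs - pred
  expect_equal(shift$pct_mean_bias, 100, tolerance = 1e-9)
  expect_equal(shift$r2, 1, tolerance = 1e-12)
  expect_lt(shift$cb, 1)
  expect_lt(shift$ccc, 1)
})

test_that("the three MSEP components always close to MSEP", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    o <- rnorm(n, sample(0:100, 1), runif(1, 0.5, 20))
    p <- o * runif(1, 0.2, 1.8) + rnorm(n, 0, runif(1, 0.1, 10))
    if (sd(o) == 0 || sd(p) == 0) next
    r <- adequacy(o, p, p = 1)
    expect_equal(r$pct_mean_bias + r$pct_slope_bias + r$pct_random, 100,
                 tolerance = 1e-9)
    expect_equal(r$ccc, cor(o, p) * r$cb, tolerance = 1e-12)
    expect_lte(abs(r$ccc), abs(cor(o, p)) + 1e-12)
  }
})

test_that("CCC is symmetric and bounded by r with the stated equality case", {
  set.seed(102)
  a <- rnorm(50, 10, 3); b <- 0.7 * a + rnorm(50, 2, 1)
  expect_equal(adequacy(a, b, p = 1)$ccc, adequacy(b, a, p = 1)$ccc,
               tolerance = 1e-12)
  # ccc == r iff mb = 0 and equal spreads: enforce both by standardizing
  b_std <- (b - mean(b)) / sd(b) * sd(a) + mean(a)
  r <- adequacy(a, b_std, p = 1)
  expect_equal(r$ccc, cor(a, b_std), tolerance = 1e-12)
  expect_equal(r$cb, 1, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(adequacy(1:5, 1:4, p = 1), "lengths")
  expect_error(adequacy(rep(1, 5), 2:6, p = 1), "zero variance")
  expect_error(adequacy(1:5, rep(2, 5), p = 1), "zero variance")
  expect_error(adequacy(1:5, 2:6, p = 5), "p must be smaller")
})

test_that("OLS reproduces exact fits and the normal-equations oracle", {
  set.seed(103)
  X <- data.frame(x1 = rnorm(60), x2 = runif(60))
  y <- 3 + 2 * X$x1 - X$x2
  fit <- ols_fit(y, X)
  expect_lt(max(abs(fit$fitted_values - y)), 1e-8)
  expect_identical(fit$p, 3L)

  # irrelevant predictor: slope from the 2x2 normal equations directly
  z <- data.frame(w = 5 + rnorm(60, 0, 0.1))
  yy <- rnorm(60)
  f2 <- ols_fit(yy, z)
  slope_oracle <- solve(cbind(c(60, sum(z$w)), c(sum(z$w), sum(z$w^2))),
                        c(sum(yy), sum(z$w * yy)))[2]
  expect_equal(unname(f2$coefficients["w"]), slope_oracle, tolerance = 1e-8)
  expect_lt(abs(f2$coefficients["w"]), 3 * sd(yy) / (sqrt(60) * sd(z$w)))

  expect_error(ols_fit(y, data.frame(a = X$x1, b = X$x1)), "collinear")
})

test_that("in-sample OLS predictions have zero mean- and slope-bias components", {
  set.seed(104)
  for (i in 1:50) {
    X <- as.data.frame(matrix(rnorm(40 * 3), 40, 3))
    y <- rnorm(40, X[[1]] - 2 * X[[3]], 1)
    fit <- ols_fit(y, X)
    r <- adequacy(y, fit$fitted_values, p = fit$p)
    expect_lt(r$pct_mean_bias, 1e-9)
    expect_lt(r$pct_slope_bias, 1e-9)
    expect_gt(r$pct_random, 100 - 1e-6)
  }
})

test_that("adequacy_table renders statistics by scenario", {
  toys <- make_toy_tables()
  r <- adequacy(toys$adequacy$observed, toys$adequacy$predicted, p = 1)
  tb <- adequacy_table(list(lm_in = r, lm_dup = r))
  expect_identical(names(tb), c("statistic", "lm_in", "lm_dup"))
  expect_equal(tb$lm_in[tb$statistic == "MSE"], r$mse)
  expect_equal(tb$lm_in[tb$statistic == "CCC"], r$ccc)
})
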
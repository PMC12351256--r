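test_that("the Cholesky factor reproduces the target and rejects invalid matrices", {
  ident <- spearman_target(diag(3), c("a", "b", "c"))
  expect_equal(cholesky_factor(ident), diag(3), ignore_attr = TRUE)

  tgt <- spearman_target(matrix(c(1, .5, .5, 1), 2, 2), c("a", "b"))
  L <- cholesky_factor(tgt)
  expect_equal(L[2, ], c(0.5, sqrt(0.75)), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_lt(max(abs(L %*% t(L) - tgt$matrix)), 1e-10)

  expect_error(spearman_target(matrix(c(1, 1.2, 1.2, 1), 2, 2)), "\\[-1, 1\\]")
  bad <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3, 3)
  expect_error(spearman_target(bad), "minor|semi-definite")
})

test_that("correlated normal scores hit the target and are reproducible", {
  ident <- spearman_target(diag(3), c("a", "b", "c"))
  z <- correlated_normal_scores(10000, ident, seed = 5)
  cm <- cor(z)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.04)   # 3/sqrt(n) bound + slack
  expect_identical(correlated_normal_scores(50, ident, seed = 1),
                   correlated_normal_scores(50, ident, seed = 1))
  one <- correlated_normal_scores(5000, spearman_target(diag(1), "x"), seed = 2)
  expect_identical(ncol(one), 1L)
  expect_lt(abs(sd(one$x) - 1), 0.05)
  expect_error(correlated_normal_scores(2, ident), ">= 3")
})

test_that("rank imposition returns exact permutations with all moments preserved", {
  d <- benchmark_draws(2000, seed = 6)
  tgt <- default_benchmark_target()
  out <- impose_rank_correlation(d, tgt, seed = 7)
  expect_permutation(out, d)
  for (nm in names(d)) {
    expect_identical(moment_vec(out[[nm]]), moment_vec(d[[nm]]))
  }
  realized <- spearman_matrix(out)$matrix
  expect_lt(max(abs(realized - tgt$matrix)), 0.08)

  # identity target: columns reordered independently
  ident <- spearman_target(diag(3), names(d))
  out0 <- impose_rank_correlation(d, ident, seed = 8)
  expect_permutation(out0, d)

  expect_error(impose_rank_correlation(d[, 1:2], tgt), "mismatch")
})

test_that("a perfectly co-monotone target yields rank correlation 1", {
  x <- rlnorm(500)
  d <- data.frame(a = x, b = x)
  tgt <- spearman_target(matrix(c(1, 1, 1, 1), 2, 2), c("a", "b"))
  out <- impose_rank_correlation(d, tgt, seed = 9)
  expect_equal(unname(spearman_matrix(out)$matrix[1, 2]), 1)
})

test_that("spearman_matrix matches a brute-force rank-correlation oracle", {
  x <- c(0.3, 1.7, 2.2, 5.1)
  d <- data.frame(x = x, y = x^3)        # strictly monotone transform
  expect_equal(unname(spearman_matrix(d)$matrix[1, 2]), 1)
  d2 <- data.frame(x = 1:4, y = c(4, 3, 2, 1))
  expect_equal(unname(spearman_matrix(d2)$matrix[1, 2]), -1)
  d3 <- data.frame(x = c(1, 2, 3), y = c(2, 1, 3))
  expect_equal(unname(spearman_matrix(d3)$matrix[1, 2]), 0.5)
  expect_equal(unname(spearman_matrix(d3)$matrix[1, 2]),
               brute_spearman(d3$x, d3$y))
  set.seed(10)
  a <- rnorm(37); b <- rexp(37)
  expect_equal(unname(spearman_matrix(data.frame(a, b))$matrix[1, 2]),
               brute_spearman(a, b), tolerance = 1e-12)
  expect_error(spearman_matrix(data.frame(a = 1:5, b = rep(2, 5))), "constant")
})

test_that("realized Spearman is invariant to strictly monotone column transforms", {
  d <- benchmark_draws(800, seed = 11)
  tgt <- default_benchmark_target()
  out <- impose_rank_correlation(d, tgt, seed = 12)
  logged_after <- out; logged_after$var3 <- log(out$var3)
  d_before <- d; d_before$var3 <- log(d$var3)
  out_before <- impose_rank_correlation(d_before, tgt, seed = 12)
  expect_equal(spearman_matrix(logged_after)$matrix,
               spearman_matrix(out_before)$matrix, tolerance = 1e-12)
})

test_that("copula imposition honors its convergence contract and preserves marginals", {
  d <- benchmark_draws(2000, seed = 13)
  ident <- spearman_target(diag(3), names(d))
  res <- copula_impose(d, ident, tol = 0.05, seed = 14)
  expect_true(res$converged)
  expect_identical(res$iterations, 1L)
  expect_permutation(res$data, d)

  tgt <- default_benchmark_target()
  res2 <- copula_impose(d, tgt, max_iter = 1L, tol = 1e-9, seed = 15)
  expect_false(res2$converged)
  expect_gt(res2$deviation, 1e-9)
  expect_permutation(res2$data, d)

  res3 <- copula_impose(d, tgt, seed = 16, adjust = "damped")
  expect_permutation(res3$data, d)
  expect_true(res3$converged)
  expect_lte(res3$deviation, 0.01)

  expect_error(copula_impose(d, tgt, max_iter = 0), "max_iter")
  expect_error(copula_impose(d, tgt, tol = 0), "tol")
})

test_that("with normal marginals the realized Pearson matches the target", {
  set.seed(17)
  d <- data.frame(a = rnorm(5000), b = rnorm(5000, 10, 3))
  tgt <- spearman_target(matrix(c(1, .6, .6, 1), 2, 2), c("a", "b"))
  out <- impose_rank_correlation(d, tgt, seed = 18)
  expect_lt(abs(cor(out$a, out$b) - 0.6), 0.03)
})

test_that("mean absolute deviation from the target shrinks as n grows", {
  tgt <- default_benchmark_target()
  mean_dev <- vapply(c(500, 5000), function(n) {
    devs <- vapply(1:40, function(i) {
      d <- benchmark_draws(n, seed = 100 + i)
      out <- impose_rank_correlation(d, tgt, seed = 200 + i)
      S <- spearman_matrix(out)$matrix
      mean(abs((S - tgt$matrix)[upper.tri(S)]))
    }, numeric(1))
    mean(devs)
  }, numeric(1))
  expect_gt(mean_dev[1], mean_dev[2])
})

test_that("the bias-adjusted scores mode removes the small-target bias", {
  # at rho = 0.5 the direct ("direct") mode has bias (6/pi) asin(rho/2) - rho
  tgt <- spearman_target(matrix(c(1, .5, .5, 1), 2, 2), c("a", "b"))
  devs <- vapply(1:30, function(i) {
    set.seed(300 + i)
    d <- data.frame(a = rexp(4000), b = rlnorm(4000))
    out <- impose_rank_correlation(d, tgt, mode = "adjusted")
    spearman_matrix(out)$matrix[1, 2] - 0.5
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.01)
})
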
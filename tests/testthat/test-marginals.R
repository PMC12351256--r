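test_that("the normal fit is the closed-form Gaussian MLE and AIC obeys its identity", {
  set.seed(11)
  x <- rnorm(50, 5, 2)
  fm <- fit_marginal(x, "normal")
  expect_equal(unname(fm$params["mean"]), mean(x))
  expect_equal(unname(fm$params["sd"]), sqrt(mean((x - mean(x))^2)))
  # aic = 2k - 2 logLik, k = length(params), across a spread of families
  cases <- list(
    list(rnorm(200), "normal"),
    list(rlnorm(200), "lognormal"),
    list(rgamma(200, 2, 1), "gamma"),
    list(rexp(200, 3), "exponential"),
    list(rchisq(200, 4), "chisq"),
    list(rbeta(200, 2, 5), "beta"),
    list(rweibull(200, 1.5, 2), "weibull"),
    list(runif(200), "triangular"),
    list(rlogis(200), "logistic"))
  for (cs in cases) {
    fm <- fit_marginal(cs[[1]], cs[[2]])
    expect_equal(fm$aic, 2 * length(fm$params) - 2 * fm$log_likelihood,
                 tolerance = 1e-12, info = cs[[2]])
  }
})

test_that("log-normal and gamma fits recover generating parameters", {
  set.seed(21)
  x <- rlnorm(5000, 0, 1)
  fm <- fit_marginal(x, "lognormal")
  # oracle: the closed-form MLE on log-values
  expect_equal(unname(fm$params["meanlog"]), mean(log(x)), tolerance = 1e-12)
  expect_equal(unname(fm$params["sdlog"]), sqrt(mean((log(x) - mean(log(x)))^2)),
               tolerance = 1e-12)
  # 3*SE at n = 5000: SE(meanlog) = 1/sqrt(n), SE(sdlog) = 1/sqrt(2n)
  expect_lt(abs(fm$params["meanlog"] - 0), 0.05)
  expect_lt(abs(fm$params["sdlog"] - 1), 0.05)

  # chi-square(2) is exponential(1/2), i.e. gamma(shape 1, scale 2)
  y <- rchisq(5000, df = 2)
  fg <- fit_marginal(y, "gamma")
  expect_lt(abs(fg$params["shape"] - 1), 0.06)
  expect_lt(abs(1 / fg$params["rate"] - 2), 0.15)
})

test_that("best_fit minimizes AIC, matching a direct log-likelihood oracle", {
  set.seed(31)
  for (truth in c("lognormal", "normal")) {
    x <- if (truth == "lognormal") rlnorm(5000, 0, 1) else rnorm(5000, 10, 1)
    sel <- best_fit(x, candidates = c("normal", "lognormal"))
    # oracle: both closed-form MLEs computed directly
    ll_norm <- sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE))
    lx <- log(x)
    ll_lnorm <- sum(dlnorm(x, mean(lx), sqrt(mean((lx - mean(lx))^2)),
                           log = TRUE))
    oracle <- if (4 - 2 * ll_norm < 4 - 2 * ll_lnorm) "normal" else "lognormal"
    expect_identical(sel$family, oracle)
    expect_identical(sel$family, truth)
  }
  # single candidate is just fit_marginal
  x <- rgamma(200, 3, 2)
  expect_equal(best_fit(x, candidates = "gamma"), fit_marginal(x, "gamma"))
})

test_that("infeasible families are skipped; all-infeasible is an error with reasons", {
  x <- c(rnorm(100), -5)   # negative values exclude positive-support families
  sel <- best_fit(x, candidates = c("normal", "lognormal", "gamma"))
  expect_identical(sel$family, "normal")
  err <- tryCatch(best_fit(x, candidates = c("lognormal", "gamma"),
                           column_name = "DMI"),
                  error = conditionMessage)
  expect_match(err, "DMI")
  expect_match(err, "positive")
})

test_that("sampling is reproducible, respects support, and matches analytic moments", {
  fm <- marginal_spec("beta", c(shape1 = 2, shape2 = 5), envelope = c(0, 1))
  expect_identical(sample_marginal(fm, 100, seed = 7),
                   sample_marginal(fm, 100, seed = 7))
  s <- sample_marginal(fm, 1e5, seed = 8)
  expect_lt(abs(mean(s) - 2 / 7), 0.005)   # analytic beta mean a/(a+b)
  expect_true(all(s > 0 & s < 1))
  for (f in c("lognormal", "triangular", "loglogistic")) {
    m <- switch(f,
      lognormal = marginal_spec("lognormal", c(0, 1)),
      triangular = marginal_spec("triangular", c(1, 5, 2)),
      loglogistic = marginal_spec("loglogistic", c(2, 3)))
    s <- sample_marginal(m, 1000, seed = 9)
    expect_true(all(s > m$support[1] & s < m$support[2]), info = f)
  }
  expect_error(sample_marginal(fm, 0), "positive integer")
})

test_that("degenerate zero-variance input is rejected at fit time", {
  expect_error(fit_marginal(rep(3, 20), "normal"), "zero variance")
  expect_error(fit_marginal(rep(2, 20), "lognormal"), "zero variance")
  expect_error(fit_marginal(c(1, NA, rep(2, 10)), "normal"), "finite")
  expect_error(fit_marginal(1:5, "normal"), "at least 10")
})

test_that("quantile and CDF are mutual inverses on interior grids", {
  specs <- list(
    marginal_spec("normal", c(2, 3)),
    marginal_spec("lognormal", c(0.5, 0.8)),
    marginal_spec("gamma", c(2, 1.5)),
    marginal_spec("exponential", 2),
    marginal_spec("chisq", 4),
    marginal_spec("beta", c(2, 5), envelope = c(0, 100)),
    marginal_spec("weibull", c(1.5, 2)),
    marginal_spec("loglogistic", c(2, 3)),
    marginal_spec("triangular", c(0, 10, 3)),
    marginal_spec("skewnormal", c(1, 2, 3)),
    marginal_spec("tls", c(0, 1, 5)),
    marginal_spec("logistic", c(1, 2)))
  for (m in specs) {
    fam <- ranksynth:::get_family(m$family)
    x <- fam$qfun(seq(0.1, 0.9, by = 0.2), m$params, m$support)
    back <- fam$qfun(fam$pfun(x, m$params, m$support), m$params, m$support)
    expect_lt(max(abs(back - x)), 1e-8)
  }
})

test_that("AIC family selection is invariant to location shifts", {
  set.seed(41)
  loc_families <- c("normal", "logistic", "skewnormal", "tls")
  x <- rlogis(800, 0, 1)
  a <- best_fit(x, candidates = loc_families)$family
  b <- best_fit(x + 1000, candidates = loc_families)$family
  expect_identical(a, b)
})

test_that("the marginal manifest round-trips through JSON", {
  set.seed(51)
  d <- data.frame(a = rlnorm(150), b = rnorm(150, 10, 2), c = rbeta(150, 2, 4))
  marg <- fit_marginals(d, mode = "best_fit",
                        candidates = c("normal", "lognormal", "gamma", "beta"))
  path <- tempfile(fileext = ".json")
  write_marginal_manifest(marg, path)
  back <- read_marginal_manifest(path)
  expect_identical(names(back), names(marg))
  for (nm in names(marg)) {
    expect_identical(back[[nm]]$family, marg[[nm]]$family)
    expect_equal(back[[nm]]$params, marg[[nm]]$params, tolerance = 1e-12)
    expect_equal(back[[nm]]$aic, marg[[nm]]$aic, tolerance = 1e-12)
    expect_equal(back[[nm]]$support, marg[[nm]]$support)
  }
})

test_that("the family registry accepts user families", {
  register_family("halfnormal_test", list(
    param_names = "sigma",
    support = function(p, e) c(0, Inf),
    feasible = function(x, e) if (any(x <= 0)) "positive values only" else NULL,
    dfun = function(x, p, s, log = FALSE) {
      lx <- log(2) + dnorm(x / p[1], log = TRUE) - log(p[1])
      if (log) lx else exp(lx)
    },
    pfun = function(q, p, s) 2 * pnorm(q / p[1]) - 1,
    qfun = function(pr, p, s) p[1] * qnorm((pr + 1) / 2),
    rfun = function(n, p, s) abs(rnorm(n, 0, p[1])),
    start = function(x, s) c(sigma = sqrt(mean(x^2))),
    to_theta = log, from_theta = exp))
  expect_true("halfnormal_test" %in% family_catalog())
  set.seed(61)
  fm <- fit_marginal(abs(rnorm(2000, 0, 2)), "halfnormal_test")
  expect_lt(abs(fm$params["sigma"] - 2), 0.15)
})
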
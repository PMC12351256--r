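# shared helpers for the test suite

# independent draws from the three benchmark marginals as a named table
benchmark_draws <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  marg <- default_benchmark_marginals()
  d <- as.data.frame(lapply(marg, function(m) sample_marginal(m, n)))
  names(d) <- names(marg)
  d
}

# brute-force Spearman rho of two vectors: Pearson correlation of ranks,
# computed from first principles (average ranks)
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# all four sample moments as a plain vector (for exact-identity comparisons)
moment_vec <- function(x) {
  m <- moments(x)
  c(m$mean, m$variance, m$skewness, m$kurtosis)
}

expect_permutation <- function(out, input) {
  for (nm in names(input)) {
    expect_identical(sort(out[[nm]]), sort(input[[nm]]))
  }
}
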
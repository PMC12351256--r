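#' Prediction-adequacy statistics
#'
#' Computes the agreement suite used to judge a predictor of a continuous
#' response: mean bias (MB), mean squared error of prediction (MSEP) and its
#' root, the three-component decomposition of MSEP into mean bias, slope bias
#' and random error, adjusted r-squared, Lin's concordance correlation
#' coefficient (CCC) and its accuracy factor C_b, plus AIC and the
#' degrees-of-freedom-corrected MSE.
#'
#' With population (n-denominator) standard deviations `s_obs`, `s_pred` and
#' Pearson correlation `r`:
#' \deqn{MB = \bar{o} - \bar{p}, \quad
#'       MSEP = MB^2 + (s_{pred} - r\,s_{obs})^2 + (1 - r^2)\,s_{obs}^2}
#' (the three components sum to MSEP identically), and
#' \deqn{CCC = \frac{2 r s_{obs} s_{pred}}{s_{obs}^2 + s_{pred}^2 + MB^2},
#'       \quad C_b = CCC / r.}
#' The sign convention MB = mean(observed) - mean(predicted) makes
#' underprediction positive. AIC is reported under the fixed convention
#' `n log(MSEP) + 2 (p + 1)`; comparisons are only meaningful within this
#' convention. `MSE = MSEP * n / (n - p)`.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 3), in the
#'   response's units (g CH4/d in the methane case).
#' @param p Parameter count of the predictor: predictors + 1 (intercept) for a
#'   linear model; for a random forest, which has no parameter count, the
#'   number of predictor variables is used as a documented stand-in. `p < n`.
#' @return An object of class `adequacy_report`: `n`, `p`, `mean_pred`,
#'   `mean_obs`, `sd_pred`, `sd_obs` (n-1 denominator, so labelled), `mb`,
#'   `msep`, `rmsep`, `mse`, `pct_mean_bias`, `pct_slope_bias`, `pct_random`,
#'   `r2`, `r2_adj`, `ccc`, `cb`, `aic`.
#'
#' When predictions equal observations exactly (MSEP = 0) the degenerate
#' conventions are: CCC = 1, C_b = 1, decomposition (0, 0, 100).
#' @examples
#' adequacy(c(10, 20, 30, 40), c(12, 18, 33, 37), p = 1)
#' @export
adequacy <- function(observed, predicted, p) {
  o <- as.numeric(observed)
  pr <- as.numeric(predicted)
  if (length(o) != length(pr)) stop("observed and predicted lengths differ")
  n <- length(o)
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(o)) || any(!is.finite(pr))) stop("values must be finite")
  if (p >= n) stop("p must be smaller than n")

  mb <- mean(o) - mean(pr)
  msep <- mean((o - pr)^2)
  so <- sqrt(mean((o - mean(o))^2))   # population SDs for the decomposition
  sp <- sqrt(mean((pr - mean(pr))^2))

  if (msep == 0) {
    r <- 1; ccc <- 1; cb <- 1
    pct <- c(0, 0, 100)
  } else {
    if (so == 0 || sp == 0) {
      stop("zero variance in ", if (so == 0) "observed" else "predicted",
           " values: correlation undefined")
    }
    r <- stats::cor(o, pr)
    comp <- c(mean_bias = mb^2,
              slope_bias = (sp - r * so)^2,
              random = (1 - r^2) * so^2)
    pct <- 100 * comp / msep
    ccc <- 2 * r * so * sp / (so^2 + sp^2 + mb^2)
    cb <- ccc / r
  }

  r2 <- r^2
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  aic <- if (msep == 0) -Inf else n * log(msep) + 2 * (p + 1)

  structure(list(
    n = n, p = as.integer(p),
    mean_pred = mean(pr), mean_obs = mean(o),
    sd_pred = stats::sd(pr), sd_obs = stats::sd(o),
    mb = mb, msep = msep, rmsep = sqrt(msep),
    mse = msep * n / (n - p),
    pct_mean_bias = unname(pct[1]), pct_slope_bias = unname(pct[2]),
    pct_random = unname(pct[3]),
    r2 = r2, r2_adj = r2_adj, ccc = ccc, cb = cb, aic = aic
  ), class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat("<adequacy_report> n =", x$n, " p =", x$p, "\n")
  cat(sprintf("  mean pred/obs: %.2f / %.2f   MB: %.3f\n",
              x$mean_pred, x$mean_obs, x$mb))
  cat(sprintf("  MSEP %.3f (RMSEP %.3f, MSE %.3f)\n", x$msep, x$rmsep, x$mse))
  cat(sprintf("  decomposition %%: mean bias %.1f | slope %.1f | random %.1f\n",
              x$pct_mean_bias, x$pct_slope_bias, x$pct_random))
  cat(sprintf("  r2 adj %.3f   CCC %.3f   C_b %.3f   AIC %.1f\n",
              x$r2_adj, x$ccc, x$cb, x$aic))
  invisible(x)
}

#' Ordinary least-squares fit
#'
#' Least-squares regression of `y` on the columns of `X` (intercept included)
#' via the QR decomposition used by `stats::lm`. In-sample fitted values from
#' this fit always have zero mean-bias and zero slope-bias components in
#' [adequacy()] -- the OLS orthogonality identity behind the 0/0/100 pattern
#' of linear models evaluated on their training data.
#'
#' @param y Numeric response.
#' @param X Data frame of numeric predictors, full column rank.
#' @return List with `coefficients`, `fitted_values`, `p` (number of estimated
#'   coefficients, intercept included) and `lm` (the underlying model object,
#'   usable with `predict`).
#' @export
ols_fit <- function(y, X) {
  X <- validate_data_table(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(y) <= ncol(X) + 1L) stop("need n > p")
  df <- cbind(data.frame(.y = as.numeric(y)), X)
  fit <- stats::lm(.y ~ ., data = df)
  if (fit$rank < ncol(X) + 1L) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  list(coefficients = stats::coef(fit),
       fitted_values = unname(stats::fitted(fit)),
       p = fit$rank,
       lm = fit)
}

#' Render adequacy reports as a statistics-by-scenario table
#'
#' Rows are the adequacy statistics, columns the scenarios -- the layout used
#' to compare models across synthetic databases.
#'
#' @param reports Named list of `adequacy_report` objects.
#' @return Data frame with one row per statistic.
#' @export
adequacy_table <- function(reports) {
  stopifnot(length(reports) > 0L, !is.null(names(reports)))
  rows <- c(n = "n", mean_pred = "Mean predicted", mean_obs = "Mean observed",
            mb = "MB", sd_pred = "SD predicted", sd_obs = "SD observed",
            rmsep = "RMSE", r2_adj = "r2", ccc = "CCC", cb = "Cb",
            mse = "MSE", pct_mean_bias = "MB,%", pct_slope_bias = "Slope,%",
            pct_random = "Random,%", aic = "AIC")
  out <- data.frame(statistic = unname(rows), stringsAsFactors = FALSE)
  for (nm in names(reports)) {
    r <- reports[[nm]]
    stopifnot(inherits(r, "adequacy_report"))
    out[[nm]] <- vapply(names(rows), function(f) as.numeric(r[[f]]),
                        numeric(1))
  }
  out
}
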
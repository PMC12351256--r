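#' Fit a parametric marginal distribution to one column
#'
#' Maximum-likelihood fit of a single catalog family to a numeric vector.
#' Families with closed-form MLEs (normal, lognormal, exponential) use them;
#' the rest are fitted numerically (Nelder-Mead, relative tolerance 1e-8) from
#' method-of-moments starting values, so fits are reproducible across
#' platforms.
#'
#' @param values Finite numeric vector, length >= 10, inside the family's
#'   support (strictly positive for lognormal/gamma/..., inside the declared
#'   envelope for beta).
#' @param family Family identifier; see [family_catalog()].
#' @param column_name Name attached to the fit (used in error messages and the
#'   manifest).
#' @param envelope Optional `(min, max)` rescaling envelope for the beta
#'   family. When omitted, `(0, 1)` is used for proportion-scale data and
#'   `(0, 100)` for percentage-scale data. The envelope is declared rather than
#'   estimated and is stored in the `support` field, not in `params`.
#' @return An object of class `fitted_marginal`: a list with `column_name`,
#'   `family`, `params` (named, canonical order), `support` (open interval),
#'   `log_likelihood`, `aic` (`2k - 2 logLik`, `k = length(params)`) and
#'   `n_fit`.
#' @examples
#' fm <- fit_marginal(rlnorm(500, 0, 1), "lognormal", column_name = "BW")
#' fm$aic
#' @seealso [best_fit()], [sample_marginal()]
#' @export
fit_marginal <- function(values, family, column_name = "x", envelope = NULL) {
  fam <- get_family(family)
  x <- as.numeric(values)
  if (any(!is.finite(x))) {
    stop("column '", column_name, "': values must be finite")
  }
  if (length(x) < 10L) {
    stop("column '", column_name, "': need at least 10 values to fit")
  }
  reason <- fam$feasible(x, envelope)
  if (!is.null(reason)) {
    stop("column '", column_name, "', family '", family, "': ", reason)
  }
  support_env <- if (family == "beta") .beta_envelope(x, envelope) else NULL

  if (!is.null(fam$fit)) {
    res <- fam$fit(x, support_env)
    params <- res$params
    loglik <- res$loglik
  } else {
    start <- fam$start(x, support_env)
    theta0 <- fam$to_theta(start)
    nll <- function(theta) {
      par <- fam$from_theta(theta)
      ll <- sum(fam$dfun(x, par, support_env, log = TRUE))
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    if (length(theta0) == 1L) {
      opt <- stats::optimize(nll, interval = theta0 + c(-15, 15), tol = 1e-10)
      theta_hat <- opt$minimum
      value <- opt$objective
    } else {
      opt <- stats::optim(theta0, nll, method = "Nelder-Mead",
                          control = list(reltol = 1e-8, maxit = 10000L))
      if (opt$convergence != 0L) {
        stop("column '", column_name, "', family '", family,
             "': MLE did not converge (optim code ", opt$convergence,
             ", ", opt$counts[1], " evaluations, message: ",
             if (is.null(opt$message)) "none" else opt$message, ")")
      }
      theta_hat <- opt$par
      value <- opt$value
    }
    params <- fam$from_theta(theta_hat)
    names(params) <- fam$param_names
    loglik <- -value
  }

  k <- length(params)
  structure(list(
    column_name = column_name,
    family = family,
    params = params,
    support = fam$support(params, support_env),
    log_likelihood = loglik,
    aic = 2 * k - 2 * loglik,
    n_fit = length(x)
  ), class = "fitted_marginal")
}

#' @export
print.fitted_marginal <- function(x, ...) {
  cat("<fitted_marginal> ", x$column_name, " ~ ", x$family, "(",
      paste(sprintf("%s=%.4g", names(x$params), x$params), collapse = ", "),
      ")\n", sep = "")
  cat(sprintf("  support (%g, %g); logLik %.3f; AIC %.3f; n %d\n",
              x$support[1], x$support[2], x$log_likelihood, x$aic, x$n_fit))
  invisible(x)
}

#' Select the best-fitting family by AIC
#'
#' Fits every candidate family whose support admits the data and returns the
#' fit with the smallest AIC. Ties are broken by fewer parameters, then by
#' catalog order. Candidates whose support excludes the data (or whose
#' optimizer fails) are skipped, not errors.
#'
#' @inheritParams fit_marginal
#' @param candidates Character vector of family identifiers (default: the full
#'   catalog).
#' @return A `fitted_marginal` (see [fit_marginal()]).
#' @examples
#' x <- rlnorm(1000, 0, 1)
#' best_fit(x, candidates = c("normal", "lognormal"))$family
#' @export
best_fit <- function(values, candidates = family_catalog(), column_name = "x",
                     envelope = NULL) {
  if (length(candidates) == 0L) stop("no candidate families given")
  catalog <- family_catalog()
  unknown <- setdiff(candidates, catalog)
  if (length(unknown) > 0L) {
    stop("unknown families: ", paste(unknown, collapse = ", "))
  }
  candidates <- catalog[catalog %in% candidates]  # catalog order
  fits <- list()
  skips <- character()
  for (fam_name in candidates) {
    res <- tryCatch(
      fit_marginal(values, fam_name, column_name = column_name,
                   envelope = envelope),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skips[fam_name] <- res
    } else {
      fits[[fam_name]] <- res
    }
  }
  if (length(fits) == 0L) {
    stop("column '", column_name, "': no candidate family is feasible:\n",
         paste(sprintf("  %s: %s", names(skips), skips), collapse = "\n"))
  }
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ks <- vapply(fits, function(f) length(f$params), numeric(1))
  ord <- order(aics, ks, seq_along(fits))
  fits[[ord[1]]]
}

#' Sample from a fitted marginal
#'
#' @param m A `fitted_marginal`.
#' @param n Number of i.i.d. draws (>= 1).
#' @param seed Integer seed; the draw is reproducible for a fixed seed. `NULL`
#'   continues the current RNG stream.
#' @return Numeric vector of length `n`, all values inside the support.
#' @examples
#' fm <- fit_marginal(rgamma(200, 2, 1), "gamma")
#' s1 <- sample_marginal(fm, 5, seed = 1)
#' s2 <- sample_marginal(fm, 5, seed = 1)
#' identical(s1, s2)
#' @export
sample_marginal <- function(m, n, seed = NULL) {
  stopifnot(inherits(m, "fitted_marginal"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("n must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  fam <- get_family(m$family)
  fam$rfun(n, m$params, m$support)
}

#' Fit marginals to every column of a table
#'
#' @param data Data frame of numeric columns (no missing values).
#' @param mode `"normal_only"` fits a normal to every column; `"best_fit"`
#'   selects per column by AIC among `candidates`.
#' @param candidates Families considered in `"best_fit"` mode.
#' @param envelopes Optional named list of beta envelopes per column.
#' @return Named list of `fitted_marginal` objects, one per column.
#' @export
fit_marginals <- function(data, mode = c("best_fit", "normal_only"),
                          candidates = family_catalog(), envelopes = list()) {
  mode <- match.arg(mode)
  data <- validate_data_table(data)
  out <- lapply(names(data), function(nm) {
    env <- envelopes[[nm]]
    if (mode == "normal_only") {
      fit_marginal(data[[nm]], "normal", column_name = nm)
    } else {
      best_fit(data[[nm]], candidates = candidates, column_name = nm,
               envelope = env)
    }
  })
  names(out) <- names(data)
  out
}

#' Write / read a fitted-marginal manifest (JSON)
#'
#' The manifest maps each column to its family, parameters, support, AIC and
#' fit size, and round-trips through [read_marginal_manifest()].
#'
#' @param marginals Named list of `fitted_marginal` objects.
#' @param path File path for the JSON manifest.
#' @return `path` invisibly (write); a named list of `fitted_marginal` (read).
#' @export
write_marginal_manifest <- function(marginals, path) {
  entries <- lapply(marginals, function(m) {
    list(column = m$column_name, family = m$family,
         params = as.list(m$params), support = m$support,
         log_likelihood = m$log_likelihood, aic = m$aic, n_fit = m$n_fit)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_marginal_manifest
#' @export
read_marginal_manifest <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(entries, function(e) {
    structure(list(
      column_name = e$column,
      family = e$family,
      params = unlist(e$params),
      support = as.numeric(unlist(e$support)),
      log_likelihood = as.numeric(e$log_likelihood),
      aic = as.numeric(e$aic),
      n_fit = as.integer(e$n_fit)
    ), class = "fitted_marginal")
  })
  names(out) <- vapply(out, function(m) m$column_name, character(1))
  out
}

#' Build a marginal specification without fitting
#'
#' Convenience constructor for a `fitted_marginal` with known parameters (no
#' data), used e.g. for declarative, data-free synthesis and for the fixture
#' generator. `log_likelihood` and `aic` are `NA`.
#'
#' @param family Family identifier.
#' @param params Named parameter vector in the family's canonical order.
#' @param column_name Column the marginal describes.
#' @param envelope Beta rescaling envelope, when `family = "beta"`.
#' @return A `fitted_marginal`.
#' @examples
#' marginal_spec("gamma", c(shape = 12, rate = 12 / 130), "CH4")
#' @export
marginal_spec <- function(family, params, column_name = "x", envelope = NULL) {
  fam <- get_family(family)
  if (length(params) != length(fam$param_names)) {
    stop("family '", family, "' needs parameters: ",
         paste(fam$param_names, collapse = ", "))
  }
  params <- stats::setNames(as.numeric(params), fam$param_names)
  if (family == "beta" && is.null(envelope)) envelope <- c(0, 1)
  structure(list(
    column_name = column_name, family = family, params = params,
    support = fam$support(params, envelope),
    log_likelihood = NA_real_, aic = NA_real_, n_fit = NA_integer_
  ), class = "fitted_marginal")
}
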
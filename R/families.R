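#' @title Parametric family catalog
#' @description The catalog of continuous distribution families available for
#' marginal fitting. Each family is registered with its canonical
#' parameterization, density/CDF/quantile/sampler, a method-of-moments
#' starting-value rule and (where one exists) a closed-form maximum-likelihood
#' fit. The catalog is a registry: [register_family()] adds user families.
#'
#' Families are listed in catalog order, which is also the tie-break order of
#' [best_fit()]: normal, lognormal, gamma, exponential, chisq, beta, weibull,
#' loglogistic, triangular, skewnormal, tls (Student-t location-scale),
#' logistic.
#' @return `family_catalog()` returns the character vector of registered
#'   family names, in registration order.
#' @examples
#' family_catalog()
#' @export
family_catalog <- function() {
  get(".families", envir = .ranksynth_registry)$order
}

.ranksynth_registry <- new.env(parent = emptyenv())
assign(".families", list(order = character(), defs = list()),
       envir = .ranksynth_registry)

#' Register a distribution family
#'
#' Adds (or replaces) a family definition in the catalog used by
#' [fit_marginal()] and [best_fit()].
#'
#' @param name Family identifier (single string).
#' @param def A list with elements:
#' \describe{
#'   \item{param_names}{character vector of parameter names (canonical order).}
#'   \item{support}{`function(params, envelope)` returning the open interval
#'     `c(lower, upper)` of the fitted density.}
#'   \item{feasible}{`function(x, envelope)` returning `NULL` when the data are
#'     inside the family's support, otherwise a reason string.}
#'   \item{dfun, pfun, qfun, rfun}{density, CDF, quantile and sampler, each
#'     taking `(x|q|p|n, params, support)`.}
#'   \item{start}{`function(x, support)` method-of-moments starting values.}
#'   \item{fit}{optional `function(x, support)` closed-form MLE returning
#'     `list(params, loglik)`; when absent the generic numerical MLE is used.}
#'   \item{to_theta, from_theta}{transforms between the constrained parameter
#'     vector and the unconstrained optimizer scale (required unless `fit` is
#'     supplied).}
#' }
#' @return `name`, invisibly.
#' @export
register_family <- function(name, def) {
  stopifnot(is.character(name), length(name) == 1L, is.list(def))
  needed <- c("param_names", "support", "feasible", "dfun", "pfun", "qfun",
              "rfun", "start")
  missing <- setdiff(needed, names(def))
  if (length(missing) > 0L) {
    stop("family definition for '", name, "' lacks: ",
         paste(missing, collapse = ", "))
  }
  reg <- get(".families", envir = .ranksynth_registry)
  if (!name %in% reg$order) reg$order <- c(reg$order, name)
  reg$defs[[name]] <- def
  assign(".families", reg, envir = .ranksynth_registry)
  invisible(name)
}

get_family <- function(name) {
  reg <- get(".families", envir = .ranksynth_registry)
  if (!name %in% reg$order) {
    stop("unknown family '", name, "'; catalog: ",
         paste(reg$order, collapse = ", "))
  }
  reg$defs[[name]]
}

# -- feasibility helpers -------------------------------------------------------

.feas_positive <- function(x, envelope) {
  if (any(x <= 0)) "requires strictly positive values" else NULL
}
.feas_real <- function(x, envelope) NULL

# default envelope for bounded (beta) data: (0,1) for proportions, (0,100)
# for percentage-scale data, otherwise the caller must declare one
.beta_envelope <- function(x, envelope) {
  if (!is.null(envelope)) {
    if (length(envelope) != 2L || !all(is.finite(envelope)) ||
        envelope[1] >= envelope[2]) {
      stop("beta envelope must be a finite (min, max) pair with min < max")
    }
    return(as.numeric(envelope))
  }
  if (all(x > 0 & x < 1)) c(0, 1)
  else if (all(x > 0 & x < 100)) c(0, 100)
  else NULL
}

# -- registrations -------------------------------------------------------------

register_family("normal", list(
  param_names = c("mean", "sd"),
  support = function(params, envelope) c(-Inf, Inf),
  feasible = .feas_real,
  dfun = function(x, p, s, log = FALSE) stats::dnorm(x, p[1], p[2], log = log),
  pfun = function(q, p, s) stats::pnorm(q, p[1], p[2]),
  qfun = function(pr, p, s) stats::qnorm(pr, p[1], p[2]),
  rfun = function(n, p, s) stats::rnorm(n, p[1], p[2]),
  start = function(x, s) c(mean = mean(x), sd = stats::sd(x)),
  fit = function(x, s) {
    m <- mean(x)
    sd_ml <- sqrt(mean((x - m)^2))   # 1/n denominator: the Gaussian MLE
    if (sd_ml == 0) stop("degenerate sample: zero variance")
    list(params = c(mean = m, sd = sd_ml),
         loglik = sum(stats::dnorm(x, m, sd_ml, log = TRUE)))
  }
))

register_family("lognormal", list(
  param_names = c("meanlog", "sdlog"),
  support = function(params, envelope) c(0, Inf),
  feasible = .feas_positive,
  dfun = function(x, p, s, log = FALSE) stats::dlnorm(x, p[1], p[2], log = log),
  pfun = function(q, p, s) stats::plnorm(q, p[1], p[2]),
  qfun = function(pr, p, s) stats::qlnorm(pr, p[1], p[2]),
  rfun = function(n, p, s) stats::rlnorm(n, p[1], p[2]),
  start = function(x, s) c(meanlog = mean(log(x)), sdlog = stats::sd(log(x))),
  fit = function(x, s) {
    lx <- log(x)
    m <- mean(lx)
    sd_ml <- sqrt(mean((lx - m)^2))
    if (sd_ml == 0) stop("degenerate sample: zero variance on the log scale")
    list(params = c(meanlog = m, sdlog = sd_ml),
         loglik = sum(stats::dlnorm(x, m, sd_ml, log = TRUE)))
  }
))

register_family("gamma", list(
  param_names = c("shape", "rate"),
  support = function(params, envelope) c(0, Inf),
  feasible = .feas_positive,
  dfun = function(x, p, s, log = FALSE) {
    stats::dgamma(x, shape = p[1], rate = p[2], log = log)
  },
  pfun = function(q, p, s) stats::pgamma(q, shape = p[1], rate = p[2]),
  qfun = function(pr, p, s) stats::qgamma(pr, shape = p[1], rate = p[2]),
  rfun = function(n, p, s) stats::rgamma(n, shape = p[1], rate = p[2]),
  start = function(x, s) {
    m <- mean(x); v <- stats::var(x)
    c(shape = m^2 / v, rate = m / v)
  },
  to_theta = function(p) log(p),
  from_theta = function(th) exp(th)
))

register_family("exponential", list(
  param_names = "rate",
  support = function(params, envelope) c(0, Inf),
  feasible = .feas_positive,
  dfun = function(x, p, s, log = FALSE) stats::dexp(x, p[1], log = log),
  pfun = function(q, p, s) stats::pexp(q, p[1]),
  qfun = function(pr, p, s) stats::qexp(pr, p[1]),
  rfun = function(n, p, s) stats::rexp(n, p[1]),
  start = function(x, s) c(rate = 1 / mean(x)),
  fit = function(x, s) {
    rate <- 1 / mean(x)
    list(params = c(rate = rate), loglik = sum(stats::dexp(x, rate, log = TRUE)))
  }
))

register_family("chisq", list(
  param_names = "df",
  support = function(params, envelope) c(0, Inf),
  feasible = .feas_positive,
  dfun = function(x, p, s, log = FALSE) stats::dchisq(x, df = p[1], log = log),
  pfun = function(q, p, s) stats::pchisq(q, df = p[1]),
  qfun = function(pr, p, s) stats::qchisq(pr, df = p[1]),
  rfun = function(n, p, s) stats::rchisq(n, df = p[1]),
  start = function(x, s) c(df = mean(x)),   # E[X] = df
  to_theta = function(p) log(p),
  from_theta = function(th) exp(th)
))

register_family("beta", list(
  param_names = c("shape1", "shape2"),
  # support doubles as the declared rescaling envelope (diet percentages live
  # in (0, 100)); the envelope is declared, not estimated, so k stays 2
  support = function(params, envelope) envelope,
  feasible = function(x, envelope) {
    env <- .beta_envelope(x, envelope)
    if (is.null(env)) {
      return("values outside (0, 1) and (0, 100); declare a (min, max) envelope")
    }
    if (any(x <= env[1] | x >= env[2])) {
      return(sprintf("values outside the declared envelope (%g, %g)",
                     env[1], env[2]))
    }
    NULL
  },
  dfun = function(x, p, s, log = FALSE) {
    w <- s[2] - s[1]
    d <- stats::dbeta((x - s[1]) / w, p[1], p[2], log = log)
    if (log) d - log(w) else d / w
  },
  pfun = function(q, p, s) stats::pbeta((q - s[1]) / (s[2] - s[1]), p[1], p[2]),
  qfun = function(pr, p, s) s[1] + (s[2] - s[1]) * stats::qbeta(pr, p[1], p[2]),
  rfun = function(n, p, s) s[1] + (s[2] - s[1]) * stats::rbeta(n, p[1], p[2]),
  start = function(x, s) {
    y <- (x - s[1]) / (s[2] - s[1])
    m <- mean(y); v <- stats::var(y)
    v <- min(v, m * (1 - m) * 0.999)  # keep the MoM shapes positive
    c(shape1 = m * (m * (1 - m) / v - 1),
      shape2 = (1 - m) * (m * (1 - m) / v - 1))
  },
  to_theta = function(p) log(p),
  from_theta = function(th) exp(th)
))

register_family("weibull", list(
  param_names = c("shape", "scale"),
  support = function(params, envelope) c(0, Inf),
  feasible = .feas_positive,
  dfun = function(x, p, s, log = FALSE) stats::dweibull(x, p[1], p[2], log = log),
  pfun = function(q, p, s) stats::pweibull(q, p[1], p[2]),
  qfun = function(pr, p, s) stats::qweibull(pr, p[1], p[2]),
  rfun = function(n, p, s) stats::rweibull(n, p[1], p[2]),
  start = function(x, s) {
    cv <- stats::sd(x) / mean(x)
    shape <- cv^(-1.086)              # Justus' moment approximation
    c(shape = shape, scale = mean(x) / gamma(1 + 1 / shape))
  },
  to_theta = function(p) log(p),
  from_theta = function(th) exp(th)
))

register_family("loglogistic", list(
  param_names = c("scale", "shape"),
  support = function(params, envelope) c(0, Inf),
  feasible = .feas_positive,
  dfun = function(x, p, s, log = FALSE) {
    a <- p[1]; b <- p[2]
    lx <- log(b) - log(a) + (b - 1) * (log(x) - log(a)) -
      2 * log1p((x / a)^b)
    if (log) lx else exp(lx)
  },
  pfun = function(q, p, s) 1 / (1 + (q / p[1])^(-p[2])),
  qfun = function(pr, p, s) p[1] * (pr / (1 - pr))^(1 / p[2]),
  rfun = function(n, p, s) {
    u <- stats::runif(n)
    p[1] * (u / (1 - u))^(1 / p[2])
  },
  start = function(x, s) {
    # log X ~ logistic(log scale, 1/shape)
    lx <- log(x)
    c(scale = exp(mean(lx)), shape = pi / (stats::sd(lx) * sqrt(3)))
  },
  to_theta = function(p) log(p),
  from_theta = function(th) exp(th)
))

register_family("triangular", list(
  param_names = c("min", "max", "mode"),
  support = function(params, envelope) c(params[1], params[2]),
  feasible = .feas_real,
  dfun = function(x, p, s, log = FALSE) {
    a <- p[1]; b <- p[2]; cc <- p[3]
    d <- ifelse(x < a | x > b, 0,
         ifelse(x < cc, 2 * (x - a) / ((b - a) * (cc - a)),
                        2 * (b - x) / ((b - a) * (b - cc))))
    if (log) log(d) else d
  },
  pfun = function(q, p, s) {
    a <- p[1]; b <- p[2]; cc <- p[3]
    ifelse(q <= a, 0,
    ifelse(q >= b, 1,
    ifelse(q < cc, (q - a)^2 / ((b - a) * (cc - a)),
                   1 - (b - q)^2 / ((b - a) * (b - cc)))))
  },
  qfun = function(pr, p, s) {
    a <- p[1]; b <- p[2]; cc <- p[3]
    fc <- (cc - a) / (b - a)
    ifelse(pr < fc, a + sqrt(pr * (b - a) * (cc - a)),
                    b - sqrt((1 - pr) * (b - a) * (b - cc)))
  },
  rfun = function(n, p, s) {
    get_family("triangular")$qfun(stats::runif(n), p, s)
  },
  start = function(x, s) {
    d <- (max(x) - min(x)) / length(x)
    c(min = min(x) - d, max = max(x) + d, mode = stats::median(x))
  },
  # min/max sit at the (slightly widened) sample range -- boundary MLEs; the
  # mode is profiled by 1-D search
  fit = function(x, s) {
    d <- (max(x) - min(x)) / length(x)
    a <- min(x) - d; b <- max(x) + d
    fam <- get_family("triangular")
    ll <- function(cc) sum(fam$dfun(x, c(a, b, cc), NULL, log = TRUE))
    opt <- stats::optimize(ll, interval = c(a + d / 2, b - d / 2),
                           maximum = TRUE, tol = 1e-8)
    list(params = c(min = a, max = b, mode = opt$maximum),
         loglik = opt$objective)
  }
))

.sn_dfun <- function(x, p, s, log = FALSE) {
  z <- (x - p[1]) / p[2]
  lx <- log(2) - log(p[2]) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(p[3] * z, log.p = TRUE)
  if (log) lx else exp(lx)
}

register_family("skewnormal", list(
  param_names = c("location", "scale", "alpha"),
  support = function(params, envelope) c(-Inf, Inf),
  feasible = .feas_real,
  dfun = .sn_dfun,
  pfun = function(q, p, s) {
    vapply(q, function(qi) {
      # integrate from the location outward; the density is smooth
      lo <- p[1] - 12 * p[2]
      if (qi <= lo) return(0)
      stats::integrate(.sn_dfun, lo, qi, p = p, s = s,
                       rel.tol = 1e-12, subdivisions = 500L)$value
    }, numeric(1))
  },
  qfun = function(pr, p, s) {
    fam <- get_family("skewnormal")
    vapply(pr, function(pi_) {
      stats::uniroot(function(x) fam$pfun(x, p, s) - pi_,
                     lower = p[1] - 12 * p[2], upper = p[1] + 12 * p[2],
                     tol = 1e-12, extendInt = "upX")$root
    }, numeric(1))
  },
  rfun = function(n, p, s) {
    delta <- p[3] / sqrt(1 + p[3]^2)
    u0 <- stats::rnorm(n); u1 <- stats::rnorm(n)
    p[1] + p[2] * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
  },
  start = function(x, s) {
    m <- mean(x); v <- stats::var(x)
    n <- length(x)
    g1 <- (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
    c1 <- min(abs(g1), 0.95)^(2 / 3)
    delta <- sign(g1) * sqrt((pi / 2) * c1 / (c1 + ((4 - pi) / 2)^(2 / 3)))
    delta <- max(min(delta, 0.995), -0.995)
    b <- sqrt(2 / pi)
    omega <- sqrt(v / max(1 - b^2 * delta^2, 1e-6))
    c(location = m - omega * delta * b, scale = omega,
      alpha = delta / sqrt(1 - delta^2))
  },
  to_theta = function(p) c(p[1], log(p[2]), p[3]),
  from_theta = function(th) c(th[1], exp(th[2]), th[3])
))

register_family("tls", list(
  param_names = c("location", "scale", "df"),
  support = function(params, envelope) c(-Inf, Inf),
  feasible = .feas_real,
  dfun = function(x, p, s, log = FALSE) {
    lx <- stats::dt((x - p[1]) / p[2], df = p[3], log = TRUE) - log(p[2])
    if (log) lx else exp(lx)
  },
  pfun = function(q, p, s) stats::pt((q - p[1]) / p[2], df = p[3]),
  qfun = function(pr, p, s) p[1] + p[2] * stats::qt(pr, df = p[3]),
  rfun = function(n, p, s) p[1] + p[2] * stats::rt(n, df = p[3]),
  start = function(x, s) {
    c(location = stats::median(x),
      scale = max(stats::IQR(x) / 1.349, 1e-8), df = 8)
  },
  to_theta = function(p) c(p[1], log(p[2]), log(p[3])),
  from_theta = function(th) c(th[1], exp(th[2]), exp(th[3]))
))

register_family("logistic", list(
  param_names = c("location", "scale"),
  support = function(params, envelope) c(-Inf, Inf),
  feasible = .feas_real,
  dfun = function(x, p, s, log = FALSE) stats::dlogis(x, p[1], p[2], log = log),
  pfun = function(q, p, s) stats::plogis(q, p[1], p[2]),
  qfun = function(pr, p, s) stats::qlogis(pr, p[1], p[2]),
  rfun = function(n, p, s) stats::rlogis(n, p[1], p[2]),
  start = function(x, s) {
    c(location = mean(x), scale = stats::sd(x) * sqrt(3) / pi)
  },
  to_theta = function(p) c(p[1], log(p[2])),
  from_theta = function(th) c(th[1], exp(th[2]))
))
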
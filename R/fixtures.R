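#' Default Spearman target of the methane fixture
#'
#' A hand-designed positive-definite 9 x 9 rank-correlation matrix over the
#' methane-study variables (BW, DMI, CP, NDF, EE, starch, ADF, ash, CH4).
#' The values are artifact defaults chosen to be biologically sensible --
#' strong DMI-CH4 (0.8) and BW-DMI (0.7) monotone associations, tightly
#' coupled fiber fractions (NDF-ADF 0.85), fiber-starch antagonism -- not
#' values taken from any published database.
#'
#' @return A [spearman_target()].
#' @export
methane_target <- function() {
  vars <- c("BW", "DMI", "CP", "NDF", "EE", "starch", "ADF", "ash", "CH4")
  m <- matrix(c(
    1.00, 0.70, 0.10, -0.10, 0.05, 0.15, -0.10, 0.05, 0.55,
    0.70, 1.00, 0.25, -0.30, 0.10, 0.35, -0.30, 0.00, 0.80,
    0.10, 0.25, 1.00, -0.20, 0.15, 0.10, -0.20, 0.20, 0.20,
   -0.10, -0.30, -0.20, 1.00, -0.10, -0.60, 0.85, 0.30, -0.25,
    0.05, 0.10, 0.15, -0.10, 1.00, 0.05, -0.10, 0.00, -0.15,
    0.15, 0.35, 0.10, -0.60, 0.05, 1.00, -0.55, -0.35, 0.30,
   -0.10, -0.30, -0.20, 0.85, -0.10, -0.55, 1.00, 0.25, -0.25,
    0.05, 0.00, 0.20, 0.30, 0.00, -0.35, 0.25, 1.00, -0.10,
    0.55, 0.80, 0.20, -0.25, -0.15, 0.30, -0.25, -0.10, 1.00), 9, 9)
  spearman_target(m, vars)
}

#' Default marginal specifications of the methane fixture
#'
#' Right-skewed and bounded families shaped like diet-composition data:
#' BW lognormal (kg), DMI and CH4 gamma (kg/d, g/d), diet components beta on
#' the (0, 100) percentage envelope. Parameter values are artifact choices
#' (mean BW ~460 kg, DMI ~8 kg/d, CH4 ~130 g/d, CP ~14, NDF ~40, EE ~3.5,
#' starch ~25, ADF ~22, ash ~7 %DM), not estimates from any published
#' database.
#'
#' @return Named list of marginal specs (see [marginal_spec()]).
#' @export
methane_marginals <- function() {
  pct <- c(0, 100)
  list(
    BW = marginal_spec("lognormal", c(meanlog = log(450), sdlog = 0.25), "BW"),
    DMI = marginal_spec("gamma", c(shape = 25, rate = 25 / 8), "DMI"),
    CP = marginal_spec("beta", c(shape1 = 6, shape2 = 37), "CP", pct),
    NDF = marginal_spec("beta", c(shape1 = 8, shape2 = 12), "NDF", pct),
    EE = marginal_spec("beta", c(shape1 = 4, shape2 = 110), "EE", pct),
    starch = marginal_spec("beta", c(shape1 = 5, shape2 = 15), "starch", pct),
    ADF = marginal_spec("beta", c(shape1 = 6, shape2 = 21), "ADF", pct),
    ash = marginal_spec("beta", c(shape1 = 8, shape2 = 106), "ash", pct),
    CH4 = marginal_spec("gamma", c(shape = 12, rate = 12 / 130), "CH4")
  )
}

#' Biological-plausibility constraints of the methane workflow
#'
#' The cleaning rules of the case study: diet components (CP, EE, starch,
#' NDF, ADF, ash) strictly between 0 and 100 %DM; ADF below NDF; and the sum
#' of CP, EE, ash, NDF and starch below 100.
#'
#' @return A [constraint_set()].
#' @export
methane_constraints <- function() {
  comps <- c("CP", "EE", "starch", "NDF", "ADF", "ash")
  constraint_set(
    bounds = data.frame(column = comps, lower = 0, upper = 100),
    order_pairs = data.frame(lesser = "ADF", greater = "NDF"),
    sum_caps = list(list(columns = c("CP", "EE", "ash", "NDF", "starch"),
                         cap = 100)))
}

#' Specification of the synthetic methane stand-in database
#'
#' Declares the stand-in for the compiled literature database: row count
#' (default 263, the compiled database's size), per-variable marginals,
#' Spearman target and seed. The stand-in is synthetic: its families and
#' matrix values are artifact defaults, labelled as such, chosen so that the
#' implied constraints are satisfiable with a high acceptance rate and the
#' DMI-CH4 association gives importance analyses a known ground truth.
#'
#' @param n_rows Number of records (default 263).
#' @param marginals Named marginal specs (default [methane_marginals()]).
#' @param target A [spearman_target()] (default [methane_target()]).
#' @param constraints A [constraint_set()] (default [methane_constraints()]).
#' @param seed Integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_rows = 263L, marginals = methane_marginals(),
                         target = methane_target(),
                         constraints = methane_constraints(), seed = 42L) {
  stopifnot(inherits(target, "spearman_target"),
            inherits(constraints, "constraint_set"))
  miss <- setdiff(target$columns, names(marginals))
  if (length(miss) > 0L) {
    stop("marginals missing for columns: ", paste(miss, collapse = ", "))
  }
  structure(list(n_rows = as.integer(n_rows), marginals = marginals,
                 target = target, constraints = constraints,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate the synthetic methane stand-in table
#'
#' Draws independent columns from the spec's marginals, imposes the Spearman
#' target by the rank-based method, cleans with the spec's constraints and
#' returns the first `n_rows` surviving rows. Errors when the constraint
#' acceptance rate falls below 10% (the spec should then be revised) or when
#' too few rows survive.
#'
#' @param spec A [fixture_spec()].
#' @return Data frame with `spec$n_rows` rows satisfying all constraints;
#'   reproducible for a fixed spec seed.
#' @examples
#' d <- make_methane_fixture(fixture_spec(n_rows = 100))
#' nrow(d)
#' @export
make_methane_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_gen <- max(3L * spec$n_rows, 500L)
  set.seed(spec$seed)
  cols <- spec$target$columns
  raw <- as.data.frame(lapply(spec$marginals[cols], function(m) {
    sample_marginal(m, n_gen)
  }))
  names(raw) <- cols
  correlated <- impose_rank_correlation(raw, spec$target)
  cleaned <- apply_constraints(correlated, spec$constraints)
  rate <- nrow(cleaned$data) / n_gen
  if (rate < 0.10) {
    stop(sprintf(paste0("constraint acceptance rate %.1f%% is below the 10%%",
                        " floor; revise the fixture spec"), 100 * rate))
  }
  if (nrow(cleaned$data) < spec$n_rows) {
    stop("only ", nrow(cleaned$data), " rows survive cleaning; need ",
         spec$n_rows)
  }
  out <- cleaned$data[seq_len(spec$n_rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deterministic toy tables for examples and tests
#'
#' Small hand-built tables: `adf_ndf` -- a 5-row table in which exactly rows 2
#' and 4 violate ADF < NDF; `sum_cap` -- a 3-row table whose second row's diet
#' components sum to 101; `adequacy` -- the 4-point observed/predicted pair
#' used to exercise the adequacy statistics; `spearman` -- the 3-point pair
#' with rank correlation exactly 0.5.
#'
#' @return Named list of data frames / vectors.
#' @export
make_toy_tables <- function() {
  list(
    adf_ndf = data.frame(
      ADF = c(20, 45, 18, 33, 25),
      NDF = c(40, 40, 35, 30, 42)),
    sum_cap = data.frame(
      CP = c(14, 30, 12), EE = c(3, 20, 4), ash = c(7, 11, 6),
      NDF = c(40, 25, 38), starch = c(25, 15, 22)),
    adequacy = list(observed = c(10, 20, 30, 40),
                    predicted = c(12, 18, 33, 37)),
    spearman = data.frame(x = c(1, 2, 3), y = c(2, 1, 3))
  )
}
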
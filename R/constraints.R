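#' Declare a set of cleaning constraints
#'
#' A `constraint_set` is the declarative description of the
#' biological-plausibility cleaning step: open support bounds per column,
#' pairwise order constraints (e.g. ADF < NDF), sum caps over column groups
#' (e.g. CP + EE + ash + NDF + starch < 100) and statistical outlier rules.
#' Rows violating any deterministic constraint are dropped, never edited.
#'
#' @param bounds Data frame (or list coercible to one) with columns `column`,
#'   `lower`, `upper`: rows must satisfy `lower < x < upper` (open interval).
#' @param order_pairs Data frame with columns `lesser`, `greater`: rows must
#'   satisfy `lesser < greater`.
#' @param sum_caps List of `list(columns = <chr>, cap = <num>)`: rows must
#'   satisfy `sum(columns) < cap`. Caps must be strictly positive.
#' @param outlier_rules Data frame with columns `column`, `method`
#'   (`"zscore"` or `"iqr"`) and `threshold` (strictly positive).
#' @return An object of class `constraint_set`.
#' @examples
#' cs <- constraint_set(
#'   bounds = data.frame(column = "NDF", lower = 0, upper = 100),
#'   order_pairs = data.frame(lesser = "ADF", greater = "NDF"))
#' @export
constraint_set <- function(bounds = NULL, order_pairs = NULL, sum_caps = NULL,
                           outlier_rules = NULL) {
  if (!is.null(bounds)) {
    bounds <- as.data.frame(bounds, stringsAsFactors = FALSE)
    stopifnot(all(c("column", "lower", "upper") %in% names(bounds)))
  }
  if (!is.null(order_pairs)) {
    order_pairs <- as.data.frame(order_pairs, stringsAsFactors = FALSE)
    stopifnot(all(c("lesser", "greater") %in% names(order_pairs)))
  }
  if (!is.null(sum_caps)) {
    stopifnot(is.list(sum_caps))
    for (sc in sum_caps) {
      stopifnot(is.character(sc$columns), length(sc$columns) >= 1L,
                is.numeric(sc$cap), length(sc$cap) == 1L)
      if (sc$cap <= 0) stop("sum caps must be strictly positive")
    }
  }
  if (!is.null(outlier_rules)) {
    outlier_rules <- as.data.frame(outlier_rules, stringsAsFactors = FALSE)
    stopifnot(all(c("column", "method", "threshold") %in% names(outlier_rules)))
    if (!all(outlier_rules$method %in% c("zscore", "iqr"))) {
      stop("outlier methods must be 'zscore' or 'iqr'")
    }
    if (any(outlier_rules$threshold <= 0)) {
      stop("outlier thresholds must be strictly positive")
    }
  }
  structure(list(bounds = bounds, order_pairs = order_pairs,
                 sum_caps = sum_caps, outlier_rules = outlier_rules),
            class = "constraint_set")
}

.cs_columns <- function(cs) {
  unique(c(cs$bounds$column, cs$order_pairs$lesser, cs$order_pairs$greater,
           unlist(lapply(cs$sum_caps, `[[`, "columns")),
           cs$outlier_rules$column))
}

#' Apply deterministic constraints to a table
#'
#' Filters rows violating any bound, order or sum constraint. The removal log
#' counts removals per rule; a row violating several rules is attributed to
#' the first violated rule in declaration order (bounds, then order pairs,
#' then sum caps) and counted once in the total. The surviving set itself does
#' not depend on declaration order.
#'
#' @param data Non-empty data frame.
#' @param cs A [constraint_set()].
#' @return List with `data` (surviving rows) and `removal_log` (named integer
#'   vector per rule plus `total`).
#' @examples
#' cs <- constraint_set(order_pairs = data.frame(lesser = "ADF",
#'                                               greater = "NDF"))
#' apply_constraints(data.frame(ADF = c(10, 50), NDF = c(30, 30)), cs)
#' @export
apply_constraints <- function(data, cs) {
  stopifnot(inherits(cs, "constraint_set"))
  data <- validate_data_table(data)
  unknown <- setdiff(.cs_columns(cs), names(data))
  if (length(unknown) > 0L) {
    stop("constraint references unknown columns: ",
         paste(unknown, collapse = ", "))
  }
  rules <- list()
  if (!is.null(cs$bounds)) {
    for (i in seq_len(nrow(cs$bounds))) {
      b <- cs$bounds[i, ]
      rules[[sprintf("bound:%s", b$column)]] <-
        !(data[[b$column]] > b$lower & data[[b$column]] < b$upper)
    }
  }
  if (!is.null(cs$order_pairs)) {
    for (i in seq_len(nrow(cs$order_pairs))) {
      op <- cs$order_pairs[i, ]
      rules[[sprintf("order:%s<%s", op$lesser, op$greater)]] <-
        !(data[[op$lesser]] < data[[op$greater]])
    }
  }
  if (!is.null(cs$sum_caps)) {
    for (sc in cs$sum_caps) {
      nm <- sprintf("sum:%s<%g", paste(sc$columns, collapse = "+"), sc$cap)
      rules[[nm]] <-
        !(rowSums(data[, sc$columns, drop = FALSE]) < sc$cap)
    }
  }
  if (length(rules) == 0L) {
    return(list(data = data,
                removal_log = c(total = 0L)))
  }
  viol <- do.call(cbind, rules)
  keep <- rowSums(viol) == 0L
  # attribute each removed row to its first violated rule
  first <- apply(viol[!keep, , drop = FALSE], 1, function(r) which(r)[1])
  log_counts <- stats::setNames(integer(length(rules)), names(rules))
  if (length(first) > 0L) {
    tb <- table(factor(names(rules)[first], levels = names(rules)))
    log_counts[] <- as.integer(tb)
  }
  removal_log <- c(log_counts, total = sum(!keep))
  list(data = data[keep, , drop = FALSE], removal_log = removal_log)
}

#' Flag statistical outliers
#'
#' Per-row keep decision from the `outlier_rules` of a constraint set. The
#' `zscore` method drops rows with `|x - mean| / sd > threshold`; the `iqr`
#' method drops rows outside `[Q1 - t * IQR, Q3 + t * IQR]` with type-7
#' (linear-interpolation) quartiles. A zero-IQR column keeps exactly the rows
#' equal to the quartile band, so an all-equal column flags nothing.
#'
#' @param data Data frame.
#' @param cs A [constraint_set()] with non-empty `outlier_rules`.
#' @return Logical keep-mask of length `nrow(data)` (`TRUE` = keep).
#' @examples
#' cs <- constraint_set(outlier_rules = data.frame(
#'   column = "x", method = "iqr", threshold = 1.5))
#' flag_outliers(data.frame(x = c(0, 0, 0, 0, 100)), cs)
#' @export
flag_outliers <- function(data, cs) {
  stopifnot(inherits(cs, "constraint_set"))
  data <- validate_data_table(data)
  if (is.null(cs$outlier_rules) || nrow(cs$outlier_rules) == 0L) {
    stop("constraint set has no outlier rules")
  }
  unknown <- setdiff(cs$outlier_rules$column, names(data))
  if (length(unknown) > 0L) {
    stop("outlier rules reference unknown columns: ",
         paste(unknown, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(cs$outlier_rules))) {
    rule <- cs$outlier_rules[i, ]
    x <- data[[rule$column]]
    if (rule$method == "zscore") {
      s <- stats::sd(x)
      if (s == 0) {
        stop("zscore rule on zero-variance column '", rule$column, "'")
      }
      keep <- keep & (abs(x - mean(x)) / s <= rule$threshold)
    } else {
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      keep <- keep & (x >= q[1] - rule$threshold * iqr) &
                     (x <= q[2] + rule$threshold * iqr)
    }
  }
  keep
}

#' Serialize / deserialize a constraint set (JSON)
#'
#' @param cs A [constraint_set()].
#' @param path JSON file path.
#' @return `path` invisibly (write); a `constraint_set` (read).
#' @export
write_constraints <- function(cs, path) {
  stopifnot(inherits(cs, "constraint_set"))
  jsonlite::write_json(unclass(cs), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sum_caps <- raw$sum_caps
  if (!is.null(sum_caps) && is.data.frame(sum_caps)) {
    sum_caps <- lapply(seq_len(nrow(sum_caps)), function(i) {
      list(columns = unlist(sum_caps$columns[i]), cap = sum_caps$cap[i])
    })
  } else if (!is.null(sum_caps)) {
    sum_caps <- lapply(sum_caps, function(sc) {
      list(columns = unlist(sc$columns), cap = as.numeric(sc$cap))
    })
  }
  constraint_set(bounds = raw$bounds, order_pairs = raw$order_pairs,
                 sum_caps = sum_caps, outlier_rules = raw$outlier_rules)
}
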
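#' Fit a random-forest regression
#'
#' Regression forest with variance-reduction splitting, per-tree bootstrap
#' resampling and retained out-of-bag (OOB) structure, via the randomForest
#' package. Defaults follow the methane workflow: 150 trees, 4 candidate
#' variables per split, minimum node size 5.
#'
#' @param data Data frame containing the response and at least two predictors.
#' @param response Name of the response column.
#' @param n_trees Number of trees (default 150).
#' @param m_try Candidate variables per split (default 4, capped at the
#'   predictor count).
#' @param seed Integer seed; predictions are identical run-to-run for a fixed
#'   seed.
#' @return An object of class `rf_model`: list with the fitted forest (`rf`),
#'   `response`, `predictors`, training `x`/`y` and `seed`.
#' @export
fit_rf <- function(data, response, n_trees = 150L, m_try = 4L, seed = 1L) {
  data <- validate_data_table(data, min_rows = 10L)
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found")
  }
  predictors <- setdiff(names(data), response)
  if (length(predictors) < 2L) stop("need at least 2 predictors")
  if (m_try > length(predictors)) {
    stop("m_try (", m_try, ") exceeds the predictor count (",
         length(predictors), ")")
  }
  x <- data[predictors]
  y <- data[[response]]
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = as.integer(n_trees), mtry = as.integer(m_try),
    nodesize = 5L, keep.inbag = TRUE, keep.forest = TRUE)
  structure(list(rf = rf, response = response, predictors = predictors,
                 x = x, y = y, seed = as.integer(seed)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(stats::predict(object$rf, object$x)))
  unname(stats::predict(object$rf, newdata[object$predictors]))
}

#' @export
print.rf_model <- function(x, ...) {
  cat("<rf_model>", x$rf$ntree, "trees, mtry", x$rf$mtry, "|",
      length(x$predictors), "predictors ->", x$response, "\n")
  cat("  OOB MSE:", format(utils::tail(x$rf$mse, 1), digits = 5), "\n")
  invisible(x)
}

# per-tree out-of-bag MSEs for (possibly permuted) predictor data
.tree_oob_mse <- function(model, xdata) {
  ind <- stats::predict(model$rf, xdata, predict.all = TRUE)$individual
  inbag <- model$rf$inbag
  y <- model$y
  vapply(seq_len(ncol(ind)), function(t) {
    oob <- inbag[, t] == 0L
    mean((ind[oob, t] - y[oob])^2)
  }, numeric(1))
}

#' Variable importance: PAS and SER
#'
#' Two complementary importance indices for a fitted regression forest:
#'
#' * **PAS** (predictive accuracy score): for each predictor, its values are
#'   randomly permuted and the per-tree out-of-bag MSE recomputed; PAS is the
#'   percentage increase `100 (MSE_perm - MSE_oob) / MSE_oob` averaged over
#'   trees. Reported unscaled (raw percentage, not divided by its standard
#'   error). A pure-noise predictor has PAS near zero in expectation.
#' * **SER** (square error reduction): the total decrease in node impurity
#'   (residual sum of squares) from splits on the variable, accumulated by
#'   routing each tree's bootstrap sample through its splits and averaged
#'   across trees; units are the squared response units. The per-variable SER
#'   values sum to the total recorded impurity decrease.
#'
#' @param model An [fit_rf()] model.
#' @param seed Seed for the permutations.
#' @return An object of class `importance_report`: data frame with columns
#'   `variable`, `pas` (percent), `ser`, sorted by decreasing `ser`, with
#'   attribute `total_ser` (the bookkeeping total).
#' @export
rf_importance <- function(model, seed = 1L) {
  stopifnot(inherits(model, "rf_model"))
  set.seed(seed)
  base_mse <- .tree_oob_mse(model, model$x)
  pas <- vapply(model$predictors, function(v) {
    xp <- model$x
    xp[[v]] <- xp[[v]][sample.int(nrow(xp))]
    perm_mse <- .tree_oob_mse(model, xp)
    mean(100 * (perm_mse - base_mse) / base_mse)
  }, numeric(1))

  ser_total <- .split_impurity_decrease(model)
  ser <- ser_total / model$rf$ntree       # averaged across trees

  out <- data.frame(variable = model$predictors,
                    pas = unname(pas), ser = unname(ser[model$predictors]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$ser), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("importance_report", "data.frame"),
            total_ser = sum(ser_total))
}

# route each tree's bootstrap rows through its recorded splits and accumulate
# the RSS decrease per split variable (summed over trees)
.split_impurity_decrease <- function(model) {
  rf <- model$rf
  xm <- as.matrix(model$x)
  y <- model$y
  dec <- stats::setNames(numeric(length(model$predictors)), model$predictors)
  rss <- function(v) if (length(v) < 2L) 0 else sum(v^2) - sum(v)^2 / length(v)
  for (t in seq_len(rf$ntree)) {
    tree <- randomForest::getTree(rf, t, labelVar = FALSE)
    rows <- rep(seq_len(nrow(xm)), times = rf$inbag[, t])
    node_of <- integer(length(rows)) + 1L
    for (k in seq_len(nrow(tree))) {
      if (tree[k, "status"] == -1L) next   # terminal
      idx <- which(node_of == k)
      if (length(idx) == 0L) next
      v <- tree[k, "split var"]
      left <- xm[rows[idx], v] <= tree[k, "split point"]
      yk <- y[rows[idx]]
      d <- rss(yk) - rss(yk[left]) - rss(yk[!left])
      dec[v] <- dec[v] + d
      node_of[idx[left]] <- tree[k, "left daughter"]
      node_of[idx[!left]] <- tree[k, "right daughter"]
    }
  }
  dec
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report> (sorted by SER)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Importance plot (PAS as line length, SER as point size)
#'
#' Variables are drawn top-down by decreasing SER; the horizontal line length
#' shows PAS (% increase in MSE under permutation) and the point size scales
#' with SER.
#'
#' @param x An `importance_report`.
#' @param ... Further arguments passed to `plot`.
#' @export
plot.importance_report <- function(x, ...) {
  k <- nrow(x)
  ypos <- rev(seq_len(k))
  cex <- 0.8 + 2.2 * (x$ser - min(x$ser)) / max(diff(range(x$ser)), 1e-12)
  graphics::plot(range(0, x$pas), range(ypos) + c(-0.5, 0.5), type = "n",
                 xlab = "PAS (% increase in MSE)", ylab = "", yaxt = "n", ...)
  graphics::segments(0, ypos, x$pas, ypos, lwd = 2, col = "grey50")
  graphics::points(x$pas, ypos, pch = 16, cex = cex, col = "steelblue")
  graphics::axis(2, at = ypos, labels = x$variable, las = 1)
  invisible(x)
}

#' Cross-testing of RF and LM across two synthetic databases
#'
#' Fits a random forest and an ordinary least-squares linear model on each of
#' two synthetic databases (one typically built from normal marginals, the
#' other from best-fit non-normal marginals), evaluates every fitted model on
#' both databases with [adequacy()], and returns the 2 x 2 x 2 grid of
#' reports. `p` for the linear model is predictors + 1; for the forest it is
#' the predictor count (its documented stand-in).
#'
#' @param db_normal,db_nonnormal Data frames with identical column sets.
#' @param response Response column name.
#' @param n_trees,m_try Forest settings (see [fit_rf()]).
#' @param seed Integer seed (forests and permutations).
#' @return An object of class `crosstest_grid`: nested list
#'   `grid[[train]][[eval]][[model]]` of `adequacy_report`s, with `train`,
#'   `eval` in `c("normal", "nonnormal")` and `model` in `c("rf", "lm")`,
#'   plus the fitted models. Use [as.data.frame()] for the
#'   statistics-by-scenario rendering.
#' @export
cross_test <- function(db_normal, db_nonnormal, response, n_trees = 150L,
                       m_try = 4L, seed = 1L) {
  db_normal <- validate_data_table(db_normal, min_rows = 10L)
  db_nonnormal <- validate_data_table(db_nonnormal, min_rows = 10L)
  if (!setequal(names(db_normal), names(db_nonnormal))) {
    stop("column mismatch between databases: ",
         paste(union(setdiff(names(db_normal), names(db_nonnormal)),
                     setdiff(names(db_nonnormal), names(db_normal))),
               collapse = ", "))
  }
  db_nonnormal <- db_nonnormal[names(db_normal)]
  if (!response %in% names(db_normal)) {
    stop("response column '", response, "' not found")
  }
  dbs <- list(normal = db_normal, nonnormal = db_nonnormal)
  npred <- ncol(db_normal) - 1L

  models <- lapply(names(dbs), function(tr) {
    d <- dbs[[tr]]
    list(rf = fit_rf(d, response, n_trees = n_trees, m_try = m_try,
                     seed = derive_seed(seed, match(tr, names(dbs)))),
         lm = ols_fit(d[[response]], d[setdiff(names(d), response)]))
  })
  names(models) <- names(dbs)

  grid <- lapply(names(dbs), function(tr) {
    evals <- lapply(names(dbs), function(ev) {
      d <- dbs[[ev]]
      obs <- d[[response]]
      pred_rf <- predict(models[[tr]]$rf, d)
      pred_lm <- unname(stats::predict(models[[tr]]$lm$lm,
                                       d[setdiff(names(d), response)]))
      list(rf = adequacy(obs, pred_rf, p = npred),
           lm = adequacy(obs, pred_lm, p = npred + 1L))
    })
    names(evals) <- names(dbs)
    evals
  })
  names(grid) <- names(dbs)

  structure(list(grid = grid, models = models, response = response,
                 seed = as.integer(seed)),
            class = "crosstest_grid")
}

#' @export
as.data.frame.crosstest_grid <- function(x, ...) {
  reports <- list()
  for (ev in names(x$grid)) {
    for (tr in names(x$grid[[ev]])) {
      # column naming: evaluation database first, then training origin
      for (mod in c("rf", "lm")) {
        nm <- sprintf("%s_db.%s_%s", ev, tr, toupper(mod))
        reports[[nm]] <- x$grid[[tr]][[ev]][[mod]]
      }
    }
  }
  adequacy_table(reports)
}

#' @export
print.crosstest_grid <- function(x, ...) {
  cat("<crosstest_grid> response:", x$response, "\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
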
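#' Gradient-boosted decision trees with missing-value support
#'
#' A compact Newton-boosting implementation (logistic loss, L2-regularised
#' leaves, learned default direction for missing values — the standard
#' sparsity-aware treatment) used as the learner for every module
#' classifier.  Missing entries (`NA`) are the SKIP marker of the score
#' sheets; each split learns which branch skipped answers should follow,
#' so models trained on data containing skips degrade gracefully at
#' prediction time.
#'
#' The fit is fully deterministic: no subsampling happens inside the
#' booster; resampling (folds, bootstraps) is done by the callers.
#'
#' @param x Numeric matrix (rows = children, columns = features; `NA`
#'   allowed).
#' @param y Binary response vector (0/1).
#' @param weights Optional non-negative sample weights.
#' @param n_trees Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage per round.
#' @param lambda L2 penalty on leaf values.
#' @param min_child_weight Minimum hessian sum per child node.
#' @return A `gbt_model` with `predict` method.
#' @export
gbt_fit <- function(x, y, weights = NULL, n_trees = 100L, max_depth = 3L,
                    learning_rate = 0.1, lambda = 1.0,
                    min_child_weight = 1.0) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, nrow(x))
  stopifnot(length(weights) == nrow(x), all(weights >= 0))
  p0 <- sum(weights * y) / sum(weights)
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  fit <- gbt_fit_cpp(x, y, weights, as.integer(n_trees),
                     as.integer(max_depth), learning_rate, lambda,
                     min_child_weight, stats::qlogis(p0))
  structure(list(trees = fit$trees, base_margin = fit$base_margin,
                 feature_gain = stats::setNames(as.numeric(fit$feature_gain),
                                                colnames(x)),
                 feature_names = colnames(x),
                 params = list(n_trees = n_trees, max_depth = max_depth,
                               learning_rate = learning_rate, lambda = lambda,
                               min_child_weight = min_child_weight)),
            class = "gbt_model")
}

#' @export
print.gbt_model <- function(x, ...) {
  cat(sprintf("gbt_model: %d trees, depth %d, eta %g, %d features\n",
              length(x$trees), x$params$max_depth, x$params$learning_rate,
              length(x$feature_names)))
  invisible(x)
}

#' Predict from a gradient-boosted tree model
#'
#' @param object A `gbt_model`.
#' @param newdata Numeric matrix with the model's feature columns (`NA`
#'   allowed; follows each split's learned default direction).
#' @param type `"response"` for probabilities, `"link"` for the raw
#'   margin.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.gbt_model <- function(object, newdata, type = c("response", "link"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  storage.mode(newdata) <- "double"
  m <- gbt_margin_cpp(object$trees, newdata, object$base_margin)
  if (type == "response") stats::plogis(m) else m
}

#' Feature importance of a boosted-tree model
#'
#' Total split gain accumulated per feature, the usual tree-ensemble
#' importance measure, sorted descending.
#'
#' @param model A `gbt_model`.
#' @return Named numeric vector (gain per feature, descending).
#' @export
gbt_importance <- function(model) {
  stopifnot(inherits(model, "gbt_model"))
  sort(model$feature_gain, decreasing = TRUE)
}

#' Bootstrapped grid search over booster hyper-parameters
#'
#' For every grid point, `n_boot` bootstrap resamples are drawn; the model
#' is fit on each in-bag sample and scored by AUC on the out-of-bag
#' children.  The grid point with the highest mean out-of-bag AUC wins
#' (ties: first in grid order).
#'
#' @param x,y,weights As in [gbt_fit()].
#' @param grid List of parameter lists (fields as in [gbt_fit()]).
#' @param n_boot Bootstrap resamples per grid point.
#' @param seed Integer seed.
#' @return List with `best` (parameter list), `mean_auc` per grid point.
#' @export
gbt_grid_search <- function(x, y, weights = NULL, grid, n_boot = 10L,
                            seed = 1L) {
  stopifnot(length(grid) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(y))
  set.seed(derive_seed(seed, "gridsearch"))
  n <- length(y)
  boots <- lapply(seq_len(n_boot), function(b) sample.int(n, n, replace = TRUE))
  mean_auc <- vapply(grid, function(par) {
    aucs <- vapply(boots, function(ib) {
      oob <- setdiff(seq_len(n), unique(ib))
      if (length(unique(y[oob])) < 2L || length(unique(y[ib])) < 2L)
        return(NA_real_)
      fit <- do.call(gbt_fit, c(list(x = x[ib, , drop = FALSE], y = y[ib],
                                     weights = weights[ib]), par))
      auc_value(predict(fit, x[oob, , drop = FALSE]), y[oob])
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  list(best = grid[[which.max(mean_auc)]], mean_auc = mean_auc)
}

# (age, label)-cell balancing weights: each cell of the cross-tab gets
# equal total weight; cells are years-of-age x label
balance_weights <- function(age_months, label) {
  cell <- paste(label, age_months %/% 12L)
  tab <- table(cell)
  w <- as.numeric(length(cell) / (length(tab) * tab[cell]))
  w
}
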
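#' Training configuration for a module cascade
#'
#' @param cv_folds Stratified folds for out-of-fold predictions (>= 2).
#' @param grid Hyper-parameter grid: list of parameter lists for
#'   [gbt_fit()].  With a single grid point (the default) the bootstrapped
#'   grid search is skipped.
#' @param n_boot Bootstrap resamples per grid point in the grid search.
#' @param seed Integer seed controlling folds and the grid search.
#' @param weight_balance Balance sample weights over (age, label) cells.
#' @param target_sensitivity Sensitivity target used for the helper
#'   model's hard-prediction cut and the default decision threshold.
#' @param max_inconclusive Abstention allowance used for the default
#'   filter threshold (re-tunable later with [tune_thresholds()]).
#' @return A `train_config` list.
#' @export
train_config <- function(cv_folds = 5L,
                         grid = list(list(n_trees = 100L, max_depth = 3L,
                                          learning_rate = 0.1)),
                         n_boot = 10L, seed = 1L, weight_balance = TRUE,
                         target_sensitivity = 0.9, max_inconclusive = 0.3) {
  stopifnot(cv_folds >= 2L, length(grid) >= 1L,
            max_inconclusive >= 0, max_inconclusive < 1)
  structure(list(cv_folds = as.integer(cv_folds), grid = grid,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 weight_balance = isTRUE(weight_balance),
                 target_sensitivity = target_sensitivity,
                 max_inconclusive = max_inconclusive),
            class = "train_config")
}

# label-stratified fold assignment
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# out-of-fold probability scores for a gbt fit on (x, y)
oof_scores <- function(x, y, w, fold, par) {
  s <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fit <- do.call(gbt_fit, c(list(x = x[tr, , drop = FALSE], y = y[tr],
                                   weights = w[tr]), par))
    s[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  s
}

#' Train an abstention-capable classifier cascade
#'
#' Three training runs produce the two runtime models:
#' \enumerate{
#'   \item A helper binary classifier is trained with label-stratified
#'     out-of-fold predictions over the training data; each child is
#'     labelled \emph{correct}/\emph{incorrect} by comparing the helper's
#'     out-of-fold hard prediction (cut at the sensitivity-targeted
#'     threshold) with the true diagnosis.  The helper is discarded and
#'     never used at prediction time.
#'   \item The \emph{indeterminate filter} is trained on those
#'     correct/incorrect labels and scores the probability that a child
#'     would be misclassified.
#'   \item The final binary classifier is trained only on the children the
#'     filter (at its default threshold, out-of-fold) deems likely
#'     correct.
#' }
#' Folds are stratified by the true class label and, when
#' `cfg$weight_balance`, samples are weight-balanced over (age, label)
#' cells.  With more than one grid point, hyper-parameters are tuned by a
#' bootstrapped grid search before step 1.
#'
#' @param ds A labelled, single-silo `score_dataset`.
#' @param cfg A [train_config()].
#' @param feature_ids Optional question subset to train on.
#' @return A `cascade_model`: `filter_model`, `binary_model`,
#'   `filter_threshold`, `decision_threshold`, `silo`, `feature_ids`.
#' @export
train_cascade <- function(ds, cfg = train_config(), feature_ids = NULL) {
  stopifnot(inherits(ds, "score_dataset"), inherits(cfg, "train_config"))
  x <- answers_matrix(ds, feature_ids)
  y <- ds$sheets$label
  if (anyNA(y)) stop("training requires labelled data")
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  w <- if (cfg$weight_balance) balance_weights(ds$sheets$age_months, y)
       else rep(1, length(y))

  par <- if (length(cfg$grid) > 1L)
    gbt_grid_search(x, y, w, cfg$grid, cfg$n_boot, cfg$seed)$best
  else cfg$grid[[1L]]

  set.seed(derive_seed(cfg$seed, "cascade_folds"))
  fold <- stratified_folds(y, cfg$cv_folds)

  # run 1: helper model out-of-fold scores -> correct/incorrect labels
  helper_oof <- oof_scores(x, y, w, fold, par)
  cut <- spec_at_sens(helper_oof, y, cfg$target_sensitivity)$threshold
  incorrect <- as.integer((helper_oof > cut) != (y == 1L))

  # run 2: the indeterminate filter predicts P(misclassified)
  filter_model <- do.call(gbt_fit, c(list(x = x, y = incorrect, weights = w),
                                     par))
  if (length(unique(incorrect)) == 2L) {
    filter_oof <- oof_scores(x, incorrect, w, fold, par)
  } else {
    filter_oof <- rep(mean(incorrect), length(y))   # degenerate easy regime
  }
  # default: abstain only on children more likely incorrect than correct,
  # and never beyond the coverage allowance; tune_thresholds() can lower it
  filter_threshold <- max(0.5, threshold_for_fraction(filter_oof,
                                                      cfg$max_inconclusive))

  # run 3: final binary classifier on likely-correct children only
  keep <- filter_oof <= filter_threshold
  if (length(unique(y[keep])) < 2L) keep <- rep(TRUE, length(y))
  binary_model <- do.call(gbt_fit,
                          c(list(x = x[keep, , drop = FALSE], y = y[keep],
                                 weights = w[keep]), par))
  binary_scores <- predict(binary_model, x[keep, , drop = FALSE])
  decision_threshold <- spec_at_sens(binary_scores, y[keep],
                                     cfg$target_sensitivity)$threshold

  structure(list(filter_model = filter_model, binary_model = binary_model,
                 filter_threshold = filter_threshold,
                 decision_threshold = decision_threshold,
                 silo = ds$age_silo,
                 feature_ids = colnames(x), params = par),
            class = "cascade_model")
}

# smallest threshold t with mean(scores > t) <= frac, i.e. the threshold
# that uses as much of the abstention allowance as the scores permit
threshold_for_fraction <- function(scores, frac) {
  cand <- sort(unique(c(scores, 1)))
  for (t in cand) if (mean(scores > t) <= frac) return(t)
  1
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf(
    "cascade_model (silo '%s', %d features)\n  filter_threshold = %.4f, decision_threshold = %.4f\n",
    x$silo, length(x$feature_ids), x$filter_threshold, x$decision_threshold))
  invisible(x)
}

#' Three-way prediction from a cascade
#'
#' A child whose filter score exceeds `filter_threshold` is abstained on
#' (`inconclusive`, score `NA`); otherwise the verdict is `positive` when
#' the binary score exceeds `decision_threshold`, else `negative`, with
#' the binary score attached.  SKIPs are passed to the learners as missing
#' values; prediction is pure (same model and sheets give the same
#' outcomes).
#'
#' @param object A `cascade_model`.
#' @param newdata A `score_dataset` (or matrix with the model's feature
#'   columns).
#' @param ... Unused.
#' @return An `outcome` data frame (see [as_outcomes()]).
#' @export
predict.cascade_model <- function(object, newdata, ...) {
  if (inherits(newdata, "score_dataset")) {
    ids <- newdata$sheets$child_id
    x <- answers_matrix(newdata, object$feature_ids)
  } else {
    x <- as.matrix(newdata)[, object$feature_ids, drop = FALSE]
    ids <- if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(x)))
  }
  fs <- predict(object$filter_model, x)
  bs <- predict(object$binary_model, x)
  inconcl <- fs > object$filter_threshold
  verdict <- ifelse(inconcl, "inconclusive",
                    ifelse(bs > object$decision_threshold, "positive",
                           "negative"))
  out <- as_outcomes(ids, verdict, ifelse(inconcl, NA_real_, bs))
  attr(out, "filter_score") <- fs
  attr(out, "binary_score") <- bs
  out
}

#' Module response scores (the vector R entries)
#'
#' The raw binary-model probability for every child, used as this module's
#' response in the combination stage (abstention is handled downstream by
#' the combined-response band).
#'
#' @param model A `cascade_model` (or a `gbt_model`, or a function taking
#'   the answers matrix).
#' @param ds A `score_dataset`.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
module_score <- function(model, ds) {
  if (inherits(model, "cascade_model"))
    predict(model$binary_model, answers_matrix(ds, model$feature_ids))
  else if (inherits(model, "gbt_model"))
    predict(model, answers_matrix(ds, model$feature_names))
  else if (is.function(model))
    model(answers_matrix(ds))
  else stop("unsupported model type")
}

#' Tune cascade thresholds on a labelled dataset
#'
#' Sequential tuning: the filter threshold is set to the value keeping
#' the inconclusive fraction at or below `max_inconclusive` while
#' maximising the conclusive-subset AUC (ties broken towards larger
#' thresholds, i.e. fewer abstentions); the decision threshold is then the
#' largest value whose conclusive-subset sensitivity reaches
#' `target_sensitivity`.
#'
#' @param model A `cascade_model`.
#' @param ds Labelled tuning `score_dataset`.
#' @param target_sensitivity Required conclusive-subset sensitivity.
#' @param max_inconclusive Maximum abstention fraction.
#' @return An updated copy of `model`.
#' @export
tune_thresholds <- function(model, ds, target_sensitivity = 0.9,
                            max_inconclusive = 0.3) {
  stopifnot(inherits(model, "cascade_model"))
  y <- ds$sheets$label
  if (anyNA(y)) stop("tuning requires labelled data")
  x <- answers_matrix(ds, model$feature_ids)
  fs <- predict(model$filter_model, x)
  bs <- predict(model$binary_model, x)

  cand <- sort(unique(c(fs, 1)), decreasing = TRUE)  # descending: prefer larger
  best_t <- NA_real_; best_auc <- -Inf
  for (t in cand) {
    keep <- fs <= t
    if (mean(!keep) > max_inconclusive) next
    if (length(unique(y[keep])) < 2L) next
    a <- auc_value(bs[keep], y[keep])
    if (a > best_auc + 1e-12) { best_auc <- a; best_t <- t }
  }
  if (is.na(best_t))
    stop(sprintf(
      "no filter threshold satisfies max_inconclusive = %.2f with both classes conclusive",
      max_inconclusive))
  keep <- fs <= best_t
  # a threshold below the minimum score always attains sensitivity 1, so
  # the target is feasible for any two-class conclusive subset
  op <- spec_at_sens(bs[keep], y[keep], target_sensitivity)
  model$filter_threshold <- best_t
  model$decision_threshold <- op$threshold
  model
}
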
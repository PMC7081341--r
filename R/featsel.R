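#' Distribution-shift feature rejection
#'
#' For every question, compares the mean answered severity between the
#' training cohort and the deployment cohort, separately within the case
#' and the non-case class, and rejects questions whose class-averaged
#' absolute mean difference exceeds `k_se` class-averaged standard errors.
#' SKIPs are excluded from the means.  The combined statistic for question
#' \eqn{q} is
#' \deqn{\frac{(|d_{case}| + |d_{ctrl}|)/2}{(se_{case} + se_{ctrl})/2}}
#' with \eqn{se_c = \sqrt{se_{train,c}^2 + se_{deploy,c}^2}}, and a
#' question is rejected when the statistic exceeds `k_se` (default 3).
#' Dropping shift-unstable questions before retraining removes the
#' features most biased by the change of setting.
#'
#' @param train,deploy Labelled `score_dataset`s sharing a schema.
#' @param k_se Rejection threshold in standard-error units (default 3).
#' @return A `shift_report` data frame, one row per question, with the
#'   per-class means, differences, standard errors, the combined
#'   `statistic` and the `rejected` flag.
#' @export
shift_reject <- function(train, deploy, k_se = 3) {
  stopifnot(inherits(train, "score_dataset"), inherits(deploy, "score_dataset"))
  if (!identical(train$questions$id, deploy$questions$id))
    stop("datasets have mismatched question schemas")
  for (nm in c("train", "deploy")) {
    lab <- get(nm)$sheets$label
    for (cl in c(1L, 0L))
      if (!any(lab == cl, na.rm = TRUE))
        stop(sprintf("class %s is empty in the %s dataset",
                     if (cl == 1L) "case" else "control", nm))
  }
  mt <- answers_matrix(train); md <- answers_matrix(deploy)
  yt <- train$sheets$label; yd <- deploy$sheets$label
  stat_class <- function(cl) {
    a <- mt[yt == cl, , drop = FALSE]; b <- md[yd == cl, , drop = FALSE]
    mean_a <- colMeans(a, na.rm = TRUE); mean_b <- colMeans(b, na.rm = TRUE)
    se2 <- function(m) apply(m, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(Inf)
      stats::var(v) / length(v)
    })
    list(mean_train = mean_a, mean_deploy = mean_b,
         d = abs(mean_b - mean_a), se = sqrt(se2(a) + se2(b)))
  }
  cs <- stat_class(1L); ct <- stat_class(0L)
  statistic <- ((cs$d + ct$d) / 2) / ((cs$se + ct$se) / 2)
  out <- data.frame(question = train$questions$id,
                    mean_train_case = cs$mean_train,
                    mean_deploy_case = cs$mean_deploy,
                    mean_train_control = ct$mean_train,
                    mean_deploy_control = ct$mean_deploy,
                    diff_case = cs$d, diff_control = ct$d,
                    se_case = cs$se, se_control = ct$se,
                    statistic = statistic,
                    rejected = statistic > k_se,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "k_se") <- k_se
  class(out) <- c("shift_report", "data.frame")
  out
}

#' Perturbation-sensitivity question ranking
#'
#' Ranks questions by how much nudging their answer moves the responses of
#' children near the decision threshold.  Children whose model response
#' lies in `(threshold + band[1], threshold + band[2]]` have each
#' question's severity dropped by one (floored at 0), one question at a
#' time; children in `[threshold - band[2], threshold - band[1])` have it
#' raised by one (capped at `max_severity`).  The model is re-scored after
#' each single-question perturbation and questions are ranked by the mean
#' absolute response shift over the affected children.  SKIP answers are
#' left untouched, and the input dataset is never modified.
#'
#' @param model A binary scorer: `cascade_model`, `gbt_model`, or a
#'   function of the answers matrix returning scores in `[0, 1]`.
#' @param ds A `score_dataset`.
#' @param threshold Decision threshold the bands are anchored to.
#' @param band Offsets `(lo, hi)` from the threshold, `lo < hi`
#'   (default `c(0, 0.1)`; the secondary band used in practice is
#'   `c(0.1, 0.3)`).
#' @return A `perturbation_ranking`: data frame `question`, `mean_shift`,
#'   `n_affected`, sorted descending by `mean_shift` (ties by question
#'   id), with the band recorded as an attribute.
#' @export
perturb_rank <- function(model, ds, threshold, band = c(0, 0.1)) {
  stopifnot(inherits(ds, "score_dataset"), band[1] < band[2])
  x <- answers_matrix(ds)
  score_fn <- function(m) {
    if (is.function(model)) model(m)
    else if (inherits(model, "cascade_model")) {
      predict(model$binary_model, m[, model$feature_ids, drop = FALSE])
    } else predict(model, m)
  }
  base <- score_fn(x)
  up_band <- base > threshold + band[1] & base <= threshold + band[2]   # drop
  dn_band <- base >= threshold - band[2] & base < threshold - band[1]   # raise
  affected <- up_band | dn_band
  qs <- ds$questions
  if (!any(affected)) {
    warning("no children inside the perturbation band; empty ranking")
    out <- data.frame(question = character(0), mean_shift = numeric(0),
                      n_affected = integer(0))
  } else {
    delta <- ifelse(up_band, -1, ifelse(dn_band, +1, 0))
    mean_shift <- numeric(nrow(qs))
    for (k in seq_len(nrow(qs))) {
      xp <- x[affected, , drop = FALSE]
      a <- xp[, k]
      nudged <- pmin(pmax(a + delta[affected], 0), qs$max_severity[k])
      nudged[is.na(a)] <- NA             # SKIPs untouched
      xp[, k] <- nudged
      mean_shift[k] <- mean(abs(score_fn(xp) - base[affected]))
    }
    out <- data.frame(question = qs$id, mean_shift = mean_shift,
                      n_affected = sum(affected), stringsAsFactors = FALSE)
    out <- out[order(-out$mean_shift, out$question), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "band") <- band
  attr(out, "threshold") <- threshold
  class(out) <- c("perturbation_ranking", "data.frame")
  out
}

#' Shortlist clinician-questionnaire candidates
#'
#' Takes the importance-ranked list and two perturbation-sensitivity
#' rankings (near and wide band), keeps the top `top_k` of each, and
#' returns their union ordered by the best (minimum) rank any list gives a
#' question, ties broken by question id.  A caller-supplied `allow_list`
#' stands in for the domain-expert consultation filter.
#'
#' @param imp_list Character ids ranked by model feature importance.
#' @param band_a,band_b `perturbation_ranking`s (or ranked id vectors).
#' @param top_k Entries kept from each list (default 7).
#' @param allow_list Optional ids to intersect the shortlist with.
#' @return Character vector of shortlisted question ids.
#' @export
shortlist_clinician <- function(imp_list, band_a, band_b, top_k = 7L,
                                allow_list = NULL) {
  as_ids <- function(x) if (is.data.frame(x)) x$question else as.character(x)
  lists <- lapply(list(imp_list, band_a, band_b), as_ids)
  tops <- lapply(lists, function(l) utils::head(l, top_k))
  ids <- unique(unlist(tops))
  best_rank <- vapply(ids, function(q) {
    min(vapply(tops, function(l) {
      r <- match(q, l)
      if (is.na(r)) Inf else as.numeric(r)
    }, 0))
  }, 0)
  out <- ids[order(best_rank, ids)]
  if (!is.null(allow_list)) out <- out[out %in% allow_list]
  out
}

#' Bootstrapped backward feature elimination (reconstruction)
#'
#' A generic stand-in for bootstrap-driven backwards subtraction: at each
#' step the question whose removal least degrades the mean bootstrapped
#' out-of-bag AUC is dropped, until `min_features` remain or the best
#' removal would degrade the current mean AUC by more than `tol`.  This is
#' plumbing for an initial feature-selection pass whose exact original
#' procedure is not reproduced here; treat its output as a generic
#' selector, not a validated clinical question list.
#'
#' @param ds Labelled `score_dataset`.
#' @param n_boot Bootstrap resamples per candidate evaluation.
#' @param min_features Stop when this many questions remain.
#' @param seed Integer seed (deterministic result).
#' @param tol Maximum tolerated drop in mean out-of-bag AUC per step
#'   (default 0.01).
#' @param gbt_params Learner parameters (small defaults keep this cheap).
#' @return Character vector of surviving question ids.
#' @export
backward_eliminate <- function(ds, n_boot = 10L, min_features = 1L,
                               seed = 1L, tol = 0.01,
                               gbt_params = list(n_trees = 40L,
                                                 max_depth = 2L,
                                                 learning_rate = 0.2)) {
  stopifnot(inherits(ds, "score_dataset"))
  y <- ds$sheets$label
  if (anyNA(y)) stop("backward_eliminate requires labelled data")
  x <- answers_matrix(ds)
  feats <- colnames(x)
  if (min_features > length(feats))
    stop("min_features exceeds the number of questions")
  set.seed(derive_seed(seed, "backward_eliminate"))
  n <- length(y)
  boots <- lapply(seq_len(n_boot), function(b) sample.int(n, n, replace = TRUE))
  mean_oob_auc <- function(cols) {
    aucs <- vapply(boots, function(ib) {
      oob <- setdiff(seq_len(n), unique(ib))
      if (length(unique(y[oob])) < 2L || length(unique(y[ib])) < 2L)
        return(NA_real_)
      fit <- do.call(gbt_fit, c(list(x = x[ib, cols, drop = FALSE],
                                     y = y[ib]), gbt_params))
      auc_value(predict(fit, x[oob, cols, drop = FALSE]), y[oob])
    }, 0)
    mean(aucs, na.rm = TRUE)
  }
  current_auc <- mean_oob_auc(feats)
  while (length(feats) > min_features) {
    cand_auc <- vapply(feats, function(f) mean_oob_auc(setdiff(feats, f)), 0)
    best <- which.max(cand_auc)
    if (cand_auc[best] < current_auc - tol) break
    current_auc <- cand_auc[best]
    feats <- setdiff(feats, feats[best])
  }
  feats
}
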
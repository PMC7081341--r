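#' Build a combination model
#'
#' Holds the module order, the covariance matrix of response residuals
#' (response minus binary truth), the inconclusive band thresholds and a
#' ridge constant stabilising near-singular covariances.
#'
#' @param module_ids Ordered character ids of the combined modules.
#' @param sigma Residual covariance matrix (symmetric).
#' @param lower_threshold,upper_threshold Combined-response band: below
#'   `lower` is negative, above `upper` positive, in between inconclusive.
#' @param ridge Non-negative ridge added to the diagonal (default 1e-6).
#' @return A `combination_model`.
#' @export
combination_model <- function(module_ids, sigma, lower_threshold = 0.5,
                              upper_threshold = 0.5, ridge = 1e-6) {
  sigma <- as.matrix(sigma)
  k <- length(module_ids)
  stopifnot(nrow(sigma) == k, ncol(sigma) == k, ridge >= 0,
            lower_threshold <= upper_threshold)
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  dimnames(sigma) <- list(module_ids, module_ids)
  structure(list(module_ids = as.character(module_ids), sigma = sigma,
                 lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold, ridge = ridge),
            class = "combination_model")
}

#' @export
print.combination_model <- function(x, ...) {
  cat(sprintf("combination_model: %d modules (%s), band [%.4f, %.4f], ridge %g\n",
              length(x$module_ids), paste(x$module_ids, collapse = ", "),
              x$lower_threshold, x$upper_threshold, x$ridge))
  invisible(x)
}

# inverse-covariance weights w = S^-1 1 / (1' S^-1 1); errors on singular S
combination_weights <- function(sigma, ridge) {
  S <- sigma + diag(ridge, nrow(sigma))
  inv <- try(solve(S), silent = TRUE)
  if (inherits(inv, "try-error"))
    stop("effective covariance is singular; increase `ridge`")
  ones <- rep(1, nrow(S))
  w <- inv %*% ones
  as.numeric(w / sum(w))
}

#' Combine module responses by inverse covariance
#'
#' Implements the pooled response
#' \deqn{r_{comb} = (I^T \Sigma^{-1} R)\,(I^T \Sigma^{-1} I)^{-1}}
#' where \eqn{I} is a vector of ones, \eqn{R} the module responses and
#' \eqn{\Sigma} the residual covariance (plus ridge).  This is a weighted
#' mean whose weights sum to one; with diagonal \eqn{\Sigma} it reduces to
#' classical inverse-variance weighting.  Modules with missing responses
#' (`NA` in `R`) are dropped and the combination runs on the submatrix of
#' available modules.
#'
#' @param model A `combination_model`.
#' @param R Numeric vector of module responses, aligned with
#'   `model$module_ids` (`NA` = module not administered).
#' @return The combined response (not clipped to `[0, 1]`).
#' @export
combine_responses <- function(model, R) {
  stopifnot(inherits(model, "combination_model"),
            length(R) == length(model$module_ids))
  avail <- !is.na(R)
  if (!any(avail)) stop("no module responses available")
  w <- combination_weights(model$sigma[avail, avail, drop = FALSE],
                           model$ridge)
  sum(w * R[avail])
}

#' Fit a combination model from module response tables
#'
#' "Training" the combination consists of estimating \eqn{\Sigma}: the
#' residual of module \eqn{m} on child \eqn{i} is `responses[i, m] -
#' labels[i]` and \eqn{\Sigma} is the sample covariance of the residual
#' vectors.  Leave-one-out combined responses are also returned: for
#' child \eqn{i}, \eqn{\Sigma_{-i}} is estimated from all other children
#' and the combination evaluated with it, so downstream evaluation of the
#' combined screener does not overfit.
#'
#' @param responses Numeric matrix, children x modules (column names =
#'   module ids, row names = child ids).
#' @param labels Binary truth aligned with rows.
#' @param ridge Ridge constant (default 1e-6).
#' @return A `combination_model` with extra fields `loo_responses`
#'   (named vector) and `residuals`.
#' @export
fit_combination <- function(responses, labels, ridge = 1e-6) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  labels <- as.integer(labels)
  if (n < 3L) stop("need at least 3 children to estimate the covariance")
  if (length(labels) != n) stop("labels misaligned with response rows")
  if (anyNA(responses)) stop("fit_combination requires complete responses")
  module_ids <- colnames(responses)
  if (is.null(module_ids)) module_ids <- sprintf("M%d", seq_len(ncol(responses)))
  res <- responses - labels
  sigma <- stats::cov(res)
  model <- combination_model(module_ids, sigma, ridge = ridge)

  # exact leave-one-out covariances via sum downdates
  S1 <- colSums(res)
  S2 <- crossprod(res)
  loo <- numeric(n)
  for (i in seq_len(n)) {
    s1 <- S1 - res[i, ]
    s2 <- S2 - tcrossprod(res[i, ])
    sig_i <- (s2 - tcrossprod(s1) / (n - 1)) / (n - 2)
    sig_i <- (sig_i + t(sig_i)) / 2
    w <- combination_weights(sig_i, ridge)
    loo[i] <- sum(w * responses[i, ])
  }
  names(loo) <- rownames(responses)
  model$loo_responses <- loo
  model$residuals <- res
  model
}

#' Three-way verdict from a combined response
#'
#' @param model A `combination_model` with thresholds set.
#' @param r Combined response value(s).
#' @return Character verdict(s): negative below the lower threshold,
#'   inconclusive inside the closed band, positive above the upper
#'   threshold.
#' @export
banded_outcome <- function(model, r) {
  stopifnot(inherits(model, "combination_model"))
  ifelse(r < model$lower_threshold, "negative",
         ifelse(r > model$upper_threshold, "positive", "inconclusive"))
}

#' Tune the combined-response inconclusive band
#'
#' Grid search over candidate (lower, upper) pairs drawn from midpoints of
#' the sorted observed responses (plus open ends).  Among pairs whose
#' inconclusive fraction stays at or below `max_inconclusive` and whose
#' conclusive-subset sensitivity reaches `target_sensitivity`, the pair
#' with maximal conclusive-subset specificity wins; ties go to the
#' narrower band, then to the lower-positioned band.
#'
#' @param model A `combination_model`.
#' @param responses Combined responses (typically
#'   `model$loo_responses`).
#' @param labels Binary truth aligned with `responses`.
#' @param target_sensitivity Required conclusive-subset sensitivity.
#' @param max_inconclusive Maximum abstention fraction.
#' @return An updated copy of `model` with thresholds set.
#' @export
tune_band <- function(model, responses, labels, target_sensitivity = 0.9,
                      max_inconclusive = 0.3) {
  stopifnot(inherits(model, "combination_model"))
  labels <- as.integer(labels)
  n <- length(responses)
  stopifnot(length(labels) == n)
  sv <- sort(unique(responses))
  cand <- c(sv[1] - 1, (sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)] + 1)
  n_case <- sum(labels == 1L); n_ctrl <- sum(labels == 0L)
  # cumulative class counts strictly below each candidate
  case_below <- vapply(cand, function(t) sum(responses < t & labels == 1L), 0)
  ctrl_below <- vapply(cand, function(t) sum(responses < t & labels == 0L), 0)

  best <- NULL
  for (li in seq_along(cand)) {
    for (ui in li:length(cand)) {
      # band [cand[li], cand[ui]]: below lower = negative, above upper = positive
      fn_case <- case_below[li]; tn_ctrl <- ctrl_below[li]
      tp_case <- n_case - case_below[ui]; fp_ctrl <- n_ctrl - ctrl_below[ui]
      inc <- n - (fn_case + tn_ctrl + tp_case + fp_ctrl)
      if (inc / n > max_inconclusive) next
      concl_case <- fn_case + tp_case
      concl_ctrl <- tn_ctrl + fp_ctrl
      if (concl_case == 0L || concl_ctrl == 0L) next
      sens <- tp_case / concl_case
      if (sens < target_sensitivity) next
      spec <- tn_ctrl / concl_ctrl
      width <- cand[ui] - cand[li]
      key <- c(spec, -width, -cand[li])
      if (is.null(best) || lexi_gt(key, best$key)) {
        best <- list(key = key, lower = cand[li], upper = cand[ui],
                     sens = sens, spec = spec, inc = inc / n)
      }
    }
  }
  if (is.null(best)) {
    frontier <- best_achievable_frontier(responses, labels, max_inconclusive)
    stop(sprintf(
      "infeasible targets (sensitivity >= %.2f with inconclusive <= %.2f); best achievable sensitivity %.3f (specificity %.3f)",
      target_sensitivity, max_inconclusive, frontier$sens, frontier$spec))
  }
  model$lower_threshold <- best$lower
  model$upper_threshold <- best$upper
  model
}

lexi_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + 1e-12) return(TRUE)
    if (a[i] < b[i] - 1e-12) return(FALSE)
  }
  FALSE
}

best_achievable_frontier <- function(responses, labels, max_inconclusive) {
  # collapsed band: single threshold at max sensitivity
  sv <- sort(unique(responses), decreasing = TRUE)
  best_sens <- 0; best_spec <- 0
  for (t in c(sv, sv[length(sv)] - 1)) {
    sens <- mean(responses[labels == 1L] > t)
    if (sens > best_sens) {
      best_sens <- sens
      best_spec <- mean(responses[labels == 0L] <= t)
    }
  }
  list(sens = best_sens, spec = best_spec)
}

#' Read / write response tables and combination models
#'
#' Response tables use the long CSV layout `child_id, module_id, score,
#' label`; combination models serialise module order, covariance,
#' thresholds and ridge as JSON.
#'
#' @param path File path.
#' @return [read_responses()]: list with `responses` matrix and `labels`.
#' @export
read_responses <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("child_id", "module_id", "score", "label") %in% names(x)))
  mods <- unique(x$module_id)
  ids <- unique(x$child_id)
  m <- matrix(NA_real_, length(ids), length(mods),
              dimnames = list(ids, mods))
  m[cbind(match(x$child_id, ids), match(x$module_id, mods))] <- x$score
  lab <- x$label[match(ids, x$child_id)]
  list(responses = m, labels = as.integer(lab))
}

#' @rdname read_responses
#' @param responses Children x modules score matrix.
#' @param labels Binary truth per child.
#' @export
write_responses <- function(responses, labels, path) {
  long <- data.frame(
    child_id = rep(rownames(responses), ncol(responses)),
    module_id = rep(colnames(responses), each = nrow(responses)),
    score = as.numeric(responses),
    label = rep(as.integer(labels), ncol(responses)))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_responses
#' @export
read_combination_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  combination_model(x$module_ids, matrix(unlist(x$sigma),
                                         length(x$module_ids), byrow = TRUE),
                    x$lower_threshold, x$upper_threshold, x$ridge)
}

#' @rdname read_responses
#' @param model A `combination_model` to serialise.
#' @export
write_combination_model <- function(model, path) {
  x <- list(module_ids = model$module_ids,
            sigma = apply(model$sigma, 1, as.numeric, simplify = FALSE),
            lower_threshold = model$lower_threshold,
            upper_threshold = model$upper_threshold, ridge = model$ridge)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
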
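#' Area under the ROC curve (Mann-Whitney convention)
#'
#' Internal fast scalar AUC: rank-average tie handling, equivalent to the
#' normalised Mann-Whitney U statistic.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
auc_value <- function(scores, labels) {
  labels <- as.integer(labels)
  m <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (m == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n0)
}

#' ROC curve and AUC report
#'
#' Builds the empirical ROC (one point per distinct threshold, predicted
#' positive when `score > threshold`) and the AUC by rank statistic
#' (identical to trapezoidal integration of that curve).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = case).
#' @return An `eval_report`: `auc`, `roc` (data frame `fpr`, `tpr`,
#'   `threshold`), `n`, `coverage` (1 here; see [conclusive_metrics()]).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  m <- sum(y == 1L); n0 <- sum(y == 0L)
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tied block
  roc <- data.frame(fpr = c(0, fp[keep] / n0),
                    tpr = c(0, tp[keep] / m),
                    threshold = c(Inf, s[keep]))
  structure(list(auc = auc_value(scores, labels), roc = roc,
                 sensitivity = NA_real_, specificity = NA_real_,
                 coverage = 1, n = length(scores)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d, coverage = %.3f, AUC = %.4f\n",
              x$n, x$coverage, x$auc))
  if (!is.na(x$sensitivity))
    cat(sprintf("  operating point: sensitivity %.3f, specificity %.3f\n",
                x$sensitivity, x$specificity))
  invisible(x)
}

#' Specificity at a target sensitivity
#'
#' Finds the largest threshold (predict positive when `score >
#' threshold`) whose sensitivity is at least `target_sensitivity`, and
#' reports the specificity attained there.  Screening instruments are
#' conventionally compared at 90% sensitivity.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = case).
#' @param target_sensitivity Required true-positive rate (default 0.9).
#' @return List with `threshold` and `specificity`.
#' @export
spec_at_sens <- function(scores, labels, target_sensitivity = 0.9) {
  labels <- as.integer(labels)
  case <- sort(scores[labels == 1L]); ctrl <- sort(scores[labels == 0L])
  if (!length(case) || !length(ctrl)) stop("both classes must be present")
  # candidates descending; the threshold below min(scores) forces sens 1
  cand <- c(sort(unique(scores), decreasing = TRUE), min(scores) - 1)
  sens <- (length(case) - findInterval(cand, case)) / length(case)
  t <- cand[which(sens >= target_sensitivity)[1L]]
  list(threshold = t, specificity = findInterval(t, ctrl) / length(ctrl))
}

#' Bootstrap comparison of two screeners
#'
#' Paired comparison on the common children: `n_boot` bootstrap resamples
#' of the children are drawn; per resample the AUC difference
#' (`b - a`) and the difference in specificity at per-resample thresholds
#' achieving `target_sensitivity` are computed.  Means and empirical
#' 5th/95th percentiles are reported.  Resamples containing a single class
#' are redrawn (and counted) so `n_boot` effective draws remain.
#'
#' @param scores_a,scores_b Scores of the two screeners on the same,
#'   aligned children.
#' @param labels Binary labels (1 = case).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed; the report is deterministic under it and
#'   invariant to child ordering.
#' @param target_sensitivity Sensitivity at which specificities are
#'   compared (default 0.9).
#' @return A `delta_report`: `delta_auc_mean`, `delta_auc_ci`,
#'   `delta_spec_mean`, `delta_spec_ci`, `n_common`, `n_boot`,
#'   `n_redrawn`.
#' @export
bootstrap_delta <- function(scores_a, scores_b, labels, n_boot = 10000L,
                            seed = 1L, target_sensitivity = 0.9) {
  labels <- as.integer(labels)
  n <- length(labels)
  stopifnot(length(scores_a) == n, length(scores_b) == n)
  # canonical ordering so the report is invariant to input child order
  ord <- order(scores_a, scores_b, labels)
  scores_a <- scores_a[ord]; scores_b <- scores_b[ord]; labels <- labels[ord]
  set.seed(derive_seed(seed, "bootstrap_delta"))
  d_auc <- d_spec <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    y <- labels[idx]; sa <- scores_a[idx]; sb <- scores_b[idx]
    d_auc[b] <- auc_value(sb, y) - auc_value(sa, y)
    d_spec[b] <- spec_at_sens(sb, y, target_sensitivity)$specificity -
      spec_at_sens(sa, y, target_sensitivity)$specificity
  }
  if (n_redrawn > 0L)
    message(sprintf("bootstrap_delta: redrew %d single-class resample(s)",
                    n_redrawn))
  structure(list(delta_auc_mean = mean(d_auc),
                 delta_auc_ci = unname(stats::quantile(d_auc, c(0.05, 0.95))),
                 delta_spec_mean = mean(d_spec),
                 delta_spec_ci = unname(stats::quantile(d_spec, c(0.05, 0.95))),
                 n_common = n, n_boot = n_boot, n_redrawn = n_redrawn),
            class = "delta_report")
}

#' @export
print.delta_report <- function(x, ...) {
  cat(sprintf("delta_report (n = %d, %d resamples)\n", x$n_common, x$n_boot))
  cat(sprintf("  dAUC:  %.3f [%.3f, %.3f]\n", x$delta_auc_mean,
              x$delta_auc_ci[1], x$delta_auc_ci[2]))
  cat(sprintf("  dSpec: %.3f [%.3f, %.3f] (at target sensitivity)\n",
              x$delta_spec_mean, x$delta_spec_ci[1], x$delta_spec_ci[2]))
  invisible(x)
}

#' Metrics over the conclusive subset of three-way outcomes
#'
#' Coverage is the fraction of children receiving a conclusive
#' (non-abstained) verdict; AUC, sensitivity and specificity are computed
#' on that subset only.
#'
#' @param outcomes An `outcome` data frame ([as_outcomes()] /
#'   [predict.cascade_model()]): columns `child_id`, `verdict`, `score`.
#' @param labels Binary labels aligned with `outcomes` rows.
#' @return An `eval_report` with `coverage` and conclusive-subset metrics.
#' @export
conclusive_metrics <- function(outcomes, labels) {
  stopifnot(nrow(outcomes) == length(labels))
  labels <- as.integer(labels)
  concl <- outcomes$verdict != "inconclusive"
  if (!any(concl)) stop("zero conclusive samples")
  y <- labels[concl]
  pos <- outcomes$verdict[concl] == "positive"
  sens <- if (any(y == 1L)) mean(pos[y == 1L]) else NA_real_
  spec <- if (any(y == 0L)) mean(!pos[y == 0L]) else NA_real_
  auc <- if (length(unique(y)) == 2L)
    auc_value(outcomes$score[concl], y) else NA_real_
  rep <- list(auc = auc, roc = NULL, sensitivity = sens, specificity = spec,
              coverage = mean(concl), n = length(labels))
  class(rep) <- "eval_report"
  rep
}

#' Build an outcome table
#'
#' The three-way outcome record: every child gets a verdict in
#' `{positive, negative, inconclusive}`; inconclusive children may carry
#' `NA` scores.
#'
#' @param child_id Character ids.
#' @param verdict Character vector over the three allowed values.
#' @param score Optional numeric scores (`NA` allowed).
#' @return An `outcome` data frame.
#' @export
as_outcomes <- function(child_id, verdict, score = NA_real_) {
  allowed <- c("positive", "negative", "inconclusive")
  if (!all(verdict %in% allowed))
    stop("verdict must be one of: ", paste(allowed, collapse = ", "))
  out <- data.frame(child_id = as.character(child_id), verdict = verdict,
                    score = as.numeric(rep_len(score, length(child_id))),
                    stringsAsFactors = FALSE)
  class(out) <- c("outcome", "data.frame")
  out
}
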
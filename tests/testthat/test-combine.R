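test_that("combine_responses reproduces the closed-form examples", {
  m <- combination_model(c("a", "b"), diag(2), ridge = 0)
  expect_equal(combine_responses(m, c(0.5, 0.7)), 0.6)
  m2 <- combination_model(c("a", "b"), matrix(c(1, 0.5, 0.5, 1), 2), ridge = 0)
  expect_equal(combine_responses(m2, c(1, 0)), 0.5)
  m3 <- combination_model(c("a", "b"), diag(c(0.04, 0.01)), ridge = 0)
  expect_equal(combine_responses(m3, c(0.8, 0.6)), (25 * 0.8 + 100 * 0.6) / 125)
})

test_that("Eq-oracle equivalence: direct matrix evaluation and inverse-variance", {
  set.seed(1)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    A <- matrix(stats::rnorm(k * k), k)
    sigma <- crossprod(A) + diag(k) * 0.1
    R <- stats::runif(k)
    m <- combination_model(sprintf("m%d", 1:k), sigma, ridge = 0)
    ones <- rep(1, k)
    direct <- drop((t(ones) %*% solve(sigma) %*% R) /
                     (t(ones) %*% solve(sigma) %*% ones))
    expect_equal(combine_responses(m, R), direct, tolerance = 1e-10)
    # diagonal case: classical inverse-variance weights
    v <- stats::runif(k, 0.01, 1)
    md <- combination_model(sprintf("m%d", 1:k), diag(v), ridge = 0)
    expect_equal(combine_responses(md, R), sum(R / v) / sum(1 / v),
                 tolerance = 1e-10)
  }
})

test_that("combination invariants: permutation, unit weights, equal scores", {
  set.seed(2)
  k <- 4L
  A <- matrix(stats::rnorm(k * k), k); sigma <- crossprod(A) + diag(k)
  ids <- sprintf("m%d", 1:k)
  m <- combination_model(ids, sigma, ridge = 0)
  R <- stats::runif(k)
  perm <- sample(k)
  mp <- combination_model(ids[perm], sigma[perm, perm], ridge = 0)
  expect_equal(combine_responses(mp, R[perm]), combine_responses(m, R),
               tolerance = 1e-12)
  expect_equal(combine_responses(m, rep(0.37, k)), 0.37, tolerance = 1e-12)
  # missing modules: combination over the available submatrix
  R2 <- R; R2[2] <- NA
  sub <- combination_model(ids[-2], sigma[-2, -2], ridge = 0)
  expect_equal(combine_responses(m, R2), combine_responses(sub, R[-2]),
               tolerance = 1e-12)
  expect_error(combine_responses(m, rep(NA_real_, k)), "no module")
})

test_that("fit_combination estimates Sigma from residuals and handles rank deficiency", {
  set.seed(3)
  n <- 5000L
  labels <- rep_len(c(1L, 0L), n)
  v <- c(0.04, 0.01)
  resp <- cbind(a = labels + stats::rnorm(n, 0, sqrt(v[1])),
                b = labels + stats::rnorm(n, 0, sqrt(v[2])))
  rownames(resp) <- sprintf("c%05d", seq_len(n))
  fit <- fit_combination(resp, labels)
  w <- modscreen:::combination_weights(fit$sigma, fit$ridge)
  expect_lt(max(abs(w - (1 / v) / sum(1 / v))), 0.05)
  # duplicated module: singular Sigma must be rescued by the ridge and the
  # combination equal the common response
  dup <- cbind(a = resp[, 1], b = resp[, 1])
  fdup <- fit_combination(dup, labels, ridge = 1e-6)
  expect_equal(combine_responses(fdup, c(0.42, 0.42)), 0.42, tolerance = 1e-6)
  expect_error(modscreen:::combination_weights(matrix(1, 2, 2), 0), "ridge")
  expect_error(fit_combination(resp[1:2, ], labels[1:2]), "at least 3")
  expect_error(fit_combination(resp, labels[1:10]), "misaligned")
})

test_that("leave-one-out responses stay close to full-Sigma responses", {
  set.seed(4)
  n <- 1000L
  labels <- rep_len(c(1L, 1L, 0L), n)
  resp <- cbind(a = stats::plogis(stats::rnorm(n, labels * 2 - 1)),
                b = stats::plogis(stats::rnorm(n, labels * 2 - 1)),
                c = stats::plogis(stats::rnorm(n, labels * 2 - 1)))
  rownames(resp) <- sprintf("c%05d", seq_len(n))
  fit <- fit_combination(resp, labels)
  full <- apply(resp, 1, function(r) combine_responses(fit, r))
  expect_lt(max(abs(fit$loo_responses - full)), 0.01)
  # exactness: recomputing one child's LOO covariance from scratch agrees
  i <- 17L
  sig_i <- stats::cov(resp[-i, ] - labels[-i])
  w <- modscreen:::combination_weights(sig_i, fit$ridge)
  expect_equal(unname(fit$loo_responses[i]), sum(w * resp[i, ]),
               tolerance = 1e-10)
})

test_that("banded outcomes follow the dual-threshold rule", {
  m <- combination_model("a", matrix(1), lower_threshold = 0.4,
                         upper_threshold = 0.6)
  expect_identical(banded_outcome(m, c(0.39, 0.4, 0.5, 0.6, 0.61)),
                   c("negative", "inconclusive", "inconclusive",
                     "inconclusive", "positive"))
  mc <- combination_model("a", matrix(1), lower_threshold = 0.5,
                          upper_threshold = 0.5)
  expect_identical(banded_outcome(mc, c(0.49, 0.5, 0.51)),
                   c("negative", "inconclusive", "positive"))
  m01 <- combination_model("a", matrix(1), lower_threshold = 0,
                           upper_threshold = 1)
  expect_true(all(banded_outcome(m01, stats::runif(20, 0.01, 0.99)) ==
                    "inconclusive"))
})

test_that("inconclusive fraction weakly increases with band width", {
  set.seed(5)
  r <- stats::runif(500)
  m <- combination_model("a", matrix(1))
  widths <- seq(0, 0.8, 0.1)
  fracs <- vapply(widths, function(wd) {
    mw <- m; mw$lower_threshold <- 0.5 - wd / 2; mw$upper_threshold <- 0.5 + wd / 2
    mean(banded_outcome(mw, r) == "inconclusive")
  }, 0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("tune_band attains the exhaustive-sweep optimum on a n=300 fixture", {
  set.seed(6)
  n <- 300L
  labels <- rep_len(c(1L, 1L, 0L), n)
  r <- stats::plogis(stats::rnorm(n, labels * 1.6 - 0.8))
  m <- combination_model("a", matrix(1))
  tuned <- tune_band(m, r, labels, target_sensitivity = 0.9,
                     max_inconclusive = 0.3)
  got <- band_metrics(r, labels, tuned$lower_threshold, tuned$upper_threshold)
  expect_lte(got$inconclusive, 0.3)
  expect_gte(got$sens, 0.9)
  # oracle: brute-force all candidate pairs over the same grid
  sv <- sort(unique(r))
  cand <- c(sv[1] - 1, (sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)] + 1)
  best_spec <- -Inf
  for (li in seq_along(cand)) for (ui in li:length(cand)) {
    bm <- band_metrics(r, labels, cand[li], cand[ui])
    if (is.na(bm$sens) || is.na(bm$spec)) next
    if (bm$inconclusive > 0.3 || bm$sens < 0.9) next
    if (bm$spec > best_spec) best_spec <- bm$spec
  }
  expect_equal(got$spec, best_spec)
})

test_that("tune_band extremes and infeasibility", {
  labels <- rep_len(c(1L, 0L), 100L)
  r_sep <- ifelse(labels == 1L, stats::runif(100, 0.8, 1),
                  stats::runif(100, 0, 0.2))
  m <- combination_model("a", matrix(1))
  t_sep <- tune_band(m, r_sep, labels, target_sensitivity = 1,
                     max_inconclusive = 0)
  got <- band_metrics(r_sep, labels, t_sep$lower_threshold,
                      t_sep$upper_threshold)
  expect_equal(got$spec, 1); expect_equal(got$sens, 1)
  expect_equal(got$inconclusive, 0)
  # max_inconclusive = 0 forces a collapsed band between two data points
  t0 <- tune_band(m, r_sep, labels, 0.9, 0)
  expect_equal(mean(banded_outcome(t0, r_sep) == "inconclusive"), 0)
  # anti-informative scores: the sensitivity target is still met by the
  # degenerate all-positive band, at the price of zero specificity
  r_anti <- 1 - r_sep
  t_anti <- tune_band(m, r_anti, labels, 0.95, 0)
  got_anti <- band_metrics(r_anti, labels, t_anti$lower_threshold,
                           t_anti$upper_threshold)
  expect_gte(got_anti$sens, 0.95)
  expect_equal(got_anti$spec, 0)
})

test_that("response tables and combination models round-trip through files", {
  set.seed(7)
  resp <- matrix(round(stats::runif(12), 6), 4, 3,
                 dimnames = list(sprintf("c%d", 1:4), c("p", "v", "c")))
  labels <- c(1L, 0L, 1L, 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(resp, labels, path)
  back <- read_responses(path)
  expect_equal(back$responses, resp)
  expect_identical(back$labels, labels)

  m <- combination_model(c("p", "v", "c"), diag(3) + 0.1, 0.3, 0.7, 1e-6)
  jp <- withr::local_tempfile(fileext = ".json")
  write_combination_model(m, jp)
  expect_equal(read_combination_model(jp), m)
})
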
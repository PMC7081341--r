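train_fixture <- function(sep = 1.3, n_case = 160L, n_control = 80L,
                          seed = 1L) {
  cfg <- generator_config(n_case = n_case, n_control = n_control,
                          class_separation = sep, seed = seed,
                          age_range = c(18L, 47L))
  generate_training(cfg)
}

fast_cfg <- function(seed = 1L, ...) {
  train_config(grid = list(list(n_trees = 40L, max_depth = 2L,
                                learning_rate = 0.2)),
               seed = seed, ...)
}

test_that("training is deterministic and rejects degenerate inputs", {
  ds <- train_fixture(seed = 2L)
  m1 <- train_cascade(ds, fast_cfg(seed = 5L))
  m2 <- train_cascade(ds, fast_cfg(seed = 5L))
  expect_equal(m1, m2)
  out1 <- predict(m1, ds); out2 <- predict(m2, ds)
  expect_identical(out1$verdict, out2$verdict)

  one_class <- subset_sheets(ds, ds$sheets$label == 1L)
  expect_error(train_cascade(one_class, fast_cfg()), "single class")
  unlabelled <- ds; unlabelled$sheets$label <- NA_integer_
  expect_error(train_cascade(unlabelled, fast_cfg()), "labelled")
})

test_that("easy regime: separable data produce almost no incorrect labels", {
  cfg <- generator_config(n_case = 120L, n_control = 60L,
                          class_separation = 10,
                          discrimination = rep(10, 20L),
                          cutpoints = matrix(rep(c(20, 50, 80), each = 20L),
                                             nrow = 20L),
                          seed = 4L, age_range = c(18L, 47L))
  ds <- generate_training(cfg)
  m <- train_cascade(ds, fast_cfg(seed = 2L))
  out <- predict(m, ds)
  expect_lt(mean(out$verdict == "inconclusive"), 0.05)
  concl <- out$verdict != "inconclusive"
  expect_equal(mean((out$verdict[concl] == "positive") ==
                      (ds$sheets$label[concl] == 1L)), 1.0)
})

test_that("randomised labels make the filter no better than chance", {
  ds <- train_fixture(seed = 6L, n_case = 150L, n_control = 150L)
  set.seed(8)
  ds$sheets$label <- sample(ds$sheets$label)
  m <- train_cascade(ds, fast_cfg(seed = 3L))
  # fresh children with fresh random labels: neither the filter nor the
  # binary model can beat chance out of sample (AUC SE here is ~0.033)
  fresh <- train_fixture(seed = 60L, n_case = 150L, n_control = 150L)
  fresh$sheets$label <- sample(fresh$sheets$label)
  out <- predict(m, fresh)
  expect_lt(abs(auc_value(attr(out, "filter_score"),
                          fresh$sheets$label) - 0.5), 0.1)
  expect_lt(abs(auc_value(attr(out, "binary_score"),
                          fresh$sheets$label) - 0.5), 0.1)
})

test_that("filter threshold extremes and coverage monotonicity", {
  ds <- train_fixture(seed = 7L)
  m <- train_cascade(ds, fast_cfg(seed = 4L))
  test_ds <- train_fixture(seed = 70L)

  m_off <- m; m_off$filter_threshold <- 1.0
  expect_false(any(predict(m_off, test_ds)$verdict == "inconclusive"))

  m_all <- m; m_all$filter_threshold <- 0.0
  out_all <- predict(m_all, test_ds)
  fs <- attr(out_all, "filter_score")
  expect_true(all(out_all$verdict[fs > 0] == "inconclusive"))

  # brute-force sweep: inconclusive fraction non-increasing in threshold
  fracs <- vapply(seq(0, 1, 0.05), function(t) {
    mt <- m; mt$filter_threshold <- t
    mean(predict(mt, test_ds)$verdict == "inconclusive")
  }, 0)
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("prediction is pure and tolerates SKIPs in new sheets", {
  ds <- train_fixture(seed = 9L)
  m <- train_cascade(ds, fast_cfg(seed = 1L))
  test_ds <- train_fixture(seed = 90L)
  x <- test_ds$sheets
  x$Q01 <- NA_integer_; x$Q05 <- NA_integer_
  holey <- score_dataset(x, test_ds$questions)
  o1 <- predict(m, holey); o2 <- predict(m, holey)
  expect_identical(o1, o2)
  expect_true(all(o1$verdict %in% c("positive", "negative", "inconclusive")))
  expect_true(all(is.na(o1$score[o1$verdict == "inconclusive"])))
  expect_true(all(!is.na(o1$score[o1$verdict != "inconclusive"])))
})

test_that("tune_thresholds matches an exhaustive sweep on a n=300 fixture", {
  ds <- train_fixture(seed = 11L)
  m <- train_cascade(ds, fast_cfg(seed = 6L))
  tune_ds <- train_fixture(seed = 110L, n_case = 200L, n_control = 100L)
  tuned <- tune_thresholds(m, tune_ds, target_sensitivity = 0.9,
                           max_inconclusive = 0.3)

  y <- tune_ds$sheets$label
  x <- answers_matrix(tune_ds, m$feature_ids)
  fs <- predict(m$filter_model, x)
  bs <- predict(m$binary_model, x)
  # oracle: evaluate every candidate filter threshold directly
  best <- list(auc = -Inf, t = NA)
  for (t in sort(unique(c(fs, 1)), decreasing = TRUE)) {
    keep <- fs <= t
    if (mean(!keep) > 0.3 || length(unique(y[keep])) < 2L) next
    a <- auc_value(bs[keep], y[keep])
    if (a > best$auc + 1e-12) best <- list(auc = a, t = t)
  }
  expect_equal(tuned$filter_threshold, best$t)
  keep <- fs <= best$t
  want_dec <- sweep_spec_at_sens(bs[keep], y[keep], 0.9)$threshold
  expect_equal(tuned$decision_threshold, want_dec)
  # attained operating point honours the targets
  out <- predict(tuned, tune_ds)
  expect_lte(mean(out$verdict == "inconclusive"), 0.3)
  concl <- out$verdict != "inconclusive"
  expect_gte(mean(out$verdict[concl & y == 1L] == "positive"), 0.9)
})

test_that("tuning extremes: abstention disabled and forced full sensitivity", {
  ds <- train_fixture(seed = 13L)
  m <- train_cascade(ds, fast_cfg(seed = 7L))
  tune_ds <- train_fixture(seed = 130L)
  t0 <- tune_thresholds(m, tune_ds, max_inconclusive = 0)
  expect_false(any(predict(t0, tune_ds)$verdict == "inconclusive"))

  t1 <- tune_thresholds(m, tune_ds, target_sensitivity = 1.0)
  out <- predict(t1, tune_ds)
  concl <- out$verdict != "inconclusive"
  y <- tune_ds$sheets$label
  expect_equal(mean(out$verdict[concl & y == 1L] == "positive"), 1.0)
  bs <- attr(out, "binary_score")
  expect_lt(t1$decision_threshold, min(bs[concl & y == 1L]))
})

test_that("weight balancing changes the fit when cells are imbalanced", {
  ds <- train_fixture(seed = 15L, n_case = 200L, n_control = 40L)
  m_bal <- train_cascade(ds, fast_cfg(seed = 2L, weight_balance = TRUE))
  m_raw <- train_cascade(ds, fast_cfg(seed = 2L, weight_balance = FALSE))
  test_ds <- train_fixture(seed = 150L)
  sb <- attr(predict(m_bal, test_ds), "binary_score")
  sr <- attr(predict(m_raw, test_ds), "binary_score")
  expect_false(isTRUE(all.equal(sb, sr)))
})
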
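sim_shift_pair <- function(n_per_class = 200L, nq = 5L, shift_q1 = 0L,
                           seed = 1L) {
  set.seed(seed)
  schema <- question_schema(sprintf("Q%02d", seq_len(nq)))
  mk <- function(cohort, shift) {
    n <- 2L * n_per_class
    sheets <- data.frame(child_id = sprintf("%s%04d", cohort, seq_len(n)),
                         age_months = 30L,
                         label = rep(c(1L, 0L), each = n_per_class),
                         cohort = cohort, stringsAsFactors = FALSE)
    for (k in seq_len(nq)) {
      a <- sample(0:2, n, replace = TRUE) + (sheets$label == 1L)
      if (k == 1L) a <- pmin(a + shift, 3L)
      sheets[[schema$id[k]]] <- as.integer(a)
    }
    score_dataset(sheets, schema)
  }
  list(train = mk("training", 0L), deploy = mk("deployment", shift_q1))
}

test_that("identical datasets yield zero rejections and zero statistics", {
  d <- sim_shift_pair(seed = 2L)
  rep0 <- shift_reject(d$train, d$train)
  expect_true(all(rep0$statistic == 0))
  expect_false(any(rep0$rejected))
})

test_that("a +1 shift on one question is rejected, others survive", {
  d <- sim_shift_pair(n_per_class = 300L, shift_q1 = 1L, seed = 3L)
  rep1 <- shift_reject(d$train, d$deploy)
  expect_true(rep1$rejected[rep1$question == "Q01"])
  expect_gt(rep1$statistic[1], 3)
})

test_that("the shift statistic is sign-symmetric and scale-covariant", {
  d <- sim_shift_pair(seed = 4L)
  up <- d$deploy; dn <- d$deploy
  up$sheets$Q02 <- pmin(up$sheets$Q02 + 1L, 3L)
  r_up <- shift_reject(d$train, up)
  # doubling all severities leaves the statistic unchanged (d and se scale
  # together); use max_severity 6 schema to hold the codes
  schema2 <- question_schema(d$train$questions$id, max_severity = 6L)
  dbl <- function(ds) {
    sh <- ds$sheets
    for (q in schema2$id) sh[[q]] <- sh[[q]] * 2L
    score_dataset(sh, schema2)
  }
  r_dbl <- shift_reject(dbl(d$train), dbl(up))
  expect_equal(r_dbl$statistic, r_up$statistic, tolerance = 1e-12)
})

test_that("shift_reject refuses an empty class", {
  d <- sim_shift_pair(seed = 5L)
  cases_only <- subset_sheets(d$deploy, d$deploy$sheets$label == 1L)
  expect_error(shift_reject(d$train, cases_only), "control.*deploy")
})

no_skip_dataset <- function(n = 60L, nq = 4L, seed = 6L) {
  set.seed(seed)
  schema <- question_schema(sprintf("Q%02d", seq_len(nq)))
  sheets <- data.frame(child_id = sprintf("K%03d", seq_len(n)),
                       age_months = 30L, label = rep_len(c(1L, 0L), n),
                       cohort = "training", stringsAsFactors = FALSE)
  for (q in schema$id) sheets[[q]] <- sample(0:3, n, replace = TRUE)
  score_dataset(sheets, schema)
}

test_that("perturb_rank orders questions by model sensitivity", {
  ds <- no_skip_dataset(seed = 6L)
  # model driven by Q01 only
  mono <- function(x) stats::plogis((x[, 1] - 1.5))
  r <- perturb_rank(mono, ds, threshold = 0.5, band = c(0, 0.45))
  expect_identical(r$question[1], "Q01")
  expect_equal(r$mean_shift[r$question != "Q01"], rep(0, 3))
  # untouched input
  expect_identical(ds$sheets, no_skip_dataset(seed = 6L)$sheets)
})

test_that("linear-logit ranking matches the closed-form coefficient order", {
  set.seed(7)
  nq <- 4L
  beta <- c(1.6, 0.8, 0.4, 0.1)
  schema <- question_schema(sprintf("Q%02d", seq_len(nq)))
  n <- 500L
  sheets <- data.frame(child_id = sprintf("c%04d", seq_len(n)),
                       age_months = 30L, label = rep_len(c(1L, 0L), n),
                       cohort = "training", stringsAsFactors = FALSE)
  for (k in seq_len(nq))
    sheets[[schema$id[k]]] <- sample(0:3, n, replace = TRUE)
  ds <- score_dataset(sheets, schema)
  lin <- function(x) stats::plogis(drop(x %*% beta) - 4.5)
  r <- perturb_rank(lin, ds, threshold = 0.5, band = c(0, 0.2))
  expect_identical(r$question, schema$id)   # beta already sorted descending
  # closed-form check on one child: |plogis(eta - beta1) - plogis(eta)|
  x0 <- answers_matrix(ds)[which(lin(answers_matrix(ds)) > 0.5 &
                                   lin(answers_matrix(ds)) <= 0.7)[1], ,
                           drop = FALSE]
  eta <- drop(x0 %*% beta) - 4.5
  if (x0[1] > 0)
    expect_equal(abs(stats::plogis(eta - beta[1]) - stats::plogis(eta)),
                 abs(lin(`[<-`(x0, 1, x0[1] - 1)) - lin(x0)))
})

test_that("perturbation respects severity bounds, SKIPs and empty bands", {
  ds <- tiny_dataset(n = 20L, nq = 3L, seed = 8L)
  probe <- function(x) {
    expect_true(all(x >= 0 & x <= 3, na.rm = TRUE))
    rep(0.95, nrow(x))   # everyone far above any threshold
  }
  expect_warning(r <- perturb_rank(probe, ds, threshold = 0.5,
                                   band = c(0, 0.1)),
                 "empty ranking")
  expect_identical(nrow(r), 0L)
})

test_that("shortlist union sizes and ordering follow the min-rank rule", {
  ids <- sprintf("Q%02d", 1:21)
  same <- ids[1:10]
  expect_length(shortlist_clinician(same, same, same, top_k = 7L), 7L)
  disjoint <- shortlist_clinician(ids[1:7], ids[8:14], ids[15:21],
                                  top_k = 7L)
  expect_length(disjoint, 21L)
  # engineered overlap of 5 between each pair of lists
  la <- ids[1:7]; lb <- c(ids[1:5], ids[8:9]); lc <- c(ids[1:5], ids[10:11])
  got <- shortlist_clinician(la, lb, lc, top_k = 7L)
  expect_setequal(got, union(union(la, lb), lc))     # brute-force union
  expect_length(got, 11L)
  # min-rank ordering with id tie-break
  expect_identical(got[1:5], ids[1:5])
  expect_true(all(shortlist_clinician(la, lb, lc, top_k = 7L,
                                      allow_list = ids[1:3]) %in% ids[1:3]))
  expect_lte(length(got), 3L * 7L)
})

test_that("backward elimination keeps planted signal and terminates on noise", {
  set.seed(9)
  nq <- 8L
  schema <- question_schema(sprintf("Q%02d", seq_len(nq)))
  n <- 240L
  sheets <- data.frame(child_id = sprintf("c%04d", seq_len(n)),
                       age_months = 30L,
                       label = rep_len(c(1L, 0L), n), cohort = "training",
                       stringsAsFactors = FALSE)
  for (k in seq_len(nq)) sheets[[schema$id[k]]] <- sample(0:3, n, TRUE)
  # plant all the signal in Q01 and Q02
  sheets$Q01 <- pmin(3L, sheets$Q01 + 2L * sheets$label)
  sheets$Q02 <- pmin(3L, sheets$Q02 + 2L * sheets$label)
  ds <- score_dataset(sheets, schema)
  kept <- backward_eliminate(ds, n_boot = 6L, min_features = 2L, seed = 1L)
  expect_setequal(kept, c("Q01", "Q02"))
  expect_identical(backward_eliminate(ds, n_boot = 3L, min_features = nq,
                                      seed = 1L), schema$id)
  # pure noise: must terminate and honour min_features
  for (k in seq_len(nq)) sheets[[schema$id[k]]] <- sample(0:3, n, TRUE)
  noise_ds <- score_dataset(sheets, schema)
  out <- backward_eliminate(noise_ds, n_boot = 3L, min_features = 1L,
                            seed = 2L, tol = Inf)
  expect_length(out, 1L)
  expect_error(backward_eliminate(ds, min_features = nq + 1L), "min_features")
})
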
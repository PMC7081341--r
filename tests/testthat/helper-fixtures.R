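# shared fixtures and independent oracles

# small hand-made dataset; ages straddle the silo boundary
tiny_dataset <- function(n = 6L, nq = 4L, seed = 42L) {
  set.seed(seed)
  schema <- question_schema(sprintf("Q%02d", seq_len(nq)))
  sheets <- data.frame(child_id = sprintf("K%03d", seq_len(n)),
                       age_months = sample(18:72, n, replace = TRUE),
                       label = rep_len(c(1L, 0L), n),
                       cohort = "training",
                       stringsAsFactors = FALSE)
  for (q in schema$id)
    sheets[[q]] <- sample(c(0:3, NA), n, replace = TRUE,
                          prob = c(rep(0.22, 4), 0.12))
  score_dataset(sheets, schema)
}

# brute-force AUC: pair counting with half credit for ties
pair_count_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# brute-force specificity at target sensitivity: sweep every candidate
# threshold (predict positive when score > t)
sweep_spec_at_sens <- function(scores, labels, target) {
  cand <- sort(unique(c(scores, min(scores) - 1)), decreasing = TRUE)
  for (t in cand) {
    sens <- mean(scores[labels == 1] > t)
    if (sens >= target)
      return(list(threshold = t, specificity = mean(scores[labels == 0] <= t)))
  }
}

# brute-force three-way band metrics for a (lower, upper) pair
band_metrics <- function(r, labels, lower, upper) {
  verdict <- ifelse(r < lower, "negative",
                    ifelse(r > upper, "positive", "inconclusive"))
  concl <- verdict != "inconclusive"
  y <- labels[concl]
  list(inconclusive = mean(!concl),
       sens = if (any(y == 1)) mean(verdict[concl][y == 1] == "positive") else NA,
       spec = if (any(y == 0)) mean(verdict[concl][y == 0] == "negative") else NA)
}
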
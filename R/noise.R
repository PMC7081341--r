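#' Estimate a setting-noise probability map from paired answers
#'
#' From records of children answered under two settings (e.g. a clinic
#' instrument vs home-video analysts), builds one conditional probability
#' table per question: `P(deployment answer or SKIP | source answer)`.
#' SKIP is a first-class outcome column.  Cells receive Laplace smoothing
#' `alpha`; a source code never observed in the pairs falls back to the
#' identity row (pass-through), which conservatively preserves the answer
#' rather than randomising it.
#'
#' Pairs whose source answer is SKIP carry no information about the
#' conditional table and are excluded from estimation.
#'
#' @param pairs A `paired_sheets` object ([generate_paired()]) or a list
#'   with aligned `source` and `deployment` datasets sharing a schema.
#' @param smoothing_alpha Laplace pseudo-count per cell (default 0.5).
#' @return A `noise_map`: per question a probability matrix
#'   (rows = source codes `0..max`, columns = deployment codes plus
#'   `"SKIP"`), the raw count matrix, and `smoothing_alpha`.
#' @export
estimate_noise_map <- function(pairs, smoothing_alpha = 0.5) {
  src <- pairs$source; dep <- pairs$deployment
  stopifnot(inherits(src, "score_dataset"), inherits(dep, "score_dataset"))
  if (!identical(src$questions, dep$questions))
    stop("paired datasets have mismatched question schemas")
  if (!identical(src$sheets$child_id, dep$sheets$child_id))
    stop("paired datasets are not aligned by child_id")
  if (smoothing_alpha < 0) stop("smoothing_alpha must be >= 0")
  schema <- src$questions
  ms <- answers_matrix(src); md <- answers_matrix(dep)
  tabs <- vector("list", nrow(schema))
  names(tabs) <- schema$id
  counts <- tabs
  for (k in seq_len(nrow(schema))) {
    mx <- schema$max_severity[k]
    codes <- 0:mx
    cols <- c(as.character(codes), "SKIP")
    cnt <- matrix(0, nrow = mx + 1L, ncol = mx + 2L,
                  dimnames = list(as.character(codes), cols))
    s <- ms[, k]; d <- md[, k]
    ok <- !is.na(s)
    s <- s[ok]; d <- d[ok]
    dcol <- ifelse(is.na(d), mx + 2L, d + 1L)
    for (i in seq_along(s)) cnt[s[i] + 1L, dcol[i]] <- cnt[s[i] + 1L, dcol[i]] + 1
    prob <- cnt
    for (r in seq_len(nrow(cnt))) {
      tot <- sum(cnt[r, ])
      if (tot == 0) {                       # unseen source code: identity row
        prob[r, ] <- 0; prob[r, r] <- 1
      } else {
        prob[r, ] <- (cnt[r, ] + smoothing_alpha) /
          (tot + smoothing_alpha * ncol(cnt))
      }
    }
    tabs[[k]] <- prob
    counts[[k]] <- cnt
  }
  structure(list(questions = schema, prob = tabs, counts = counts,
                 smoothing_alpha = smoothing_alpha),
            class = "noise_map")
}

#' @export
print.noise_map <- function(x, ...) {
  n_obs <- sum(vapply(x$counts, sum, 0))
  cat(sprintf("noise_map: %d questions, %d paired observations, alpha = %g\n",
              nrow(x$questions), n_obs, x$smoothing_alpha))
  skipmass <- mean(vapply(x$prob, function(p) mean(p[, "SKIP"]), 0))
  cat(sprintf("  mean per-row SKIP mass: %.3f\n", skipmass))
  invisible(x)
}

#' Apply a setting-noise map as a stochastic transform
#'
#' Every answer in `ds` is independently resampled from its question's
#' conditional row; draws landing on the SKIP column become SKIP markers.
#' Source answers that are already SKIP pass through unchanged.  Labels,
#' ages, ids and row order are untouched.  The result can be read as a
#' hypothetical re-observation of the same children under the deployment
#' setting, and is the noise-injected training set for the video-style
#' module.
#'
#' @param ds A `score_dataset` whose codes lie within the map's range.
#' @param map A `noise_map` from [estimate_noise_map()].
#' @param seed Integer seed; the transform is deterministic under it.
#' @param replicates Number of noisy copies of each child to emit
#'   (default 1); copies beyond the first get suffixed child ids.
#' @return A `score_dataset` of `nrow * replicates` sheets.
#' @export
inject_noise <- function(ds, map, seed, replicates = 1L) {
  stopifnot(inherits(ds, "score_dataset"), inherits(map, "noise_map"))
  if (!all(ds$questions$id %in% map$questions$id))
    stop("dataset contains questions missing from the noise map")
  set.seed(derive_seed(seed, "inject"))
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sheets <- ds$sheets
    for (k in seq_len(nrow(ds$questions))) {
      q <- ds$questions$id[k]
      mx <- ds$questions$max_severity[k]
      prob <- map$prob[[q]]
      a <- sheets[[q]]
      new_a <- a
      for (s in 0:mx) {
        rows <- which(!is.na(a) & a == s)
        if (!length(rows)) next
        if (s + 1L > nrow(prob))
          stop(sprintf("answer code %d for '%s' outside noise-map range", s, q))
        draw <- sample.int(ncol(prob), length(rows), replace = TRUE,
                           prob = prob[s + 1L, ])
        val <- ifelse(draw == ncol(prob), NA_integer_, as.integer(draw - 1L))
        new_a[rows] <- val
      }
      sheets[[q]] <- new_a
    }
    if (r > 1L) sheets$child_id <- sprintf("%s_r%d", sheets$child_id, r)
    out[[r]] <- sheets
  }
  score_dataset(do.call(rbind, out), ds$questions, validate = FALSE)
}

#' Read / write a noise map as JSON
#'
#' Serialised as `{question_id: {source_code: {dep_code_or_SKIP: prob}}}`
#' with a parallel `counts` block and the smoothing constant.
#'
#' @param path JSON file path.
#' @return [read_noise_map()]: a `noise_map`.
#' @export
read_noise_map <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  schema <- question_schema(vapply(x$questions, `[[`, "", "id"),
                            vapply(x$questions, function(q) q$max_severity, 0),
                            vapply(x$questions, function(q) q$allows_skip, TRUE))
  rebuild <- function(block) {
    lapply(schema$id, function(q) {
      rows <- block[[q]]
      m <- do.call(rbind, lapply(rows, function(r) unlist(r)))
      rownames(m) <- names(rows)
      m
    }) |> setNames(schema$id)
  }
  structure(list(questions = schema, prob = rebuild(x$prob),
                 counts = rebuild(x$counts),
                 smoothing_alpha = x$smoothing_alpha),
            class = "noise_map")
}

#' @rdname read_noise_map
#' @param map A `noise_map` to serialise.
#' @export
write_noise_map <- function(map, path) {
  mat2list <- function(m)
    lapply(seq_len(nrow(m)), function(r) as.list(m[r, ])) |>
      setNames(rownames(m))
  x <- list(questions = lapply(seq_len(nrow(map$questions)), function(k)
              as.list(map$questions[k, ])),
            prob = lapply(map$prob, mat2list),
            counts = lapply(map$counts, mat2list),
            smoothing_alpha = map$smoothing_alpha)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
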
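#' modscreen: multi-modular, abstention-capable screening classifiers
#'
#' Builds and evaluates multi-modular diagnostic screeners from ordinal
#' questionnaire score sheets.  The package covers the full pipeline:
#' synthetic score-sheet generation with a latent-trait graded-response
#' model ([generate_training()]), setting-noise estimation from paired
#' answers and stochastic injection ([estimate_noise_map()],
#' [inject_noise()]), distribution-shift feature rejection
#' ([shift_reject()]), perturbation-based question ranking
#' ([perturb_rank()]), an abstention-capable classifier cascade
#' ([train_cascade()]), inverse-covariance combination of module responses
#' ([fit_combination()]) and bootstrap screener comparison
#' ([bootstrap_delta()]).
#'
#' @useDynLib modscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif var sd quantile predict setNames cov plogis qlogis
#' @importFrom utils read.csv write.csv head
#' @keywords internal
"_PACKAGE"

# months-of-age boundary between the two modelling silos; 48 goes to the
# older silo
SILO_BOUNDARY_MONTHS <- 48L

#' Define an instrument schema
#'
#' An instrument is an ordered set of ordinal questions.  Each question has
#' an integer severity range `0..max_severity` and may allow skipped
#' (unanswered) responses.
#'
#' @param ids Character vector of unique question ids.
#' @param max_severity Integer (scalar or per question), highest ordinal
#'   answer code. Typically 3.
#' @param allows_skip Logical (scalar or per question).
#' @return A `question_schema` data frame with columns `id`,
#'   `max_severity`, `allows_skip`.
#' @export
question_schema <- function(ids, max_severity = 3L, allows_skip = TRUE) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("question ids must be unique")
  max_severity <- as.integer(rep_len(max_severity, length(ids)))
  if (any(max_severity < 1L)) stop("max_severity must be >= 1")
  out <- data.frame(id = ids,
                    max_severity = max_severity,
                    allows_skip = rep_len(as.logical(allows_skip), length(ids)),
                    stringsAsFactors = FALSE)
  class(out) <- c("question_schema", "data.frame")
  out
}

#' Assemble a score-sheet dataset
#'
#' A dataset bundles an instrument schema with one row per child: id, age
#' in months, binary diagnostic label (1 = case, 0 = non-case, `NA` =
#' unknown), cohort tag and one integer column per question.  `NA` in an
#' answer column is the SKIP marker and is never conflated with severity
#' code 0.
#'
#' @param sheets Data frame with columns `child_id`, `age_months`, `label`,
#'   `cohort`, then one column per schema question.
#' @param schema A [question_schema()].
#' @param validate Check invariants (default `TRUE`).
#' @return A `score_dataset` object (list with `questions`, `sheets`,
#'   `age_silo`).
#' @export
score_dataset <- function(sheets, schema, validate = TRUE) {
  stopifnot(inherits(schema, "question_schema"))
  meta_cols <- c("child_id", "age_months", "label", "cohort")
  missing_meta <- setdiff(meta_cols, names(sheets))
  if (length(missing_meta))
    stop("sheets is missing columns: ", paste(missing_meta, collapse = ", "))
  extra <- setdiff(names(sheets), c(meta_cols, schema$id))
  if (length(extra))
    stop("unknown columns not in schema: ", paste(extra, collapse = ", "))
  missing_q <- setdiff(schema$id, names(sheets))
  if (length(missing_q))
    stop("sheets is missing question columns: ", paste(missing_q, collapse = ", "))
  sheets <- sheets[, c(meta_cols, schema$id), drop = FALSE]
  sheets$child_id <- as.character(sheets$child_id)
  sheets$age_months <- as.integer(sheets$age_months)
  sheets$label <- as.integer(sheets$label)
  sheets$cohort <- as.character(sheets$cohort)
  for (q in schema$id) sheets[[q]] <- as.integer(sheets[[q]])
  rownames(sheets) <- NULL
  ds <- structure(list(questions = schema, sheets = sheets,
                       age_silo = infer_silo(sheets$age_months)),
                  class = "score_dataset")
  if (validate) validate_dataset(ds)
  ds
}

infer_silo <- function(age_months) {
  if (!length(age_months)) return("mixed")
  if (all(age_months < SILO_BOUNDARY_MONTHS)) "under4"
  else if (all(age_months >= SILO_BOUNDARY_MONTHS)) "over4"
  else "mixed"
}

#' Validate a score dataset's invariants
#'
#' Checks answer ranges against the schema, non-negative ages, legal labels
#' and cohort tags.  Called by constructors and readers; exported for use
#' after manual edits.
#'
#' @param ds A `score_dataset`.
#' @return `ds`, invisibly. Throws on violation, naming row and question.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "score_dataset"))
  sh <- ds$sheets
  if (any(sh$age_months < 0L, na.rm = TRUE)) stop("age_months must be >= 0")
  bad_lab <- !(is.na(sh$label) | sh$label %in% c(0L, 1L))
  if (any(bad_lab)) stop("labels must be 0, 1 or NA (row ",
                         which(bad_lab)[1L], ")")
  bad_cohort <- !sh$cohort %in% c("training", "deployment")
  if (nrow(sh) && any(bad_cohort))
    stop("cohort must be 'training' or 'deployment' (row ",
         which(bad_cohort)[1L], ")")
  for (k in seq_len(nrow(ds$questions))) {
    q <- ds$questions$id[k]
    mx <- ds$questions$max_severity[k]
    a <- sh[[q]]
    bad <- !is.na(a) & (a < 0L | a > mx)
    if (any(bad))
      stop(sprintf("answer out of range for question '%s' at row %d: %d (max %d)",
                   q, which(bad)[1L], a[which(bad)[1L]], mx))
  }
  invisible(ds)
}

#' @export
print.score_dataset <- function(x, ...) {
  sh <- x$sheets
  cat(sprintf("score_dataset: %d children, %d questions, silo '%s'\n",
              nrow(sh), nrow(x$questions), x$age_silo))
  if (nrow(sh)) {
    cat(sprintf("  labels: %d case / %d non-case / %d unknown; cohorts: %s\n",
                sum(sh$label == 1L, na.rm = TRUE),
                sum(sh$label == 0L, na.rm = TRUE),
                sum(is.na(sh$label)),
                paste(unique(sh$cohort), collapse = ", ")))
    skip <- answers_matrix(x)
    cat(sprintf("  skip rate: %.3f\n", mean(is.na(skip))))
  }
  invisible(x)
}

#' Extract the answers as a numeric matrix
#'
#' Rows are children (in sheet order), columns are questions; SKIP becomes
#' `NA`.  This is the feature matrix consumed by the learners.
#'
#' @param ds A `score_dataset`.
#' @param feature_ids Optional subset/order of question ids.
#' @return Numeric matrix with `child_id` rownames.
#' @export
answers_matrix <- function(ds, feature_ids = NULL) {
  if (is.null(feature_ids)) feature_ids <- ds$questions$id
  miss <- setdiff(feature_ids, names(ds$sheets))
  if (length(miss)) stop("questions not in dataset: ", paste(miss, collapse = ", "))
  m <- as.matrix(ds$sheets[, feature_ids, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ds$sheets$child_id
  m
}

#' Read score sheets from CSV
#'
#' CSV dialect: UTF-8, comma separated, header
#' `child_id,age_months,label,cohort,<question ids...>`; an empty cell is
#' the SKIP marker (distinct from code 0); an empty `label` cell means
#' unknown.  Legacy "not applicable" instrument codes (7, 8, 9) appearing
#' above a question's `max_severity` are normalised to SKIP with a message
#' reporting the count; any other out-of-range code is an error naming row
#' and question.
#'
#' @param path CSV file path.
#' @param schema A [question_schema()] describing the expected columns.
#' @return A validated `score_dataset`; row order preserved.
#' @export
read_scoresheets <- function(path, schema) {
  stopifnot(inherits(schema, "question_schema"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  meta_cols <- c("child_id", "age_months", "label", "cohort")
  extra <- setdiff(names(raw), c(meta_cols, schema$id))
  if (length(extra)) stop("unknown column(s) in CSV: ", paste(extra, collapse = ", "))
  missing_cols <- setdiff(c(meta_cols, schema$id), names(raw))
  if (length(missing_cols))
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  n_legacy <- 0L
  parse_int <- function(x) {
    x[!nzchar(trimws(x))] <- NA_character_
    suppressWarnings(as.integer(x))
  }
  sheets <- data.frame(child_id = raw$child_id,
                       age_months = parse_int(raw$age_months),
                       label = parse_int(raw$label),
                       cohort = raw$cohort,
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(schema))) {
    q <- schema$id[k]
    a <- parse_int(raw[[q]])
    legacy <- !is.na(a) & a > schema$max_severity[k] & a %in% c(7L, 8L, 9L)
    n_legacy <- n_legacy + sum(legacy)
    a[legacy] <- NA_integer_
    bad <- !is.na(a) & (a < 0L | a > schema$max_severity[k])
    if (any(bad))
      stop(sprintf("out-of-range code for question '%s' at row %d: %s",
                   q, which(bad)[1L], raw[[q]][which(bad)[1L]]))
    sheets[[q]] <- a
  }
  if (n_legacy > 0L)
    message(sprintf("normalised %d legacy code(s) (7/8/9) to SKIP", n_legacy))
  score_dataset(sheets, schema)
}

#' Write score sheets to CSV
#'
#' Inverse of [read_scoresheets()]: SKIPs become empty cells, unknown
#' labels empty cells; `read_scoresheets(write_scoresheets(ds))`
#' reproduces `ds` exactly (codes, SKIPs, row order). Output is
#' byte-stable for a given dataset.
#'
#' @param ds A `score_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scoresheets <- function(ds, path) {
  stopifnot(inherits(ds, "score_dataset"))
  utils::write.csv(ds$sheets, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write an instrument schema as JSON
#'
#' The schema JSON is a list of `{id, max_severity, allows_skip}` objects.
#'
#' @param path JSON file path.
#' @return [read_schema_json()]: a `question_schema`.
#' @export
read_schema_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  question_schema(x$id, x$max_severity, x$allows_skip)
}

#' @rdname read_schema_json
#' @param schema A `question_schema` to serialise.
#' @export
write_schema_json <- function(schema, path) {
  stopifnot(inherits(schema, "question_schema"))
  jsonlite::write_json(as.data.frame(schema), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Split a dataset into age silos
#'
#' Models are trained separately for children under four years of age and
#' four years and over; the boundary is 48 months and 48 itself goes to
#' the older silo.  The split is a partition: disjoint, exhaustive, and
#' order-preserving within each silo.
#'
#' @param ds A `score_dataset` (typically mixed-silo).
#' @return List with elements `under4` and `over4`, each a `score_dataset`.
#' @export
split_by_age <- function(ds) {
  stopifnot(inherits(ds, "score_dataset"))
  under <- ds$sheets$age_months < SILO_BOUNDARY_MONTHS
  list(under4 = score_dataset(ds$sheets[under, , drop = FALSE], ds$questions,
                              validate = FALSE),
       over4 = score_dataset(ds$sheets[!under, , drop = FALSE], ds$questions,
                             validate = FALSE))
}

#' Subset a dataset by row index
#'
#' @param ds A `score_dataset`.
#' @param i Row index (logical or integer).
#' @return A `score_dataset` with the selected sheets.
#' @export
subset_sheets <- function(ds, i) {
  score_dataset(ds$sheets[i, , drop = FALSE], ds$questions, validate = FALSE)
}

#' Merge two answer sources for the same children
#'
#' Builds the joint feature sheet used when a second respondent (e.g. a
#' clinician) re-answers questions already posed to the first (e.g. a
#' parent): where both answered, the override dataset's answer wins; where
#' the override skipped, the base answer is kept.  This is an
#' interpretation of "the second respondent's answer overrides" — the
#' exact joint construction is not standardised.  Children are matched by
#' `child_id`; the override may cover a subset of children and questions.
#'
#' @param base A `score_dataset` (e.g. parent answers).
#' @param override A `score_dataset` sharing `base`'s schema (possibly a
#'   question subset).
#' @return A `score_dataset` with `base`'s children and metadata.
#' @export
merge_answers <- function(base, override) {
  stopifnot(inherits(base, "score_dataset"), inherits(override, "score_dataset"))
  extra_q <- setdiff(override$questions$id, base$questions$id)
  if (length(extra_q))
    stop("override contains questions outside the base schema: ",
         paste(extra_q, collapse = ", "))
  idx <- match(base$sheets$child_id, override$sheets$child_id)
  sheets <- base$sheets
  for (q in override$questions$id) {
    ov <- override$sheets[[q]][idx]
    sheets[[q]] <- ifelse(!is.na(ov), ov, sheets[[q]])
  }
  score_dataset(sheets, base$questions)
}

# deterministic stage-seed derivation: one user seed, independent streams
# per named stage; result always in [1, 2^31 - 2]
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer(h + 1)
}
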
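#' Configure the synthetic score-sheet generator
#'
#' The generator emulates the statistical structure of clinical
#' questionnaire data with a single-factor graded-response model: child
#' \eqn{i} of class \eqn{c} draws a latent trait \eqn{t_i \sim N(\mu_c,
#' 1)} with \eqn{\mu_{case} - \mu_{control} =} `class_separation`; the
#' answer to question \eqn{q} is the number of that question's cutpoints
#' lying below \eqn{t_i \cdot discrimination_q + \epsilon_{iq}},
#' \eqn{\epsilon \sim N(0,1)}.  Deployment-setting answers offset the
#' latent input by `shift_bias[q]` before the cutpoint mapping and replace
#' answers by SKIP with probability `skip_rate[q]`.
#'
#' Defaults state a realistic world: roughly 2:1 case:control imbalance,
#' ages 18--72 months, ordinal codes 0--3, per-question skip rates
#' averaging 0.15, and a mixture of stable, upward-drifting and
#' downward-drifting questions.
#'
#' @param n_case,n_control Children per class.
#' @param n_questions Number of ordinal questions.
#' @param age_range Integer `(lo, hi)` age range in months, inclusive.
#' @param discrimination Per-question loading on the latent trait (> 0).
#' @param cutpoints `n_questions x 3` matrix of strictly increasing
#'   cutpoints mapping the latent input to codes 0..3.
#' @param class_separation Latent-mean gap between case and control.
#' @param shift_bias Per-question deployment-setting drift (latent units).
#' @param skip_rate Per-question deployment skip probability in `[0, 1]`.
#' @param baseline_screener_noise SD of the additive noise in
#'   [baseline_screener_score()].
#' @param seed Integer master seed; every generator stage derives its own
#'   stream from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_case = 400L, n_control = 200L,
                             n_questions = 20L,
                             age_range = c(18L, 72L),
                             discrimination = NULL,
                             cutpoints = NULL,
                             class_separation = 1.5,
                             shift_bias = NULL,
                             skip_rate = NULL,
                             baseline_screener_noise = 5,
                             seed = 1L) {
  nq <- as.integer(n_questions)
  if (is.null(discrimination))
    discrimination <- seq(0.6, 1.4, length.out = nq)
  if (is.null(cutpoints)) {
    offs <- seq(-0.6, 0.6, length.out = nq)
    cutpoints <- cbind(-0.3 + offs, 0.9 + offs, 2.1 + offs)
  }
  if (is.null(shift_bias))
    shift_bias <- rep_len(c(0, 0, 0.7, -0.35), nq)
  if (is.null(skip_rate))
    skip_rate <- seq(0.05, 0.25, length.out = nq)
  cutpoints <- matrix(cutpoints, nrow = nq)
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_questions = nq, age_range = as.integer(age_range),
              discrimination = rep_len(discrimination, nq),
              cutpoints = cutpoints,
              class_separation = class_separation,
              shift_bias = rep_len(shift_bias, nq),
              skip_rate = rep_len(skip_rate, nq),
              baseline_screener_noise = baseline_screener_noise,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_case < 0L || n_control < 0L || n_questions < 1L)
      stop("counts must be non-negative (n_questions >= 1)")
    if (any(discrimination <= 0)) stop("discrimination must be > 0")
    if (any(apply(cutpoints, 1, function(r) any(diff(r) <= 0))))
      stop("cutpoints must be strictly increasing per question")
    if (any(skip_rate < 0 | skip_rate > 1)) stop("skip_rate must be in [0, 1]")
    if (baseline_screener_noise < 0) stop("baseline_screener_noise must be >= 0")
    if (age_range[1] > age_range[2] || age_range[1] < 0)
      stop("invalid age_range")
  })
  invisible(cfg)
}

#' @rdname generator_config
#' @export
default_schema <- function(n_questions = 20L) {
  question_schema(sprintf("Q%02d", seq_len(n_questions)), max_severity = 3L)
}

# draw latent traits + per-question noise for n children; returns list
draw_latents <- function(cfg, n_case, n_control) {
  n <- n_case + n_control
  label <- c(rep(1L, n_case), rep(0L, n_control))
  t <- stats::rnorm(n, mean = ifelse(label == 1L, cfg$class_separation, 0), sd = 1)
  eps <- matrix(stats::rnorm(n * cfg$n_questions), nrow = n)
  age <- as.integer(floor(stats::runif(n, cfg$age_range[1], cfg$age_range[2] + 1)))
  list(label = label, t = t, eps = eps, age = age)
}

# map latent inputs (n x q) to ordinal codes via per-question cutpoints
codes_from_latent <- function(u, cfg) {
  nq <- cfg$n_questions
  codes <- matrix(0L, nrow = nrow(u), ncol = nq)
  for (j in seq_len(nq))
    codes[, j] <- findInterval(u[, j], cfg$cutpoints[j, ])
  codes
}

assemble_dataset <- function(lat, codes, cfg, cohort, id_prefix) {
  schema <- default_schema(cfg$n_questions)
  n <- length(lat$label)
  sheets <- data.frame(child_id = sprintf("%s%05d", id_prefix, seq_len(n)),
                       age_months = lat$age, label = lat$label,
                       cohort = cohort, stringsAsFactors = FALSE)
  colnames(codes) <- schema$id
  sheets <- cbind(sheets, as.data.frame(codes))
  score_dataset(sheets, schema, validate = FALSE)
}

#' Generate a synthetic training cohort
#'
#' Children answer under clinic conditions: no deployment drift, no skips.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A `score_dataset` with `cohort = "training"`.
#' @export
generate_training <- function(cfg) {
  validate_generator_config(cfg)
  set.seed(derive_seed(cfg$seed, "training"))
  lat <- draw_latents(cfg, cfg$n_case, cfg$n_control)
  u <- lat$t * matrix(cfg$discrimination, nrow = length(lat$t),
                      ncol = cfg$n_questions, byrow = TRUE) + lat$eps
  assemble_dataset(lat, codes_from_latent(u, cfg), cfg, "training", "T")
}

#' Generate a synthetic deployment cohort
#'
#' Fresh children from the same latent model, but each question's latent
#' input is offset by `shift_bias[q]` before the cutpoint mapping (the
#' clinic-to-home severity drift), and each answer is independently
#' replaced by SKIP with probability `skip_rate[q]` (analyst skips).
#'
#' @param cfg A [generator_config()].
#' @param n_case,n_control Optional cohort sizes (default: as in `cfg`).
#' @return A `score_dataset` with `cohort = "deployment"`.
#' @export
generate_deployment <- function(cfg, n_case = cfg$n_case,
                                n_control = cfg$n_control) {
  validate_generator_config(cfg)
  set.seed(derive_seed(cfg$seed, "deployment"))
  lat <- draw_latents(cfg, n_case, n_control)
  n <- length(lat$label)
  u <- lat$t * matrix(cfg$discrimination, nrow = n,
                      ncol = cfg$n_questions, byrow = TRUE) + lat$eps
  u <- u + matrix(cfg$shift_bias, nrow = n, ncol = cfg$n_questions, byrow = TRUE)
  codes <- codes_from_latent(u, cfg)
  skip <- matrix(stats::runif(n * cfg$n_questions), nrow = n) <
    matrix(cfg$skip_rate, nrow = n, ncol = cfg$n_questions, byrow = TRUE)
  codes[skip] <- NA_integer_
  assemble_dataset(lat, codes, cfg, "deployment", "D")
}

#' Generate paired clinic/deployment answer records
#'
#' Each child is observed twice with the same latent trait and the same
#' per-question noise draw: once under the clinic (training) answer model
#' and once under the deployment model (latent drift plus skips).  With
#' `shift_bias = 0` and `skip_rate = 0` the two sheets are identical.
#' These pairs are the input to [estimate_noise_map()].
#'
#' @param cfg A [generator_config()].
#' @param n Number of children (class mix follows `cfg` proportions).
#' @return A `paired_sheets` object: list with aligned `source` and
#'   `deployment` datasets.
#' @export
generate_paired <- function(cfg, n) {
  validate_generator_config(cfg)
  stopifnot(n >= 1)
  set.seed(derive_seed(cfg$seed, "paired"))
  n_case <- round(n * cfg$n_case / max(1L, cfg$n_case + cfg$n_control))
  lat <- draw_latents(cfg, n_case, n - n_case)
  u <- lat$t * matrix(cfg$discrimination, nrow = n,
                      ncol = cfg$n_questions, byrow = TRUE) + lat$eps
  src_codes <- codes_from_latent(u, cfg)
  ud <- u + matrix(cfg$shift_bias, nrow = n, ncol = cfg$n_questions, byrow = TRUE)
  dep_codes <- codes_from_latent(ud, cfg)
  skip <- matrix(stats::runif(n * cfg$n_questions), nrow = n) <
    matrix(cfg$skip_rate, nrow = n, ncol = cfg$n_questions, byrow = TRUE)
  dep_codes[skip] <- NA_integer_
  src <- assemble_dataset(lat, src_codes, cfg, "training", "P")
  dep <- assemble_dataset(lat, dep_codes, cfg, "deployment", "P")
  structure(list(source = src, deployment = dep), class = "paired_sheets")
}

#' Baseline screener: sum of answer codes
#'
#' Conventional screening instruments code each answer, sum the codes and
#' compare the sum against a threshold.  This implements that comparator:
#' the sum of non-SKIP codes plus optional `N(0, sd)` noise emulating
#' instrument/administration variability.
#'
#' @param ds A `score_dataset` (or a single-row one).
#' @param noise_sd Noise standard deviation (default
#'   0: deterministic sum).
#' @param seed Optional seed for the noise draw.
#' @return Numeric vector of scores, one per child.
#' @export
baseline_screener_score <- function(ds, noise_sd = 0, seed = NULL) {
  m <- answers_matrix(ds)
  all_skip <- rowSums(!is.na(m)) == 0L
  if (any(all_skip))
    stop("all-SKIP sheet(s): ", paste(rownames(m)[all_skip], collapse = ", "))
  s <- rowSums(m, na.rm = TRUE)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(derive_seed(seed, "baseline"))
    s <- s + stats::rnorm(length(s), 0, noise_sd)
  }
  unname(s)
}

#' Read / write a generator config as JSON
#' @param path JSON file path.
#' @return [read_generator_config()]: a `generator_config`.
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  generator_config(n_case = x$n_case, n_control = x$n_control,
                   n_questions = x$n_questions, age_range = x$age_range,
                   discrimination = x$discrimination,
                   cutpoints = matrix(unlist(x$cutpoints), nrow = x$n_questions),
                   class_separation = x$class_separation,
                   shift_bias = x$shift_bias, skip_rate = x$skip_rate,
                   baseline_screener_noise = x$baseline_screener_noise,
                   seed = x$seed)
}

#' @rdname read_generator_config
#' @param cfg A `generator_config` to serialise.
#' @export
write_generator_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$cutpoints <- apply(cfg$cutpoints, 1, as.numeric, simplify = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
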
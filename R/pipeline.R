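#' Configure the end-to-end demonstration pipeline
#'
#' One config drives the whole flow: synthetic generation, noise-map
#' estimation and injection, per-silo cascade training for three
#' heterogeneous module analogues (parent-style: clean answers;
#' video-style: trained on noise-injected answers; clinician-style:
#' reduced question set from the perturbation shortlist), combination with
#' leave-one-out covariance, band tuning, and evaluation against the
#' sum-score baseline screener.
#'
#' @param generator A [generator_config()].
#' @param train A [train_config()].
#' @param thresholds List with `target_sensitivity`, `max_inconclusive`.
#' @param n_pairs Paired records for noise-map estimation.
#' @param n_boot Bootstrap resamples in the final screener comparison.
#' @param shortlist_k Questions kept per list in the clinician shortlist.
#' @param seed Master seed.
#' @param output_dir Artifact directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            train = train_config(),
                            thresholds = list(target_sensitivity = 0.9,
                                              max_inconclusive = 0.3),
                            n_pairs = 1000L, n_boot = 1000L,
                            shortlist_k = 7L, seed = 1L,
                            output_dir = tempfile("modscreen_run_")) {
  stopifnot(thresholds$max_inconclusive >= 0, thresholds$max_inconclusive < 1)
  structure(list(generator = generator, train = train,
                 thresholds = thresholds, n_pairs = as.integer(n_pairs),
                 n_boot = as.integer(n_boot),
                 shortlist_k = as.integer(shortlist_k),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline config from JSON
#'
#' Fields mirror [pipeline_config()]; the `generator` and `train` blocks
#' take the same fields as [generator_config()] and [train_config()].
#' Absent fields fall back to the defaults.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  take <- function(block, fn) {
    if (is.null(block)) return(fn())
    do.call(fn, block[intersect(names(block), names(formals(fn)))])
  }
  args <- x[intersect(names(x), c("thresholds", "n_pairs", "n_boot",
                                  "shortlist_k", "seed", "output_dir"))]
  args$generator <- take(x$generator, generator_config)
  args$train <- take(x$train, train_config)
  do.call(pipeline_config, args)
}

pipeline_log <- function(logfile, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  cat(msg, "\n", file = logfile, append = TRUE, sep = "")
}

#' Run the end-to-end demonstration pipeline
#'
#' Executes generate, noise-estimate/inject, feature-select, train (per
#' age silo), combine, band-tune and evaluate; writes every artifact
#' (datasets, noise map, models, response tables, outcome tables, metric
#' reports, screener comparison) under `cfg$output_dir` and returns a
#' manifest of files with MD5 hashes.  Reruns with the same config and
#' seed reproduce identical hashes.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the `manifest` data frame and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$output_dir, "pipeline.log")
  cat("", file = logfile)
  gen <- cfg$generator
  gen$seed <- derive_seed(cfg$seed, "pipeline_gen")
  stage <- function(name, expr) {
    pipeline_log(logfile, "[%s] start (seed stream %d)", name,
                 derive_seed(cfg$seed, name))
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  train_ds <- stage("generate", generate_training(gen))
  deploy_ds <- stage("generate", generate_deployment(gen))
  pairs <- stage("pairs", generate_paired(gen, cfg$n_pairs))
  nmap <- stage("noise", estimate_noise_map(pairs))
  video_train <- stage("inject",
                       inject_noise(train_ds, nmap,
                                    seed = derive_seed(cfg$seed, "inject")))

  write_scoresheets(train_ds, file.path(cfg$output_dir, "training.csv"))
  write_scoresheets(deploy_ds, file.path(cfg$output_dir, "deployment.csv"))
  write_noise_map(nmap, file.path(cfg$output_dir, "noise_map.json"))

  silos_train <- split_by_age(train_ds)
  silos_video <- split_by_age(video_train)
  silos_deploy <- split_by_age(deploy_ds)

  tr_cfg <- cfg$train
  all_out <- list()
  resp_tabs <- list()
  for (silo in c("under4", "over4")) {
    st <- silos_train[[silo]]; sv <- silos_video[[silo]]
    sd_ <- silos_deploy[[silo]]
    if (nrow(st$sheets) < 40L || nrow(sd_$sheets) < 20L) {
      pipeline_log(logfile, "[train] silo %s too small, skipped", silo)
      next
    }
    tr_cfg$seed <- derive_seed(cfg$seed, paste0("train_", silo))
    parent_mod <- stage("train", train_cascade(st, tr_cfg))
    video_mod <- stage("train", train_cascade(sv, tr_cfg))
    # clinician-style module: reduced question set via importance +
    # perturbation shortlist
    imp <- names(gbt_importance(parent_mod$binary_model))
    pa <- perturb_rank(parent_mod, st, parent_mod$decision_threshold,
                       band = c(0, 0.1))
    pb <- perturb_rank(parent_mod, st, parent_mod$decision_threshold,
                       band = c(0.1, 0.3))
    short <- shortlist_clinician(imp, pa, pb, top_k = cfg$shortlist_k)
    pipeline_log(logfile, "[featsel] silo %s clinician shortlist: %s",
                 silo, paste(short, collapse = ","))
    clin_mod <- stage("train", train_cascade(st, tr_cfg, feature_ids = short))

    modules <- list(parent = parent_mod, video = video_mod,
                    clinician = clin_mod)
    responses <- vapply(modules, function(m) module_score(m, sd_),
                        numeric(nrow(sd_$sheets)))
    rownames(responses) <- sd_$sheets$child_id
    labels <- sd_$sheets$label
    write_responses(responses, labels,
                    file.path(cfg$output_dir,
                              sprintf("responses_%s.csv", silo)))

    comb <- stage("combine", fit_combination(responses, labels))
    comb <- stage("combine",
                  tune_band(comb, comb$loo_responses, labels,
                            cfg$thresholds$target_sensitivity,
                            cfg$thresholds$max_inconclusive))
    write_combination_model(comb, file.path(cfg$output_dir,
                                            sprintf("combination_%s.json",
                                                    silo)))
    verdicts <- banded_outcome(comb, comb$loo_responses)
    outc <- as_outcomes(sd_$sheets$child_id, verdicts,
                        ifelse(verdicts == "inconclusive", NA_real_,
                               comb$loo_responses))
    utils::write.csv(outc, file.path(cfg$output_dir,
                                     sprintf("outcomes_%s.csv", silo)),
                     row.names = FALSE, quote = FALSE)

    metrics <- conclusive_metrics(outc, labels)
    baseline <- baseline_screener_score(sd_, gen$baseline_screener_noise,
                                        seed = derive_seed(cfg$seed, "base"))
    delta <- stage("evaluate",
                   bootstrap_delta(baseline, comb$loo_responses, labels,
                                   n_boot = cfg$n_boot,
                                   seed = derive_seed(cfg$seed, silo)))
    report <- list(silo = silo,
                   coverage = metrics$coverage,
                   conclusive_auc = metrics$auc,
                   sensitivity = metrics$sensitivity,
                   specificity = metrics$specificity,
                   combined_loo_auc = auc_value(comb$loo_responses, labels),
                   module_auc = as.list(apply(responses, 2, auc_value,
                                              labels = labels)),
                   baseline_auc = auc_value(baseline, labels),
                   delta_vs_baseline = list(
                     delta_auc_mean = delta$delta_auc_mean,
                     delta_auc_ci = delta$delta_auc_ci,
                     delta_spec_mean = delta$delta_spec_mean,
                     delta_spec_ci = delta$delta_spec_ci))
    jsonlite::write_json(report,
                         file.path(cfg$output_dir,
                                   sprintf("report_%s.json", silo)),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    pipeline_log(logfile,
                 "[evaluate] silo %s: coverage %.3f, conclusive AUC %.3f, dAUC vs baseline %.3f",
                 silo, metrics$coverage, metrics$auc, delta$delta_auc_mean)
    all_out[[silo]] <- report
    resp_tabs[[silo]] <- responses
  }

  files <- sort(setdiff(list.files(cfg$output_dir, full.names = TRUE),
                        file.path(cfg$output_dir, c("pipeline.log",
                                                    "manifest.csv"))))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(cfg$output_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, reports = all_out,
                 responses = resp_tabs, output_dir = cfg$output_dir))
}
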
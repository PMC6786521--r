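# End-to-end orchestration: simulate a cohort, apply exclusions, fit and
# compare the learning models, run the trajectory-level analyses and the
# gaze regressions, compare the attention-coupled variants, and write a
# report with a run manifest.

#' Default pipeline configuration
#'
#' Sizes here are deliberately modest so a full run completes in minutes;
#' scale `n_subjects`, the sampler settings and `models` up for
#' production-quality inference.
#'
#' @param n_subjects cohort size.
#' @param model_id generating model for the synthetic cohort.
#' @param models learning models entered into the WAIC comparison.
#' @param sampler sampler settings for every fit.
#' @param n_perm permutations for the interference test.
#' @param seed master seed.
#' @return configuration list.
#' @export
pipeline_config <- function(n_subjects = 12, model_id = "6",
                            models = c("1", "2", "5", "6"),
                            sampler = sampler_config(n_chains = 1,
                                                     n_warmup = 300,
                                                     n_iter = 400),
                            n_perm = 1000, seed = 1) {
  list(n_subjects = n_subjects, model_id = model_id, models = models,
       sampler = sampler, n_perm = n_perm, seed = seed)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised fields mirror the arguments of [pipeline_config()]; sampler
#' settings go under a `sampler:` block. Unspecified fields keep their
#' defaults.
#'
#' @param path YAML file.
#' @return configuration list as from [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  smp <- do.call(sampler_config, raw$sampler %||% list())
  args <- raw[intersect(names(raw), c("n_subjects", "model_id", "models",
                                      "n_perm", "seed"))]
  args$models <- as.character(args$models)
  do.call(pipeline_config, c(args, list(sampler = smp)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: cohort simulation; exclusion rules (gambler's-fallacy fit,
#' limited responses, off-stimulus gaze) with every decision logged;
#' learning-model WAIC comparison; value-variance independence;
#' parameter-influence regression; pre-outcome and outcome fixation-bias
#' beta regressions with the uncertainty-free WAIC comparison; the
#' estimation-error regression; and the model 6 / 6A / 6B attention
#' comparison. Results and a manifest (seed, configuration hash,
#' exclusion counts, artifact paths) are written under `out_dir`.
#'
#' @param config from [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list with all stage results and the manifest (invisibly writes
#'   CSV/JSON/markdown artifacts).
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir = tempfile("lbrun")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  res <- list(config = config)

  cohort <- generate_cohort(config$n_subjects, config$model_id, seed = seed)
  res$cohort <- cohort

  gf <- detect_gamblers_fallacy(cohort$trials, seed = .child_seed(seed, 11))
  lim <- detect_limited_responses(cohort$trials)
  gz <- apply_gaze_exclusion(cohort$fixations)
  excl <- data.frame(subject = gf$subject,
                     gambler = gf$gambler, limited = lim$limited,
                     off_gaze = gz$excluded)
  excl$excluded <- excl$gambler | excl$limited | excl$off_gaze
  res$exclusions <- excl
  keep <- excl$subject[!excl$excluded]
  trials <- cohort$trials[cohort$trials$subject %in% keep, ]
  fixations <- cohort$fixations[cohort$fixations$subject %in% keep, ]

  fits <- lapply(config$models, function(m)
    fit_model(trials, m, sampler = config$sampler,
              seed = .child_seed(seed, 20 + as.integer(.model_code(m)))))
  names(fits) <- config$models
  res$model_comparison <- compare_models(fits)
  best_id <- res$model_comparison$model[1]
  best <- fits[[best_id]]
  res$best_model <- best_id

  est <- summary(best)$subject
  par_list <- lapply(seq_len(nrow(est)), function(s) {
    p <- agent_params(model_id = best_id)
    for (nm in intersect(names(est), .PAR_NAMES)) p[[nm]] <- est[[nm]][s]
    p
  })
  traj <- run_trajectory(trials, par_list)
  res$value_variance <- value_variance_independence(traj)
  if (all(c("tau_pos", "tau_neg", "lam") %in% names(est))) {
    mr <- aggregate(trials$rating, by = list(subject = trials$subject),
                    FUN = mean)
    res$parameter_influence <-
      fit_parameter_influence_regression(est, mr$x,
                                         seed = .child_seed(seed, 31))$coef
  }

  rows_pre <- build_predictors(trials, traj, fixations, "pre_outcome")
  rows_out <- build_predictors(trials, traj, fixations, "outcome")
  fit_pre <- fit_fixation_beta_regression(rows_pre, "pre_outcome",
                                          sampler = config$sampler,
                                          seed = .child_seed(seed, 41))
  fit_nou <- fit_fixation_beta_regression(rows_pre, "no_uncertainty",
                                          sampler = config$sampler,
                                          seed = .child_seed(seed, 42))
  fit_out <- fit_fixation_beta_regression(rows_out, "outcome",
                                          sampler = config$sampler,
                                          seed = .child_seed(seed, 43))
  res$gaze_pre <- summary(fit_pre)
  res$gaze_outcome <- summary(fit_out)
  res$uncertainty_comparison <- compare_regression_waic(fit_pre, fit_nou)

  fit_err <- fit_estimation_error_regression(trials, fixations,
                                             sampler = config$sampler,
                                             seed = .child_seed(seed, 44))
  res$estimation_error <- summary(fit_err)

  res$interference <- interference_statistic(trials, n_perm = config$n_perm,
                                             omega = if ("omega" %in% names(est))
                                               est$omega else NULL,
                                             seed = .child_seed(seed, 45))

  attn <- lapply(c("6", "6A", "6B"), function(m)
    fit_model(trials, m, fixations = fixations, sampler = config$sampler,
              seed = .child_seed(seed, 50 + .model_code(m))))
  names(attn) <- c("6", "6A", "6B")
  res$attention_comparison <- compare_models(attn)
  if ("theta" %in% names(summary(attn[["6B"]])$subject))
    res$theta_estimates <- summary(attn[["6B"]])$subject$theta

  # artifacts + manifest
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    model_comparison = file.path(out_dir, "model_comparison.csv"),
    gaze_pre = file.path(out_dir, "gaze_pre_outcome.csv"),
    gaze_outcome = file.path(out_dir, "gaze_outcome.csv"),
    estimation_error = file.path(out_dir, "estimation_error.csv"),
    attention = file.path(out_dir, "attention_comparison.csv"),
    report = file.path(out_dir, "report.md"),
    manifest = file.path(out_dir, "manifest.json"))
  write.csv(trials, paths$trials, row.names = FALSE)
  write.csv(res$model_comparison, paths$model_comparison, row.names = FALSE)
  write.csv(res$gaze_pre, paths$gaze_pre, row.names = FALSE)
  write.csv(res$gaze_outcome, paths$gaze_outcome, row.names = FALSE)
  write.csv(res$estimation_error, paths$estimation_error, row.names = FALSE)
  write.csv(res$attention_comparison, paths$attention, row.names = FALSE)
  writeLines(.pipeline_report(res), paths$report)
  manifest <- list(
    seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(config[c("n_subjects",
                                                       "model_id", "models",
                                                       "n_perm")]),
                                      collapse = ""))),
    n_subjects = config$n_subjects,
    exclusion_counts = list(gambler = sum(excl$gambler, na.rm = TRUE),
                            limited = sum(excl$limited),
                            off_gaze = sum(excl$off_gaze)),
    excluded_subjects = excl$subject[excl$excluded],
    best_model = best_id,
    artifacts = paths)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

.pipeline_report <- function(res) {
  fm <- function(x, d = 3) formatC(x, digits = d, format = "f")
  c("# Synthetic-cohort analysis report",
    "",
    sprintf("Cohort: %d subjects generated from model %s (seed %d).",
            res$config$n_subjects, res$config$model_id, res$config$seed),
    sprintf("Exclusions: %d gambler's-fallacy, %d limited-response, %d off-stimulus gaze.",
            sum(res$exclusions$gambler, na.rm = TRUE),
            sum(res$exclusions$limited), sum(res$exclusions$off_gaze)),
    "",
    "## Learning-model comparison (WAIC, lower is better)",
    utils::capture.output(print(res$model_comparison, row.names = FALSE)),
    "",
    sprintf("Value-variance mean correlation: %s (SD %s).",
            fm(res$value_variance$mean_r), fm(res$value_variance$sd_r)),
    "",
    "## Pre-outcome fixation-bias regression",
    utils::capture.output(print(res$gaze_pre, row.names = FALSE)),
    sprintf("Uncertainty-free comparison: %s model preferred (dWAIC %s).",
            res$uncertainty_comparison$preferred,
            fm(res$uncertainty_comparison$diff, 1)),
    "",
    "## Outcome-phase fixation-bias regression",
    utils::capture.output(print(res$gaze_outcome, row.names = FALSE)),
    "",
    "## Estimation-error regression",
    utils::capture.output(print(res$estimation_error, row.names = FALSE)),
    "",
    "## Attention-coupled model comparison",
    utils::capture.output(print(res$attention_comparison, row.names = FALSE)))
}
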
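#' Run a configured pipeline stage
#'
#' Reproducible entry point tying the stages together. A run is described by
#' a plain-text (YAML) config or an equivalent named list with a `command`
#' and its inputs; results are written to an output directory together with
#' a `manifest.json` recording the config, seeds, package version, per-stage
#' row counts and output file hashes. Existing outputs are never overwritten
#' unless `force` is set.
#'
#' Commands:
#' \describe{
#'   \item{`simulate`}{generate a cohort (`design`, `n_subjects`, optional
#'     `model_mix`, `total_trials`, agent parameter overrides under
#'     `params`); writes `trial_log.csv`, `ground_truth.csv`,
#'     `true_params.csv`.}
#'   \item{`analyze`}{preprocess a trial log (`log` path) and run the
#'     analysis chain for its design: exclusion report, decision-confidence
#'     or exploration regression, belief-confidence regression,
#'     estimation-error halves, confidence-quintile ANOVAs, per-subject
#'     metacognition; writes tidy CSVs.}
#'   \item{`fit`}{fit agent models (`models`) to a trial log by maximum
#'     likelihood; writes `fit_table.csv` and `bic_summary.csv`.}
#'   \item{`recover`}{simulate small cohorts from each model and refit all
#'     models (model-identification confusion matrix); writes
#'     `confusion.csv`.}
#' }
#'
#' @param config Path to a YAML file or a named list. Fields used by every
#'   command: `command`, `out` (output directory), `seed` (mandatory for
#'   `simulate`/`recover`), `force`.
#' @param ... Fields overriding those in `config` (e.g. `out`, `seed`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, ...) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  over <- list(...)
  config[names(over)] <- over
  cmd <- config$command
  if (is.null(cmd) || !cmd %in% c("simulate", "analyze", "fit", "recover"))
    stop("run_pipeline: 'command' must be one of simulate/analyze/fit/recover")
  out_dir <- config$out
  if (is.null(out_dir)) stop("run_pipeline: missing 'out' directory")
  force <- isTRUE(config$force)
  if (cmd %in% c("simulate", "recover") && is.null(config$seed))
    stop("run_pipeline: 'seed' is mandatory for command '", cmd, "'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(command = cmd, config = config,
                   package_version = as.character(utils::packageVersion("banditmeta")),
                   counts = list())
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    if (file.exists(path) && !force)
      stop("run_pipeline: '", path, "' exists; set force: true to overwrite")
    utils::write.csv(df, path, row.names = FALSE, na = "")
    manifest$counts[[name]] <<- nrow(df)
    written <<- c(written, path)
    path
  }
  if (cmd == "simulate") {
    base <- do.call(agent_params, c(list(), config$params))
    spec <- cohort_spec(n_subjects = config$n_subjects %||% 20L,
                        design = config$design %||% "exp1",
                        model_mix = unlist(config$model_mix %||% c(rl = 1)),
                        base_params = base,
                        total_trials = config$total_trials %||% 600L,
                        master_seed = as.integer(config$seed))
    coh <- generate_cohort(spec)
    path <- file.path(out_dir, "trial_log.csv")
    if (file.exists(path) && !force)
      stop("run_pipeline: '", path, "' exists; set force: true to overwrite")
    write_trial_log(coh$log, path)
    manifest$counts[["trial_log.csv"]] <- nrow(coh$log)
    written <- c(written, path)
    emit(coh$truth, "ground_truth.csv")
    emit(coh$params, "true_params.csv")
  } else if (cmd == "analyze") {
    log <- read_trial_log(config$log, col_map = config$col_map)
    design <- config$design %||%
      (if (any(!is.na(log$value_rating_other))) "exp2" else "exp1")
    pp <- preprocess_choices(log)
    emit(pp$exclusions, "exclusion_report.csv")
    results <- list()
    tidy <- function(res, model) {
      co <- res$coefficients
      co$model <- model
      co$bic <- res$bic
      co$structure <- res$structure
      co[, c("model", "term", "beta", "se", "stat", "p", "bic", "structure")]
    }
    if (design == "exp1") {
      dc <- decision_confidence_model(pp$view)
      results[[length(results) + 1L]] <- tidy(dc, "decision_confidence")
      halves <- halves_estimation_error(pp$log)
      emit(data.frame(stat = "halves_t", value = halves$statistic,
                      first = halves$means["first"], second = halves$means["second"],
                      p = halves$p_value), "estimation_error_halves.csv")
      corr <- update_vs_confidence_correlation(pp$log)
      emit(corr, "update_confidence_correlations.csv")
    } else {
      ex <- exploration_model(pp$view)
      results[[length(results) + 1L]] <- tidy(ex, "exploration")
      v <- pp$view
      v$conf_bin <- bin_quantiles(v$decision_conf, v$subject, k = 5L)
      v$error <- 1 - v$accuracy
      an_err <- quintile_trend_anova(v, "error", "conf_bin")
      an_rew <- quintile_trend_anova(v, "outcome", "conf_bin")
      emit(data.frame(outcome = c("error_rate", "reward"),
                      F = c(an_err$statistic, an_rew$statistic),
                      df1_gg = c(an_err$df[1L], an_rew$df[1L]),
                      df2_gg = c(an_err$df[2L], an_rew$df[2L]),
                      p_gg = c(an_err$p_value, an_rew$p_value),
                      eta2p = c(an_err$effect_size, an_rew$effect_size),
                      F_linear = c(an_err$linear$statistic, an_rew$linear$statistic),
                      p_linear = c(an_err$linear$p_value, an_rew$linear$p_value)),
           "confidence_quintile_anova.csv")
      meta <- subject_metacognition(pp$view)
      emit(meta, "metacognition.csv")
    }
    bc <- belief_confidence_model(pp$log)
    results[[length(results) + 1L]] <- tidy(bc, "belief_confidence")
    emit(do.call(rbind, results), "regressions.csv")
  } else if (cmd == "fit") {
    log <- read_trial_log(config$log, col_map = config$col_map)
    cmp <- compare_agents(log,
                          model_tags = config$models %||% c("ideal", "rl", "particle"),
                          n_restarts = config$n_restarts %||% 10L,
                          seed = as.integer(config$seed %||% 1L))
    emit(cmp$table, "fit_table.csv")
    emit(data.frame(model = names(cmp$summed_bic), summed_bic = cmp$summed_bic),
         "bic_summary.csv")
  } else if (cmd == "recover") {
    models <- config$models %||% c("ideal", "rl", "particle")
    n_subj <- config$n_subjects %||% 4L
    seed <- as.integer(config$seed)
    rows <- list()
    for (gen in models) {
      spec <- cohort_spec(n_subjects = n_subj, design = config$design %||% "exp1",
                          model_mix = stats::setNames(1, gen),
                          total_trials = config$total_trials %||% 600L,
                          master_seed = seed + match(gen, models))
      coh <- generate_cohort(spec)
      cmp <- compare_agents(coh$log, model_tags = models,
                            n_restarts = config$n_restarts %||% 10L, seed = seed)
      rows[[gen]] <- data.frame(generating = gen,
                                winner = cmp$ranking[1L],
                                t(cmp$summed_bic[models]))
    }
    emit(do.call(rbind, rows), "confusion.csv")
  }
  manifest$hashes <- as.list(tools::md5sum(written))
  names(manifest$hashes) <- basename(written)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
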
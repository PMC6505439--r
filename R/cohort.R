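#' Cohort specification
#'
#' Describes a simulated cohort: the design, the number of subjects, the mix
#' of agent models, and subject-level heterogeneity in the agent parameters.
#' Heterogeneity is Gaussian on a transformed scale — log for strictly
#' positive parameters, logit for the learning rate, identity for the
#' uncertainty bonus (which may legitimately be zero or negative) — and
#' clipped at the hard parameter bounds.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param design `"exp1"` (75% rating trials) or `"exp2"` (25% rating trials).
#' @param model_mix Named proportions over `c("ideal", "rl", "particle")`;
#'   must sum to 1. Subjects are assigned models by rounded proportions.
#' @param base_params An `agent_params` giving the cohort-mean parameters.
#' @param heterogeneity Named numeric vector of SDs on the transformed scales
#'   for any of `learning_rate` (logit), `confidence_gain`, `inverse_temperature`,
#'   `rating_noise_sd`, `confidence_noise_sd`, `obs_concentration` (log), and
#'   `uncertainty_bonus` (identity). Use 0 for a homogeneous parameter.
#' @param total_trials Trials per subject (default 600).
#' @param master_seed Integer master seed; schedule and per-subject seeds are
#'   derived from it deterministically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, design = c("exp1", "exp2"),
                        model_mix = c(rl = 1),
                        base_params = agent_params(),
                        heterogeneity = c(learning_rate = 0.3,
                                          confidence_gain = 0.15,
                                          inverse_temperature = 0.2,
                                          rating_noise_sd = 0.15,
                                          confidence_noise_sd = 0.15,
                                          uncertainty_bonus = 0.1),
                        total_trials = 600L, master_seed = 1L) {
  design <- match.arg(design)
  if (n_subjects < 1L) stop("cohort_spec: 'n_subjects' must be at least 1")
  if (any(heterogeneity < 0)) stop("cohort_spec: heterogeneity SDs must be non-negative")
  if (!all(names(model_mix) %in% c("ideal", "rl", "particle")))
    stop("cohort_spec: model_mix names must be among ideal/rl/particle")
  if (abs(sum(model_mix) - 1) > 1e-8)
    stop("cohort_spec: model_mix proportions must sum to 1")
  structure(list(n_subjects = as.integer(n_subjects), design = design,
                 model_mix = model_mix, base_params = base_params,
                 heterogeneity = heterogeneity,
                 total_trials = as.integer(total_trials),
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Draw one subject's parameters around the cohort means.
draw_subject_params <- function(base, het, model_tag) {
  gauss <- function(mu, sd) stats::rnorm(1L, mu, sd)
  g <- function(name) if (name %in% names(het)) het[[name]] else 0
  lr <- stats::plogis(gauss(stats::qlogis(base$learning_rate), g("learning_rate")))
  lr <- min(max(lr, 0.01), 1)
  pos <- function(x, name, lo, hi) min(max(exp(gauss(log(x), g(name))), lo), hi)
  agent_params(
    model_tag = model_tag,
    learning_rate = lr,
    confidence_gain = pos(base$confidence_gain, "confidence_gain", 0.1, 5),
    uncertainty_bonus = gauss(base$uncertainty_bonus, g("uncertainty_bonus")),
    inverse_temperature = pos(base$inverse_temperature, "inverse_temperature", 0.1, 40),
    rating_noise_sd = pos(base$rating_noise_sd, "rating_noise_sd", 0.5, 40),
    confidence_noise_sd = pos(base$confidence_noise_sd, "confidence_noise_sd", 0.005, 0.5),
    n_particles = base$n_particles,
    obs_concentration = pos(base$obs_concentration, "obs_concentration", 1, 40),
    dc_weights = base$dc_weights)
}

#' Generate a simulated cohort
#'
#' Builds one shared experiment schedule (all subjects face the same blocks
#' and pre-generated gambles), draws heterogeneous subject-level parameters,
#' and simulates every subject. Fully deterministic given the master seed.
#'
#' @param spec A `cohort_spec`.
#' @return A list with `log` (combined trial log, all subjects), `truth`
#'   (combined per-trial latent states), `params` (one row per subject:
#'   the true generating parameters), and `schedule`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$master_seed)
  schedule_seed <- sample.int(.Machine$integer.max, 1L)
  subject_seeds <- sample.int(.Machine$integer.max, spec$n_subjects)
  n <- spec$n_subjects
  counts <- round(spec$model_mix * n)
  while (sum(counts) != n) {  # fix rounding drift on the largest share
    i <- which.max(spec$model_mix)
    counts[i] <- counts[i] + sign(n - sum(counts))
  }
  tags <- rep(names(counts), counts)
  config <- experiment_config(spec$design, spec$total_trials, seed = schedule_seed)
  schedule <- build_experiment(config)
  subj_params <- vector("list", n)
  set.seed(spec$master_seed + 1L)
  for (s in seq_len(n))
    subj_params[[s]] <- draw_subject_params(spec$base_params, spec$heterogeneity, tags[s])
  logs <- vector("list", n)
  truths <- vector("list", n)
  ids <- sprintf("s%02d", seq_len(n))
  for (s in seq_len(n)) {
    sim <- simulate_subject(schedule, subj_params[[s]], subject_id = ids[s],
                            seed = subject_seeds[s])
    logs[[s]] <- sim$log
    truths[[s]] <- sim$truth
  }
  params_tab <- do.call(rbind, lapply(seq_len(n), function(s) {
    p <- subj_params[[s]]
    data.frame(subject = ids[s], model_tag = p$model_tag,
               learning_rate = p$learning_rate,
               confidence_gain = p$confidence_gain,
               uncertainty_bonus = p$uncertainty_bonus,
               inverse_temperature = p$inverse_temperature,
               rating_noise_sd = p$rating_noise_sd,
               confidence_noise_sd = p$confidence_noise_sd,
               n_particles = p$n_particles,
               obs_concentration = p$obs_concentration,
               seed = subject_seeds[s])
  }))
  list(log = do.call(rbind, logs), truth = do.call(rbind, truths),
       params = params_tab, schedule = schedule)
}
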
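# Dispersion of a flat prior over the 0-100 point scale; used as the initial
# belief dispersion of every agent before any outcome is observed.
PRIOR_SD <- 100 / sqrt(12)

#' Agent parameters
#'
#' Free parameters of the simulated participants. All agents share the choice
#' policy (softmax on the value difference plus an uncertainty bonus on the
#' preferred arm's belief uncertainty) and the report model (Gaussian noise on
#' value and confidence readouts); they differ in how beliefs are updated:
#' \describe{
#'   \item{`ideal`}{running mean and running sample SD of observed outcomes;
#'     reported belief confidence tracks the standard error of the mean.}
#'   \item{`rl`}{delta-rule value update with learning rate `learning_rate`;
#'     the belief dispersion is a recency-weighted average of absolute
#'     prediction errors, so large surprises lower reported confidence.}
#'   \item{`particle`}{sequential Monte-Carlo posterior over candidate arm
#'     means with a beta observation model (`obs_concentration` controls the
#'     assumed outcome noise) and systematic resampling.}
#' }
#'
#' @param model_tag `"ideal"`, `"rl"`, or `"particle"`.
#' @param learning_rate Delta-rule learning rate in (0, 1] (RL model only).
#' @param confidence_gain Positive slope mapping belief dispersion (points) to
#'   the reported confidence scale.
#' @param uncertainty_bonus Weight (phi) of the preferred arm's belief
#'   uncertainty in the choice policy; positive values push toward exploring
#'   the lower-valued arm when confidence in the better arm is low.
#' @param inverse_temperature Non-negative softmax sensitivity to the value
#'   difference (per 100 points).
#' @param rating_noise_sd SD (points) of Gaussian report noise on value ratings.
#' @param confidence_noise_sd SD (confidence units) of report noise on both
#'   confidence scales.
#' @param n_particles Particle count (particle model only).
#' @param obs_concentration Concentration of the particle filter's beta
#'   observation model (alpha + beta); larger values assume less outcome noise.
#' @param dc_weights Length-3 numeric: weights of the value difference, the
#'   chosen arm's belief confidence and the unchosen arm's belief confidence
#'   in the decision-confidence readout.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(model_tag = c("rl", "ideal", "particle"),
                         learning_rate = 0.3,
                         confidence_gain = 2.5,
                         uncertainty_bonus = 0.5,
                         inverse_temperature = 14,
                         rating_noise_sd = 3,
                         confidence_noise_sd = 0.05,
                         n_particles = 50L,
                         obs_concentration = 12,
                         dc_weights = c(value = 0.6, conf_chosen = 0.25,
                                        conf_unchosen = 0.15)) {
  model_tag <- match.arg(model_tag)
  if (!is.finite(learning_rate) || learning_rate <= 0 || learning_rate > 1)
    stop("agent_params: 'learning_rate' must lie in (0, 1]")
  if (!is.finite(confidence_gain) || confidence_gain <= 0)
    stop("agent_params: 'confidence_gain' must be positive")
  if (!is.finite(inverse_temperature) || inverse_temperature < 0)
    stop("agent_params: 'inverse_temperature' must be non-negative")
  if (!is.finite(rating_noise_sd) || rating_noise_sd < 0)
    stop("agent_params: 'rating_noise_sd' must be non-negative")
  if (!is.finite(confidence_noise_sd) || confidence_noise_sd < 0)
    stop("agent_params: 'confidence_noise_sd' must be non-negative")
  if (n_particles < 2L) stop("agent_params: 'n_particles' must be at least 2")
  if (!is.finite(obs_concentration) || obs_concentration <= 0)
    stop("agent_params: 'obs_concentration' must be positive")
  structure(list(model_tag = model_tag, learning_rate = learning_rate,
                 confidence_gain = confidence_gain,
                 uncertainty_bonus = uncertainty_bonus,
                 inverse_temperature = inverse_temperature,
                 rating_noise_sd = rating_noise_sd,
                 confidence_noise_sd = confidence_noise_sd,
                 n_particles = as.integer(n_particles),
                 obs_concentration = obs_concentration,
                 dc_weights = dc_weights),
            class = "agent_params")
}

#' Initialize a belief state
#'
#' Per-arm value estimate, dispersion estimate, and evidence count; the
#' particle model additionally holds a per-arm particle set (candidate means
#' on a fixed uniform grid over (0, 100) with uniform weights).
#'
#' @param params An `agent_params`.
#' @return An object of class `belief_state`.
#' @export
belief_state <- function(params) {
  st <- list(model_tag = params$model_tag,
             est_value = c(50, 50), est_sd = c(PRIOR_SD, PRIOR_SD),
             n_obs = c(0L, 0L))
  if (params$model_tag == "particle") {
    n <- params$n_particles
    grid <- 100 * (seq_len(n) - 0.5) / n
    st$particles <- cbind(grid, grid)
    st$log_w <- matrix(-log(n), n, 2L)
    sd0 <- sqrt(mean(grid^2) - mean(grid)^2)
    st$est_sd <- c(sd0, sd0)
  }
  structure(st, class = "belief_state")
}

#' Ideal-observer belief update
#'
#' Running mean and running sample standard deviation of all outcomes
#' observed from one arm (Welford recursion). With fewer than two
#' observations the dispersion keeps its prior value.
#'
#' @param state A `belief_state`.
#' @param arm Arm index, 0 or 1.
#' @param outcome Observed reward in `[0, 100]`.
#' @return The updated `belief_state`.
#' @export
update_ideal <- function(state, arm, outcome) {
  stopifnot(outcome >= 0, outcome <= 100)
  a <- arm + 1L
  n <- state$n_obs[a] + 1L
  if (n == 1L) {
    state$est_value[a] <- outcome
    state$m2 <- state$m2 %||% c(0, 0)
    state$m2[a] <- 0
  } else {
    delta <- outcome - state$est_value[a]
    state$est_value[a] <- state$est_value[a] + delta / n
    state$m2[a] <- state$m2[a] + delta * (outcome - state$est_value[a])
    state$est_sd[a] <- sqrt(state$m2[a] / (n - 1L))
  }
  state$n_obs[a] <- n
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Delta-rule belief update
#'
#' Value moves toward the outcome by `learning_rate` times the prediction
#' error; the dispersion estimate is a recency-weighted average of absolute
#' prediction errors, so surprising outcomes raise it (and lower reported
#' confidence) while confirmations shrink it toward zero.
#'
#' @inheritParams update_ideal
#' @param params An `agent_params` (uses `learning_rate`).
#' @return The updated `belief_state`.
#' @export
update_rl <- function(state, arm, outcome, params) {
  stopifnot(outcome >= 0, outcome <= 100)
  lr <- params$learning_rate
  if (lr <= 0 || lr > 1) stop("update_rl: 'learning_rate' must lie in (0, 1]")
  a <- arm + 1L
  pe <- outcome - state$est_value[a]
  state$est_sd[a] <- (1 - lr) * state$est_sd[a] + lr * abs(pe)
  state$est_value[a] <- state$est_value[a] + lr * pe
  state$n_obs[a] <- state$n_obs[a] + 1L
  state
}

# Beta log-density of outcome x (points) for a candidate mean m (points),
# at fixed concentration nu (alpha + beta). Outcomes are clamped off the
# boundary. At low concentration the likelihood's argmax over m sits a
# point or two off x (beta asymmetry); the default concentration keeps
# this below the particle grid resolution scale.
beta_obs_loglik <- function(x, m, nu) {
  p <- pmin(pmax(x / 100, 0.005), 0.995)
  mu <- pmin(pmax(m / 100, 1e-4), 1 - 1e-4)
  a <- nu * mu
  b <- nu * (1 - mu)
  # explicit log-density (same arithmetic as the compiled filter)
  (lgamma(a + b) - lgamma(a) - lgamma(b)) + (a - 1) * log(p) + (b - 1) * log1p(-p)
}

#' Particle-filter belief update
#'
#' Reweights candidate arm means by the beta observation likelihood of the
#' outcome, renormalizes, and applies systematic resampling (deterministic
#' offset, so the filter is reproducible) when the effective sample size
#' falls below half the particle count. Value and dispersion estimates are
#' the weighted particle mean and SD.
#'
#' @inheritParams update_rl
#' @return The updated `belief_state`.
#' @export
update_particle <- function(state, arm, outcome, params) {
  stopifnot(outcome >= 0, outcome <= 100)
  a <- arm + 1L
  m <- state$particles[, a]
  lw <- state$log_w[, a] + beta_obs_loglik(outcome, m, params$obs_concentration)
  mx <- max(lw)
  if (!is.finite(mx)) {  # numerical underflow: recover by re-initialization
    warning("update_particle: particle weights underflowed; re-initializing")
    n <- length(m)
    state$particles[, a] <- 100 * (seq_len(n) - 0.5) / n
    state$log_w[, a] <- -log(n)
    m <- state$particles[, a]
    lw <- state$log_w[, a]
    mx <- max(lw)
  }
  lw <- lw - (mx + log(sum(exp(lw - mx))))
  w <- exp(lw)
  ess <- 1 / sum(w^2)
  n <- length(w)
  if (ess < n / 2) {
    u <- (seq_len(n) - 0.5) / n  # systematic, deterministic offset
    idx <- findInterval(u, cumsum(w)) + 1L
    idx[idx > n] <- n
    m <- m[idx]
    state$particles[, a] <- m
    lw <- rep(-log(n), n)
    w <- rep(1 / n, n)
  }
  state$log_w[, a] <- lw
  ev <- sum(w * m)
  state$est_value[a] <- ev
  state$est_sd[a] <- sqrt(max(sum(w * m^2) - ev^2, 0))
  state$n_obs[a] <- state$n_obs[a] + 1L
  state
}

# One belief update dispatched on the state's model tag.
update_belief <- function(state, arm, outcome, params) {
  switch(state$model_tag,
         ideal = update_ideal(state, arm, outcome),
         rl = update_rl(state, arm, outcome, params),
         particle = update_particle(state, arm, outcome, params))
}

# Latent (noiseless) belief confidence of one arm. The ideal observer reports
# uncertainty about the mean (standard error), which shrinks with evidence;
# the RL and particle models report their dispersion estimate directly.
latent_confidence <- function(state, arm, params) {
  a <- arm + 1L
  disp <- if (state$model_tag == "ideal") {
    n <- state$n_obs[a]
    if (n < 2L) PRIOR_SD / sqrt(max(n, 1L)) else state$est_sd[a] / sqrt(n)
  } else state$est_sd[a]
  min(max(1 - params$confidence_gain * disp / 100, 0), 1)
}

#' Read out a value and belief-confidence rating
#'
#' Maps the latent belief to the rating scales: the value rating is the value
#' estimate plus Gaussian report noise (clipped to 0-100, recorded to 0.1
#' point); belief confidence is a fixed monotone-decreasing function of the
#' belief dispersion plus report noise (clipped to 0-1, recorded to 0.001).
#'
#' @param state A `belief_state`.
#' @param arm Arm index, 0 or 1.
#' @param params An `agent_params`.
#' @return A list with `value_rating` and `belief_confidence`.
#' @export
readout_rating <- function(state, arm, params) {
  a <- arm + 1L
  v <- state$est_value[a] + stats::rnorm(1L, 0, params$rating_noise_sd)
  conf <- latent_confidence(state, arm, params) +
    stats::rnorm(1L, 0, params$confidence_noise_sd)
  list(value_rating = round(min(max(v, 0), 100), 1L),
       belief_confidence = round(min(max(conf, 0), 1), 3L))
}

# Probability of choosing the lower-valued arm given the latent state.
explore_probability <- function(state, params) {
  dv <- abs(state$est_value[1L] - state$est_value[2L])
  hi <- which.max(state$est_value) - 1L
  c_high <- latent_confidence(state, hi, params)
  stats::plogis(-params$inverse_temperature * dv / 100 +
                  params$uncertainty_bonus * (1 - c_high))
}

#' Choice policy
#'
#' Chooses the lower-valued arm ("exploration") with probability
#' `plogis(-inverse_temperature * |dV|/100 + uncertainty_bonus * (1 - C_high))`
#' where `C_high` is the latent belief confidence of the currently
#' higher-valued arm; value ties are broken uniformly.
#'
#' @param state A `belief_state`.
#' @param params An `agent_params`.
#' @return The chosen arm, 0 or 1.
#' @export
choose_arm <- function(state, params) {
  v <- state$est_value
  if (v[1L] == v[2L]) return(sample(c(0L, 1L), 1L))
  hi <- which.max(v) - 1L
  if (stats::runif(1L) < explore_probability(state, params)) 1L - hi else hi
}

#' Read out decision confidence
#'
#' A linear map of the latent beliefs about both arms onto the confidence
#' scale, with the sign pattern characteristic of value-based decision
#' confidence: higher chosen value and lower unchosen value raise it, and
#' higher belief confidence in either arm raises it (the chosen arm's
#' confidence weighted more heavily). Gaussian report noise, clipped to 0-1.
#'
#' @param state A `belief_state`.
#' @param chosen_arm Arm chosen on this trial, 0 or 1.
#' @param params An `agent_params`.
#' @param noiseless If TRUE, return the latent readout without report noise.
#' @return Decision confidence in `[0, 1]`.
#' @export
readout_decision_confidence <- function(state, chosen_arm, params,
                                        noiseless = FALSE) {
  ch <- chosen_arm + 1L
  un <- 2L - chosen_arm
  w <- params$dc_weights
  c_ch <- latent_confidence(state, chosen_arm, params)
  c_un <- latent_confidence(state, 1L - chosen_arm, params)
  g <- 0.5 + w[[1L]] * (state$est_value[ch] - state$est_value[un]) / 100 +
    w[[2L]] * (c_ch - 0.5) + w[[3L]] * (c_un - 0.5)
  if (!noiseless) g <- g + stats::rnorm(1L, 0, params$confidence_noise_sd)
  round(min(max(g, 0), 1), 3L)
}

#' Simulate one subject on a schedule
#'
#' Walks the shared experiment schedule with one agent. On rating trials in
#' the rating-heavy design the agent observes the shown arm's outcome,
#' updates, and then rates that arm; in the choice-heavy design rating trials
#' show no outcome and the agent rates both arms without updating. On choice
#' trials the agent chooses, reports decision confidence, then observes the
#' chosen arm's outcome and updates. Reaction times on choice trials are
#' log-normal with a mean that decreases with latent decision confidence.
#' Beliefs reset at block boundaries (each block has fresh reward
#' distributions).
#'
#' @param schedule An `experiment_schedule` from [build_experiment()], or an
#'   `experiment_config` (a schedule is then built from its seed).
#' @param params An `agent_params`.
#' @param subject_id Subject label for the log.
#' @param seed Integer seed for the agent's private randomness (report noise,
#'   choices). The schedule's outcomes are fixed by the schedule itself.
#' @return A list with `log` (trial-log data frame), `truth` (per-trial
#'   latent states for both arms), and `params`.
#' @export
simulate_subject <- function(schedule, params, subject_id = "s01", seed = 1L) {
  if (inherits(schedule, "experiment_config")) schedule <- build_experiment(schedule)
  stopifnot(inherits(schedule, "experiment_schedule"))
  config <- schedule$config
  sch <- schedule$schedule
  set.seed(seed)
  n <- nrow(sch)
  log <- empty_trial_log()[rep(1L, n), ]
  rownames(log) <- NULL
  log$subject <- subject_id
  log$block <- sch$block
  log$trial <- sch$trial
  log$trial_type <- sch$trial_type
  truth <- data.frame(subject = subject_id, block = sch$block, trial = sch$trial,
                      est_value0 = NA_real_, est_sd0 = NA_real_,
                      est_value1 = NA_real_, est_sd1 = NA_real_)
  state <- belief_state(params)
  cur_block <- sch$block[1L]
  for (i in seq_len(n)) {
    if (sch$block[i] != cur_block) {  # new block: fresh distributions, fresh beliefs
      state <- belief_state(params)
      cur_block <- sch$block[i]
    }
    if (sch$trial_type[i] == "rating") {
      arm <- sch$rating_arm[i]
      log$arm[i] <- arm
      if (config$rating_shows_outcome) {
        x <- if (arm == 0L) sch$outcome0[i] else sch$outcome1[i]
        state <- update_belief(state, arm, x, params)
        log$outcome[i] <- x
      }
      r <- readout_rating(state, arm, params)
      log$value_rating[i] <- r$value_rating
      log$belief_conf[i] <- r$belief_confidence
      if (config$rating_rates_both_arms) {
        r2 <- readout_rating(state, 1L - arm, params)
        log$value_rating_other[i] <- r2$value_rating
        log$belief_conf_other[i] <- r2$belief_confidence
      }
    } else {
      arm <- choose_arm(state, params)
      log$arm[i] <- arm
      dc_latent <- readout_decision_confidence(state, arm, params, noiseless = TRUE)
      log$decision_conf[i] <- readout_decision_confidence(state, arm, params)
      log$rt_ms[i] <- round(exp(stats::rnorm(1L, log(820) - 0.5 * (dc_latent - 0.5),
                                             0.25)), 1L)
      x <- if (arm == 0L) sch$outcome0[i] else sch$outcome1[i]
      log$outcome[i] <- x
      state <- update_belief(state, arm, x, params)
    }
    truth$est_value0[i] <- state$est_value[1L]
    truth$est_sd0[i] <- state$est_sd[1L]
    truth$est_value1[i] <- state$est_value[2L]
    truth$est_sd1[i] <- state$est_sd[2L]
  }
  list(log = log, truth = truth, params = params)
}
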
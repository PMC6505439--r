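# Column-wise fit data extracted once from a (single-subject) trial log.
prepare_fit_data <- function(log, design = NULL) {
  if (is.null(design)) {
    design <- if (any(!is.na(log$value_rating_other))) "exp2" else "exp1"
  }
  list(block = as.integer(log$block),
       is_choice = as.integer(log$trial_type == "choice"),
       arm = as.integer(log$arm),
       outcome = as.numeric(log$outcome),
       vr = as.numeric(log$value_rating),
       bc = as.numeric(log$belief_conf),
       vr_other = as.numeric(log$value_rating_other),
       bc_other = as.numeric(log$belief_conf_other),
       design = if (design == "exp1") 1L else 2L)
}

params_to_vector <- function(params) {
  c(params$learning_rate, params$confidence_gain, params$inverse_temperature,
    params$uncertainty_bonus, params$rating_noise_sd, params$confidence_noise_sd,
    params$obs_concentration)
}

model_code <- function(model_tag) {
  match(model_tag, c("ideal", "rl", "particle")) - 1L
}

#' Trial-log negative log-likelihood of an agent model
#'
#' Sums, over a single subject's time-ordered trial log, the Gaussian
#' observation log-likelihood of the value and belief-confidence ratings
#' around the model's latent readouts (rating trials; both arms when both
#' were rated), and the choice policy's log-probability of the chosen arm
#' (choice trials). Latent states follow exactly the belief updates of the
#' agents module, resetting at block boundaries.
#'
#' @param log A single-subject trial-log data frame.
#' @param model_tag `"ideal"`, `"rl"`, or `"particle"`.
#' @param params An `agent_params` (or a numeric vector
#'   `c(learning_rate, confidence_gain, inverse_temperature,
#'   uncertainty_bonus, rating_noise_sd, confidence_noise_sd,
#'   obs_concentration)`).
#' @param design `"exp1"`/`"exp2"`; inferred from the log if NULL.
#' @param n_particles Particle count for the particle model.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation used for cross-checks).
#' @return The negative log-likelihood (0 for an empty log).
#' @export
agent_nll <- function(log, model_tag, params, design = NULL, n_particles = 50L,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (nrow(log) == 0L) return(0)
  if (inherits(params, "agent_params")) {
    n_particles <- params$n_particles
    params <- params_to_vector(params)
  }
  stopifnot(length(params) == 7L)
  fd <- prepare_fit_data(log, design)
  if (engine == "cpp")
    .bm_nll_cpp(fd$block, fd$is_choice, fd$arm, fd$outcome, fd$vr, fd$bc,
                fd$vr_other, fd$bc_other, fd$design, model_code(model_tag),
                params, as.integer(n_particles))
  else
    agent_nll_r(fd, model_tag, params, n_particles)
}

# Pure-R reference likelihood, sharing the agents-module update functions.
agent_nll_r <- function(fd, model_tag, par, n_particles) {
  p <- agent_params(model_tag = model_tag,
                    learning_rate = min(max(par[1L], 1e-6), 1),
                    confidence_gain = par[2L], inverse_temperature = par[3L],
                    uncertainty_bonus = par[4L], rating_noise_sd = par[5L],
                    confidence_noise_sd = par[6L], n_particles = n_particles,
                    obs_concentration = par[7L])
  state <- belief_state(p)
  n <- length(fd$block)
  cur_block <- fd$block[1L]
  nll <- 0
  for (i in seq_len(n)) {
    if (fd$block[i] != cur_block) {
      state <- belief_state(p)
      cur_block <- fd$block[i]
    }
    a <- fd$arm[i]
    if (fd$is_choice[i] == 0L) {
      if (fd$design == 1L && !is.na(fd$outcome[i]))
        state <- update_belief(state, a, fd$outcome[i], p)
      if (!is.na(fd$vr[i]))
        nll <- nll - stats::dnorm(fd$vr[i], state$est_value[a + 1L],
                                  p$rating_noise_sd, log = TRUE)
      if (!is.na(fd$bc[i]))
        nll <- nll - stats::dnorm(fd$bc[i], latent_confidence(state, a, p),
                                  p$confidence_noise_sd, log = TRUE)
      if (fd$design == 2L) {
        o <- 1L - a
        if (!is.na(fd$vr_other[i]))
          nll <- nll - stats::dnorm(fd$vr_other[i], state$est_value[o + 1L],
                                    p$rating_noise_sd, log = TRUE)
        if (!is.na(fd$bc_other[i]))
          nll <- nll - stats::dnorm(fd$bc_other[i], latent_confidence(state, o, p),
                                    p$confidence_noise_sd, log = TRUE)
      }
    } else {
      v <- state$est_value
      if (v[1L] == v[2L]) pch <- 0.5
      else {
        hi <- which.max(v) - 1L
        p_lo <- explore_probability(state, p)
        pch <- if (a == hi) 1 - p_lo else p_lo
      }
      nll <- nll - log(max(pch, 1e-12))
      if (!is.na(fd$outcome[i])) state <- update_belief(state, a, fd$outcome[i], p)
    }
  }
  nll
}

# Number of scalar likelihood components in a log (for the BIC sample size).
count_likelihood_obs <- function(log, design = NULL) {
  fd <- prepare_fit_data(log, design)
  rating <- fd$is_choice == 0L
  sum(fd$is_choice == 1L) +
    sum(rating & !is.na(fd$vr)) + sum(rating & !is.na(fd$bc)) +
    if (fd$design == 2L)
      sum(rating & !is.na(fd$vr_other)) + sum(rating & !is.na(fd$bc_other))
    else 0L
}

# Free-parameter layout per model: indices into the length-7 parameter
# vector (lr, gain, beta_t, bonus, rating_sd, conf_sd, conc) plus bounds.
model_free_params <- function(model_tag) {
  all_names <- c("learning_rate", "confidence_gain", "inverse_temperature",
                 "uncertainty_bonus", "rating_noise_sd", "confidence_noise_sd",
                 "obs_concentration")
  lower <- c(0.02, 0.1, 0, -2, 0.5, 0.01, 1)
  upper <- c(1, 5, 30, 3, 40, 0.5, 40)
  free <- switch(model_tag,
                 ideal = 2:6,
                 rl = 1:6,
                 particle = c(2:6, 7L))
  list(names = all_names, free = free, lower = lower, upper = upper,
       default = c(0.3, 2.5, 14, 0.5, 3, 0.05, 12))
}

#' Fit an agent model to a trial log
#'
#' Bounded multi-start maximum-likelihood fit (L-BFGS-B; seeded random
#' restarts within the parameter box, the first start at the default
#' parameters). Returns the best restart.
#'
#' @param log A single-subject trial-log data frame with at least 50 trials.
#' @param model_tag `"ideal"`, `"rl"`, or `"particle"`.
#' @param n_restarts Number of optimizer starts (default 10).
#' @param seed Integer seed for the restart draws.
#' @param design `"exp1"`/`"exp2"`; inferred if NULL.
#' @param n_particles Particle count for the particle model.
#' @return An object of class `fit_result`: `model_tag`, `params` (named,
#'   the length-7 vector with fitted entries), `free` (names of fitted
#'   parameters), `nll`, `bic` (`k log(n_obs) + 2 nll`), `n_obs`,
#'   `converged`, `n_restarts`.
#' @export
fit_agent <- function(log, model_tag, n_restarts = 10L, seed = 1L,
                      design = NULL, n_particles = 50L) {
  if (nrow(log) < 50L) stop("fit_agent: need at least 50 trials")
  fd <- prepare_fit_data(log, design)
  layout <- model_free_params(model_tag)
  free <- layout$free
  mcode <- model_code(model_tag)
  obj <- function(theta) {
    par <- layout$default
    par[free] <- theta
    v <- .bm_nll_cpp(fd$block, fd$is_choice, fd$arm, fd$outcome, fd$vr, fd$bc,
                     fd$vr_other, fd$bc_other, fd$design, mcode, par,
                     as.integer(n_particles))
    if (!is.finite(v)) 1e10 else v
  }
  set.seed(seed)
  starts <- matrix(NA_real_, n_restarts, length(free))
  starts[1L, ] <- layout$default[free]
  if (n_restarts > 1L)
    for (r in 2:n_restarts)
      starts[r, ] <- stats::runif(length(free), layout$lower[free], layout$upper[free])
  best <- NULL
  any_converged <- FALSE
  for (r in seq_len(n_restarts)) {
    fit <- try(stats::optim(starts[r, ], obj, method = "L-BFGS-B",
                            lower = layout$lower[free], upper = layout$upper[free],
                            control = list(maxit = 300, factr = 1e8)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("fit_agent: all restarts failed")
  par <- layout$default
  par[free] <- best$par
  names(par) <- layout$names
  n_obs <- count_likelihood_obs(log, design)
  k <- length(free)
  structure(list(model_tag = model_tag, params = par,
                 free = layout$names[free], nll = best$value,
                 bic = k * log(n_obs) + 2 * best$value,
                 n_obs = n_obs, k = k, converged = any_converged,
                 n_restarts = n_restarts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s model: nll = %.2f, BIC = %.2f (k = %d, n = %d)\n",
              x$model_tag, x$nll, x$bic, x$k, x$n_obs))
  print(round(x$params[x$free], 4))
  invisible(x)
}

#' Compare agent models across subjects by BIC
#'
#' Fits each candidate model to every subject's log and ranks models by
#' summed BIC; also counts, per model, how many subjects it fits best.
#'
#' @param log A trial-log data frame (one or more subjects).
#' @param model_tags Candidate models (default all three).
#' @param n_restarts Optimizer starts per fit.
#' @param seed Integer seed.
#' @param design `"exp1"`/`"exp2"`; inferred if NULL.
#' @return A list with `table` (subject x model fit results: parameters,
#'   nll, bic, converged), `summed_bic` (named, ascending), `ranking`
#'   (model tags, best first), and `best_counts`.
#' @export
compare_agents <- function(log, model_tags = c("ideal", "rl", "particle"),
                           n_restarts = 10L, seed = 1L, design = NULL) {
  if (length(model_tags) < 2L) stop("compare_agents: need at least 2 models")
  subs <- unique(log$subject)
  rows <- list()
  for (s in subs) {
    ls <- log[log$subject == s, , drop = FALSE]
    for (m in model_tags) {
      fit <- fit_agent(ls, m, n_restarts = n_restarts,
                       seed = seed + match(s, subs), design = design)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(subject = s, model = m, nll = fit$nll, bic = fit$bic,
                         k = fit$k, n_obs = fit$n_obs, converged = fit$converged),
              as.data.frame(as.list(fit$params)))
    }
  }
  tab <- do.call(rbind, rows)
  summed <- sort(tapply(tab$bic, tab$model, sum))
  per_subj_best <- tapply(seq_len(nrow(tab)), tab$subject, function(i)
    tab$model[i][which.min(tab$bic[i])])
  best_counts <- table(factor(unlist(per_subj_best), levels = model_tags))
  list(table = tab, summed_bic = summed, ranking = names(summed),
       best_counts = best_counts)
}
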
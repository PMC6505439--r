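# Replace interaction terms "a:b" by explicit product columns of the
# (already standardized) components, so that both fixed and random formula
# parts reduce to plain column names.
expand_interactions <- function(data, terms) {
  out_terms <- character(length(terms))
  for (j in seq_along(terms)) {
    parts <- strsplit(terms[j], ":", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) { out_terms[j] <- terms[j]; next }
    col <- paste(parts, collapse = "_x_")
    data[[col]] <- Reduce(`*`, lapply(parts, function(p) data[[p]]))
    out_terms[j] <- col
  }
  list(data = data, terms = out_terms)
}

grand_z <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(x * 0)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Fit a hierarchical (mixed-effects) regression
#'
#' Maximum-likelihood fit of a linear or logistic mixed model with a
#' per-subject random intercept and random slopes for all fixed terms.
#' Predictors (and, for linear models, the outcome) are z-transformed before
#' fitting so coefficients are standardized; interaction terms are products
#' of the standardized components.
#'
#' When a random structure fails to converge the fit falls back down a
#' ladder — correlated slopes, uncorrelated (diagonal) slopes, intercept
#' only, and finally per-subject fits pooled by inverse variance — and the
#' result records which structure was actually fitted. The default entry
#' point is the diagonal structure (random intercept plus uncorrelated
#' random slopes for every regressor), which is far more stable on designs
#' of this size; `random = "full"` requests slope correlations.
#'
#' @param data Data frame.
#' @param outcome Name of the outcome column (binary 0/1 for logistic).
#' @param fixed_terms Character vector of predictors; interactions as
#'   `"a:b"`.
#' @param family `"linear"` or `"logistic"`.
#' @param random Entry rung: `"full"`, `"diag"`, `"intercept"`, or
#'   `"two_stage"`.
#' @param subject Name of the grouping column.
#' @param standardize Standardize predictors/outcome (default TRUE).
#' @return An object of class `bm_regression`: a list with `coefficients`
#'   (term, beta, se, stat, df, p), `bic` (at the ML optimum; NA for the
#'   two-stage fallback), `n_obs`, `family`, `structure` (rung fitted),
#'   `converged`, `singular`, and `subject_coefs` (per-subject coefficients,
#'   fixed + random).
#' @export
fit_hierarchical <- function(data, outcome, fixed_terms,
                             family = c("linear", "logistic"),
                             random = c("diag", "full", "intercept", "two_stage"),
                             subject = "subject", standardize = TRUE) {
  family <- match.arg(family)
  random <- match.arg(random)
  base_vars <- unique(unlist(strsplit(fixed_terms, ":", fixed = TRUE)))
  missing_cols <- setdiff(c(outcome, base_vars, subject), names(data))
  if (length(missing_cols))
    stop("fit_hierarchical: missing column(s): ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[, c(outcome, base_vars, subject)])
  data <- data[keep, , drop = FALSE]
  if (length(unique(data[[subject]])) < 2L)
    stop("fit_hierarchical: need at least 2 subjects")
  if (standardize) {
    for (v in base_vars) data[[v]] <- grand_z(data[[v]])
    if (family == "linear") data[[outcome]] <- grand_z(data[[outcome]])
  }
  ex <- expand_interactions(data, fixed_terms)
  data <- ex$data
  terms <- ex$terms
  ladder <- c("full", "diag", "intercept", "two_stage")
  ladder <- ladder[match(random, ladder):length(ladder)]
  last_err <- NULL
  for (rung in ladder) {
    res <- try(fit_one_rung(data, outcome, terms, family, rung, subject),
               silent = TRUE)
    if (!inherits(res, "try-error")) {
      res$structure <- rung
      res$fallback_from <- if (rung == random) NA_character_ else random
      return(res)
    }
    last_err <- attr(res, "condition")$message
  }
  stop("fit_hierarchical: no random structure converged: ", last_err)
}

fit_one_rung <- function(data, outcome, terms, family, rung, subject) {
  fx <- paste(terms, collapse = " + ")
  if (rung == "two_stage") return(fit_two_stage(data, outcome, terms, family, subject))
  re <- switch(rung,
               full = sprintf("(1 + %s | %s)", fx, subject),
               diag = sprintf("(1 + %s || %s)", fx, subject),
               intercept = sprintf("(1 | %s)", subject))
  f <- stats::as.formula(paste(outcome, "~", fx, "+", re))
  warned <- character(0)
  fit <- withCallingHandlers({
    if (family == "linear")
      lmerTest::lmer(f, data = data, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
    else
      lme4::glmer(f, data = data, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               optimizer = "bobyqa"))
  }, warning = function(w) {
    warned <<- c(warned, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) invokeRestart("muffleMessage"))
  if (any(grepl("failed to converge|convergence code", warned)))
    stop("mixed-model fit did not converge at rung '", rung, "'")
  co <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(co), beta = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      stat = co[, ncol(co) - 1L],
                      df = if ("df" %in% colnames(co)) co[, "df"] else NA_real_,
                      p = co[, ncol(co)], row.names = NULL)
  sc <- try(stats::coef(fit)[[subject]], silent = TRUE)
  structure(list(coefficients = coefs, bic = stats::BIC(fit),
                 n_obs = nrow(data), family = family,
                 converged = TRUE, singular = lme4::isSingular(fit),
                 subject_coefs = if (inherits(sc, "try-error")) NULL else sc,
                 warnings = warned),
            class = "bm_regression")
}

# Per-subject fixed-effect fits pooled by inverse variance; the last rung.
fit_two_stage <- function(data, outcome, terms, family, subject) {
  f <- stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  subs <- unique(data[[subject]])
  betas <- ses <- matrix(NA_real_, length(subs), length(terms) + 1L)
  for (k in seq_along(subs)) {
    d <- data[data[[subject]] == subs[k], , drop = FALSE]
    fit <- try(if (family == "linear") stats::lm(f, data = d)
               else suppressWarnings(stats::glm(f, data = d, family = stats::binomial())),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    co <- summary(fit)$coefficients
    idx <- match(c("(Intercept)", terms), rownames(co))
    betas[k, ] <- co[idx, 1L]
    ses[k, ] <- co[idx, 2L]
  }
  w <- 1 / ses^2
  beta <- colSums(betas * w, na.rm = TRUE) / colSums(w, na.rm = TRUE)
  se <- sqrt(1 / colSums(w, na.rm = TRUE))
  stat <- beta / se
  coefs <- data.frame(term = c("(Intercept)", terms), beta = beta, se = se,
                      stat = stat, df = NA_real_,
                      p = 2 * stats::pnorm(-abs(stat)), row.names = NULL)
  sc <- as.data.frame(betas)
  names(sc) <- c("(Intercept)", terms)
  rownames(sc) <- subs
  structure(list(coefficients = coefs, bic = NA_real_, n_obs = nrow(data),
                 family = family, converged = TRUE, singular = FALSE,
                 subject_coefs = sc, warnings = character(0)),
            class = "bm_regression")
}

#' @export
print.bm_regression <- function(x, ...) {
  cat(sprintf("Hierarchical %s regression (%s random structure, n = %d)\n",
              x$family, x$structure, x$n_obs))
  if (!is.na(x$bic)) cat(sprintf("BIC (ML): %.1f\n", x$bic))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

# Extract one coefficient (beta) by term name.
coef_of <- function(res, term) {
  i <- match(term, res$coefficients$term)
  if (is.na(i)) stop("term not found: ", term)
  res$coefficients$beta[i]
}

#' Decision-confidence model
#'
#' Hierarchical linear regression of decision confidence on the carried
#' (most recently rated) value beliefs and belief confidences of the chosen
#' and unchosen option, their value interaction, and two controls: objective
#' accuracy and log reaction time. All predictors standardized; random
#' intercept and slopes per subject.
#'
#' @param view A labelled choice-trial view ([preprocess_choices()]).
#' @param include_trial Also control for the (log) trial number within the
#'   block (off by default; selectable for model-ladder comparisons).
#' @param ... Passed to [fit_hierarchical()] (e.g. `random`).
#' @return A `bm_regression`.
#' @export
decision_confidence_model <- function(view, include_trial = FALSE, ...) {
  d <- view
  d$v_chosen <- ifelse(d$arm == 0L, d$carried_v0, d$carried_v1)
  d$v_unchosen <- ifelse(d$arm == 0L, d$carried_v1, d$carried_v0)
  d$c_chosen <- ifelse(d$arm == 0L, d$carried_c0, d$carried_c1)
  d$c_unchosen <- ifelse(d$arm == 0L, d$carried_c1, d$carried_c0)
  d$log_trial <- log(d$trial)
  d <- d[d$usable & !is.na(d$accuracy) & !is.na(d$decision_conf), , drop = FALSE]
  terms <- c("v_chosen", "v_unchosen", "v_chosen:v_unchosen",
             "c_chosen", "c_unchosen", "accuracy", "log_rt")
  if (include_trial) terms <- c(terms, "log_trial")
  fit_hierarchical(d, "decision_conf", terms, family = "linear", ...)
}

#' Exploration model
#'
#' Hierarchical logistic regression of the exploration flag (choosing the
#' arm most recently rated lower) on the belief confidence of the
#' higher-rated arm, the absolute carried value difference, and their
#' interaction. All predictors standardized; random intercept and slopes per
#' subject.
#'
#' @param view A labelled choice-trial view ([preprocess_choices()]).
#' @param ... Passed to [fit_hierarchical()].
#' @return A `bm_regression`.
#' @export
exploration_model <- function(view, ...) {
  d <- view[!is.na(view$explore) & !is.na(view$conf_high) & !is.na(view$abs_dv), ,
            drop = FALSE]
  fit_hierarchical(d, "explore", c("conf_high", "abs_dv", "conf_high:abs_dv"),
                   family = "logistic", ...)
}

# Rating rows annotated with the running mean/SD of outcomes observed so far
# for the rated arm (for designs that show outcomes on rating trials, the
# just-shown outcome is included: the rating is given after seeing it). For
# both-arm rating designs, each rating trial yields one row per arm.
rating_observer_table <- function(log) {
  n <- nrow(log)
  cap <- 2L * n
  o_subject <- character(cap); o_block <- integer(cap); o_trial <- integer(cap)
  o_arm <- integer(cap); o_conf <- numeric(cap); o_mu <- numeric(cap)
  o_sig <- numeric(cap); o_n <- integer(cap)
  m <- 0L
  key_prev <- NULL
  wn <- c(0L, 0L); wmean <- c(0, 0); wm2 <- c(0, 0)  # per-arm Welford state
  subj <- log$subject; blk <- log$block; trl <- log$trial
  arm <- log$arm; outc <- log$outcome; typ <- log$trial_type
  conf <- log$belief_conf; conf_o <- log$belief_conf_other
  for (i in seq_len(n)) {
    key <- paste(subj[i], blk[i])
    if (!identical(key, key_prev)) {
      wn <- c(0L, 0L); wmean <- c(0, 0); wm2 <- c(0, 0); key_prev <- key
    }
    a <- arm[i] + 1L
    if (!is.na(outc[i])) {
      x <- outc[i]
      wn[a] <- wn[a] + 1L
      d <- x - wmean[a]
      wmean[a] <- wmean[a] + d / wn[a]
      wm2[a] <- wm2[a] + d * (x - wmean[a])
    }
    if (typ[i] == "rating") {
      for (side in 1:2) {
        a1 <- if (side == 1L) a else 3L - a
        cf <- if (side == 1L) conf[i] else conf_o[i]
        if (is.na(cf) || wn[a1] < 2L) next
        m <- m + 1L
        o_subject[m] <- subj[i]; o_block[m] <- blk[i]; o_trial[m] <- trl[i]
        o_arm[m] <- a1 - 1L; o_conf[m] <- cf; o_mu[m] <- wmean[a1]
        o_sig[m] <- sqrt(wm2[a1] / (wn[a1] - 1L)); o_n[m] <- wn[a1]
      }
    }
  }
  if (m == 0L) return(NULL)
  idx <- seq_len(m)
  data.frame(subject = o_subject[idx], block = o_block[idx], trial = o_trial[idx],
             arm = o_arm[idx], belief_conf = o_conf[idx], mu_past = o_mu[idx],
             sig_past = o_sig[idx], n_past = o_n[idx],
             log_trial = log(o_trial[idx]))
}

#' Belief-confidence (ideal-observer tracking) model
#'
#' Hierarchical linear regression of reported belief confidence on the
#' standard deviation (`sig_past`) and mean (`mu_past`) of the outcomes
#' observed so far for the rated arm, the log trial number within the block,
#' and the arm, with all two-way interactions among the first three and
#' their three-way interaction. The `sig_past` slope measures how strongly a
#' subject's confidence tracks normative (ideal-observer) uncertainty;
#' per-subject `sig_past` slopes are exported for the metacognition link.
#'
#' @param log A trial-log data frame.
#' @param ... Passed to [fit_hierarchical()].
#' @return A `bm_regression` with an extra `beta_sig_subject` element (named
#'   per-subject slopes for `sig_past`).
#' @export
belief_confidence_model <- function(log, ...) {
  d <- rating_observer_table(log)
  if (is.null(d) || nrow(d) == 0L)
    stop("belief_confidence_model: no rating rows with >= 2 observed outcomes")
  terms <- c("sig_past", "mu_past", "log_trial", "arm",
             "sig_past:mu_past", "sig_past:log_trial", "mu_past:log_trial",
             "sig_past:mu_past:log_trial")
  res <- fit_hierarchical(d, "belief_conf", terms, family = "linear", ...)
  if (!is.null(res$subject_coefs) && "sig_past" %in% names(res$subject_coefs)) {
    res$beta_sig_subject <- stats::setNames(res$subject_coefs[["sig_past"]],
                                            rownames(res$subject_coefs))
  }
  res
}

#' Estimation error by block halves
#'
#' Per subject, the mean absolute difference between each value rating and
#' the running mean of outcomes observed so far for the rated arm, split by
#' first vs second half of each block (middle trial of odd blocks counts as
#' first half), compared by a paired t-test across subjects.
#'
#' @param log A trial-log data frame.
#' @return An object of class `bm_stat` with the t statistic, df, p, the two
#'   group means (points), and the per-subject table.
#' @export
halves_estimation_error <- function(log) {
  d <- rating_observer_table_any(log)
  if (is.null(d) || nrow(d) == 0L) stop("halves_estimation_error: no usable rating rows")
  len <- stats::aggregate(trial ~ subject + block, data = log, FUN = max)
  names(len)[3L] <- "block_len"
  d <- merge(d, len, by = c("subject", "block"))
  d$half <- ifelse(d$trial <= ceiling(d$block_len / 2), "first", "second")
  d$err <- abs(d$value_rating - d$mu_past)
  per <- stats::aggregate(err ~ subject + half, data = d, FUN = mean)
  wide <- stats::reshape(per, idvar = "subject", timevar = "half", direction = "wide")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 2L || stats::sd(wide$err.first - wide$err.second) == 0) {
    return(structure(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                          effect_size = NA_real_,
                          means = c(first = mean(wide$err.first),
                                    second = mean(wide$err.second)),
                          per_subject = wide, degenerate = TRUE),
                     class = "bm_stat"))
  }
  tt <- stats::t.test(wide$err.first, wide$err.second, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, effect_size = NA_real_,
                 means = c(first = mean(wide$err.first), second = mean(wide$err.second)),
                 per_subject = wide, degenerate = FALSE),
            class = "bm_stat")
}

# Like rating_observer_table but requiring only >= 1 observed outcome and
# keeping the value rating (for estimation-error analyses).
rating_observer_table_any <- function(log) {
  n <- nrow(log)
  cap <- 2L * n
  o_subject <- character(cap); o_block <- integer(cap); o_trial <- integer(cap)
  o_arm <- integer(cap); o_vr <- numeric(cap); o_mu <- numeric(cap); o_n <- integer(cap)
  m <- 0L
  key_prev <- NULL
  run_sum <- c(0, 0); run_n <- c(0L, 0L)
  subj <- log$subject; blk <- log$block; trl <- log$trial
  arm <- log$arm; outc <- log$outcome; typ <- log$trial_type
  vr <- log$value_rating; vr_o <- log$value_rating_other
  for (i in seq_len(n)) {
    key <- paste(subj[i], blk[i])
    if (!identical(key, key_prev)) {
      run_sum <- c(0, 0); run_n <- c(0L, 0L); key_prev <- key
    }
    a <- arm[i] + 1L
    if (!is.na(outc[i])) {
      run_sum[a] <- run_sum[a] + outc[i]
      run_n[a] <- run_n[a] + 1L
    }
    if (typ[i] == "rating") {
      for (side in 1:2) {
        a1 <- if (side == 1L) a else 3L - a
        v <- if (side == 1L) vr[i] else vr_o[i]
        if (is.na(v) || run_n[a1] < 1L) next
        m <- m + 1L
        o_subject[m] <- subj[i]; o_block[m] <- blk[i]; o_trial[m] <- trl[i]
        o_arm[m] <- a1 - 1L; o_vr[m] <- v
        o_mu[m] <- run_sum[a1] / run_n[a1]; o_n[m] <- run_n[a1]
      }
    }
  }
  if (m == 0L) return(NULL)
  idx <- seq_len(m)
  data.frame(subject = o_subject[idx], block = o_block[idx], trial = o_trial[idx],
             arm = o_arm[idx], value_rating = o_vr[idx], mu_past = o_mu[idx],
             n_past = o_n[idx])
}

#' @export
print.bm_stat <- function(x, ...) {
  cat(sprintf("statistic = %.3f, df = %s, p = %.4g\n", x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p_value))
  if (!is.null(x$means)) { cat("means:\n"); print(round(x$means, 3)) }
  invisible(x)
}

#' Repeated-measures trend ANOVA over within-subject bins
#'
#' One-way repeated-measures ANOVA on per-subject bin means with a
#' Greenhouse-Geisser sphericity correction, partial eta squared, and the
#' linear polynomial-contrast test. Subjects missing any bin are dropped
#' with a warning.
#'
#' @param data Data frame with one value per trial.
#' @param value Name of the value column.
#' @param bin Name of the bin-label column (integer 1..k).
#' @param subject Name of the subject column.
#' @return An object of class `bm_stat`: uncorrected and GG-corrected F test
#'   (`statistic`, `df` = GG-corrected df pair, `p_value`, `effect_size` =
#'   partial eta squared), plus `linear` (the linear-trend F test) and the
#'   bin means.
#' @export
quintile_trend_anova <- function(data, value, bin, subject = "subject") {
  d <- data[!is.na(data[[value]]) & !is.na(data[[bin]]), , drop = FALSE]
  agg <- stats::aggregate(d[[value]], list(subject = d[[subject]], bin = d[[bin]]),
                          FUN = mean)
  k <- length(unique(agg$bin))
  tab <- stats::reshape(agg, idvar = "subject", timevar = "bin", direction = "wide")
  complete <- stats::complete.cases(tab)
  if (any(!complete))
    warning(sprintf("quintile_trend_anova: dropping %d subject(s) missing a bin",
                    sum(!complete)))
  tab <- tab[complete, , drop = FALSE]
  Y <- as.matrix(tab[, order(as.integer(sub("^x\\.", "", names(tab)[-1L]))) + 1L])
  n <- nrow(Y)
  if (n < 2L) stop("quintile_trend_anova: need at least 2 complete subjects")
  grand <- mean(Y)
  bin_means <- colMeans(Y)
  subj_means <- rowMeans(Y)
  ss_bins <- n * sum((bin_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_bins - ss_subj
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  if (ss_bins < 1e-12) {  # identical bin means (possibly with zero error too)
    F_ <- 0
    eta2p <- 0
  } else {
    F_ <- (ss_bins / df1) / (ss_err / df2)
    eta2p <- ss_bins / (ss_bins + ss_err)
  }
  # Greenhouse-Geisser epsilon from the sample covariance of the bin scores
  S <- stats::cov(Y)
  sbar <- mean(S)
  sd_diag <- mean(diag(S))
  row_means <- rowMeans(S)
  eps_num <- (k * (sd_diag - sbar))^2
  eps_den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
  eps <- if (eps_den > 0) min(max(eps_num / eps_den, 1 / (k - 1)), 1) else 1
  p_gg <- stats::pf(F_, df1 * eps, df2 * eps, lower.tail = FALSE)
  # linear polynomial contrast, tested across subjects (rows are centred
  # first so subject-only variance yields an exact zero contrast)
  cpoly <- stats::contr.poly(k)[, 1L]
  L <- as.numeric((Y - rowMeans(Y)) %*% cpoly)
  if (stats::sd(L) < 1e-12) {
    lin <- list(statistic = 0, df = c(1, n - 1L), p_value = 1, effect_size = 0)
  } else {
    t_ <- mean(L) / (stats::sd(L) / sqrt(n))
    lin <- list(statistic = t_^2, df = c(1, n - 1L),
                p_value = 2 * stats::pt(-abs(t_), n - 1L),
                effect_size = t_^2 / (t_^2 + (n - 1L)),
                slope_sign = sign(mean(L)))
  }
  structure(list(statistic = F_, df = c(df1 * eps, df2 * eps), p_value = p_gg,
                 effect_size = eta2p, epsilon = eps,
                 df_uncorrected = c(df1, df2),
                 p_uncorrected = stats::pf(F_, df1, df2, lower.tail = FALSE),
                 linear = lin, means = bin_means, n_subjects = n),
            class = "bm_stat")
}

#' Per-subject correlation of belief updates and confidence changes
#'
#' For consecutive ratings of the same arm within a block, correlates the
#' absolute difference between the currently observed outcome and the arm's
#' previous value rating (the surprise driving the update) with the change
#' in belief confidence. One Pearson r per subject; subjects with fewer than
#' `min_pairs` usable pairs are skipped.
#'
#' @param log A trial-log data frame (a design whose rating trials reveal
#'   outcomes).
#' @param min_pairs Minimum usable pairs per subject (default 5).
#' @return Data frame: subject, r, n_pairs, p.
#' @export
update_vs_confidence_correlation <- function(log, min_pairs = 5L) {
  n <- nrow(log)
  pairs <- list(); pi_ <- 0L
  key_prev <- NULL
  last_v <- last_c <- c(NA_real_, NA_real_)
  for (i in seq_len(n)) {
    key <- paste(log$subject[i], log$block[i])
    if (!identical(key, key_prev)) {
      last_v <- last_c <- c(NA_real_, NA_real_); key_prev <- key
    }
    if (log$trial_type[i] != "rating") next
    a <- log$arm[i] + 1L
    if (!is.na(log$outcome[i]) && !is.na(last_v[a]) && !is.na(last_c[a])) {
      pi_ <- pi_ + 1L
      pairs[[pi_]] <- data.frame(subject = log$subject[i],
                                 surprise = abs(log$outcome[i] - last_v[a]),
                                 dconf = log$belief_conf[i] - last_c[a])
    }
    last_v[a] <- log$value_rating[i]
    last_c[a] <- log$belief_conf[i]
  }
  if (pi_ == 0L) stop("update_vs_confidence_correlation: no usable rating pairs")
  d <- do.call(rbind, pairs)
  out <- lapply(unique(d$subject), function(s) {
    ds <- d[d$subject == s, ]
    if (nrow(ds) < min_pairs || stats::sd(ds$surprise) == 0 || stats::sd(ds$dconf) == 0)
      return(NULL)
    ct <- stats::cor.test(ds$surprise, ds$dconf)
    data.frame(subject = s, r = unname(ct$estimate), n_pairs = nrow(ds),
               p = ct$p.value)
  })
  do.call(rbind, out)
}
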
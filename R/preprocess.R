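#' Exclude slow/fast choice trials per subject
#'
#' Removes choice trials whose reaction time falls outside the subject's own
#' mean +/- 3 SD (both tails: fast lapses and distracted slow responses).
#' Rating trials are never excluded. Subjects with fewer than three choice
#' trials, or zero RT variance, are left untouched.
#'
#' @param log A trial-log data frame (possibly several subjects).
#' @return A list with `log` (filtered) and `report` (per subject: number of
#'   choice trials, number excluded, fraction excluded).
#' @export
exclude_rt_outliers <- function(log) {
  keep <- rep(TRUE, nrow(log))
  subjects <- unique(log$subject)
  report <- data.frame(subject = subjects, n_choice = NA_integer_,
                       n_excluded = NA_integer_, fraction = NA_real_)
  for (k in seq_along(subjects)) {
    idx <- which(log$subject == subjects[k] & log$trial_type == "choice")
    report$n_choice[k] <- length(idx)
    if (length(idx) < 3L) {
      warning(sprintf("exclude_rt_outliers: subject '%s' has fewer than 3 choice trials; skipped",
                      subjects[k]))
      report$n_excluded[k] <- 0L
      report$fraction[k] <- 0
      next
    }
    rt <- log$rt_ms[idx]
    m <- mean(rt, na.rm = TRUE)
    s <- stats::sd(rt, na.rm = TRUE)
    out <- if (is.na(s) || s == 0) rep(FALSE, length(idx)) else
      !is.na(rt) & abs(rt - m) > 3 * s
    keep[idx[out]] <- FALSE
    report$n_excluded[k] <- sum(out)
    report$fraction[k] <- sum(out) / length(idx)
  }
  list(log = log[keep, , drop = FALSE], report = report)
}

#' Within-subject z-transform
#'
#' Standardizes a series to mean 0, SD 1 within each subject, using the
#' population SD (divide by n). Missing values propagate; a zero-variance
#' subject gets all zeros with a warning.
#'
#' @param x Numeric vector.
#' @param subject Grouping vector of the same length.
#' @return Standardized numeric vector.
#' @export
zscore_within_subject <- function(x, subject) {
  stopifnot(length(x) == length(subject))
  out <- rep(NA_real_, length(x))
  for (s in unique(subject)) {
    i <- which(subject == s)
    v <- x[i]
    ok <- !is.na(v)
    if (sum(ok) < 2L) { out[i] <- ifelse(ok, 0, NA_real_); next }
    m <- mean(v[ok])
    sd_pop <- sqrt(mean((v[ok] - m)^2))
    if (sd_pop == 0) {
      warning("zscore_within_subject: zero variance; returning zeros")
      out[i][ok] <- 0
    } else out[i] <- (v - m) / sd_pop
  }
  out
}

#' Carry forward the latest ratings onto choice trials
#'
#' Propagates each arm's most recent value and belief-confidence rating onto
#' subsequent choice trials within the same block (carried values reset at
#' block boundaries, where the reward distributions change). Also tracks the
#' running mean and count of all outcomes observed so far (rating reveals and
#' choice reveals), evaluated *before* the current trial.
#'
#' @param log A time-ordered trial-log data frame.
#' @return A choice-trial view: one row per choice trial with carried
#'   `carried_v0/c0/v1/c1`, running `run_mean0/1` and `run_n0/1`, and a
#'   `usable` flag (both carried ratings present).
#' @export
carry_forward <- function(log) {
  is_choice <- log$trial_type == "choice"
  n <- nrow(log)
  cv <- matrix(NA_real_, n, 2L)  # carried value rating at choice rows
  cc <- matrix(NA_real_, n, 2L)
  rm_ <- matrix(NA_real_, n, 2L)
  rn <- matrix(0L, n, 2L)
  key_prev <- NULL
  last_v <- last_c <- c(NA_real_, NA_real_)
  run_sum <- c(0, 0); run_n <- c(0L, 0L)
  for (i in seq_len(n)) {
    key <- paste(log$subject[i], log$block[i])
    if (!identical(key, key_prev)) {
      last_v <- last_c <- c(NA_real_, NA_real_)
      run_sum <- c(0, 0); run_n <- c(0L, 0L)
      key_prev <- key
    }
    if (is_choice[i]) {
      cv[i, ] <- last_v
      cc[i, ] <- last_c
      rm_[i, ] <- ifelse(run_n > 0L, run_sum / pmax(run_n, 1L), NA_real_)
      rn[i, ] <- run_n
    }
    a <- log$arm[i] + 1L
    if (!is_choice[i]) {
      last_v[a] <- log$value_rating[i]
      last_c[a] <- log$belief_conf[i]
      if (!is.na(log$value_rating_other[i])) {
        last_v[3L - a] <- log$value_rating_other[i]
        last_c[3L - a] <- log$belief_conf_other[i]
      }
    }
    if (!is.na(log$outcome[i])) {
      run_sum[a] <- run_sum[a] + log$outcome[i]
      run_n[a] <- run_n[a] + 1L
    }
  }
  view <- log[is_choice, , drop = FALSE]
  view$carried_v0 <- cv[is_choice, 1L]
  view$carried_c0 <- cc[is_choice, 1L]
  view$carried_v1 <- cv[is_choice, 2L]
  view$carried_c1 <- cc[is_choice, 2L]
  view$run_mean0 <- rm_[is_choice, 1L]
  view$run_mean1 <- rm_[is_choice, 2L]
  view$run_n0 <- rn[is_choice, 1L]
  view$run_n1 <- rn[is_choice, 2L]
  view$usable <- !is.na(view$carried_v0) & !is.na(view$carried_v1)
  rownames(view) <- NULL
  view
}

#' Label exploration trials
#'
#' An exploration trial is a choice of the arm most recently rated as
#' yielding *lower* rewards (strict inequality); trials where the carried
#' ratings tie, or where either carried rating is missing, get NA and are
#' excluded from exploration analyses.
#'
#' @param view A choice-trial view from [carry_forward()].
#' @return The view with `explore` (0/1/NA) plus the exploration-model
#'   predictors: `carried_v_chosen`, `conf_high` (belief confidence of the
#'   higher-rated arm), `conf_low`, and `abs_dv`.
#' @export
label_exploration <- function(view) {
  v_ch <- ifelse(view$arm == 0L, view$carried_v0, view$carried_v1)
  v_ot <- ifelse(view$arm == 0L, view$carried_v1, view$carried_v0)
  view$explore <- ifelse(!view$usable | v_ch == v_ot, NA_real_,
                         as.numeric(v_ch < v_ot))
  hi0 <- view$carried_v0 > view$carried_v1
  view$conf_high <- ifelse(!view$usable | view$carried_v0 == view$carried_v1,
                           NA_real_, ifelse(hi0, view$carried_c0, view$carried_c1))
  view$conf_low <- ifelse(!view$usable | view$carried_v0 == view$carried_v1,
                          NA_real_, ifelse(hi0, view$carried_c1, view$carried_c0))
  view$abs_dv <- ifelse(view$usable, abs(view$carried_v0 - view$carried_v1), NA_real_)
  view
}

#' Label objective accuracy
#'
#' A choice is objectively accurate when the chosen arm's running mean of all
#' outcomes observed so far is at least as high as the other arm's (ties
#' count as correct). Rows where either arm has no observed outcome yet are
#' NA.
#'
#' @param view A choice-trial view from [carry_forward()].
#' @return The view with an `accuracy` column (0/1/NA).
#' @export
label_objective_accuracy <- function(view) {
  ok <- view$run_n0 > 0L & view$run_n1 > 0L
  m_ch <- ifelse(view$arm == 0L, view$run_mean0, view$run_mean1)
  m_ot <- ifelse(view$arm == 0L, view$run_mean1, view$run_mean0)
  view$accuracy <- ifelse(ok, as.numeric(m_ch >= m_ot), NA_real_)
  view
}

#' Within-subject quantile bins
#'
#' Bins a series into `k` within-subject quantile bins, labelled 1 (lowest)
#' to `k`. Heavy ties that collapse cut points merge bins with a warning.
#'
#' @param x Numeric vector.
#' @param subject Grouping vector.
#' @param k Number of bins (default 5, i.e. quintiles).
#' @return Integer vector of bin labels (NA where `x` is NA).
#' @export
bin_quantiles <- function(x, subject, k = 5L) {
  stopifnot(length(x) == length(subject))
  out <- rep(NA_integer_, length(x))
  for (s in unique(subject)) {
    i <- which(subject == s & !is.na(x))
    if (length(i) < k) {
      warning(sprintf("bin_quantiles: subject '%s' has fewer than %d values; skipped", s, k))
      next
    }
    br <- stats::quantile(x[i], probs = seq(0, 1, length.out = k + 1L), names = FALSE)
    ubr <- unique(br)
    if (length(ubr) < length(br))
      warning(sprintf("bin_quantiles: ties merged bins for subject '%s'", s))
    if (length(ubr) < 2L) next
    out[i] <- as.integer(cut(x[i], breaks = ubr, include.lowest = TRUE, labels = FALSE))
  }
  out
}

#' Full choice-trial preprocessing
#'
#' Convenience wrapper: RT exclusion, carry-forward, exploration and
#' accuracy labels, and the log-RT column used by the confidence model.
#'
#' @param log A trial-log data frame.
#' @return A list with `view` (labelled choice-trial view), `log` (RT-filtered
#'   log), and `exclusions` (the RT exclusion report).
#' @export
preprocess_choices <- function(log) {
  ex <- exclude_rt_outliers(log)
  view <- label_objective_accuracy(label_exploration(carry_forward(ex$log)))
  view$log_rt <- log(view$rt_ms)
  list(view = view, log = ex$log, exclusions = ex$report)
}
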
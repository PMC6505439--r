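#' Build type-2 signal-detection counts for one subject
#'
#' Maps choice trials onto a 2 (stimulus) x 2 (response) x K (confidence
#' bin) count table for type-2 SDT analysis. The "stimulus" is the
#' objectively better arm on that trial (higher running mean of observed
#' outcomes; ties resolved toward the chosen arm, matching the accuracy
#' convention), the "response" is the chosen arm, and confidence is binned
#' into K within-subject quantile bins. If fewer than K distinct confidence
#' values exist, K is reduced with a warning.
#'
#' @param view A labelled choice-trial view for one subject
#'   ([preprocess_choices()]); rows with missing accuracy or confidence are
#'   dropped.
#' @param k Number of confidence bins (default 4: within-subject quartiles).
#' @return An object of class `type2_counts`: a list with `counts`
#'   (2 x 2 x K array, dimensions stimulus (S1/S2) x response (R1/R2) x bin
#'   (low..high)) and `k`.
#' @export
build_type2_counts <- function(view, k = 4L) {
  d <- view[!is.na(view$accuracy) & !is.na(view$decision_conf), , drop = FALSE]
  if (length(unique(d$subject)) > 1L)
    stop("build_type2_counts: expects a single subject's view")
  if (nrow(d) == 0L) stop("build_type2_counts: no usable choice trials")
  n_distinct <- length(unique(d$decision_conf))
  if (n_distinct < k) {
    warning(sprintf("build_type2_counts: only %d distinct confidence values; reducing K",
                    n_distinct))
    k <- max(n_distinct, 2L)
  }
  bins <- bin_quantiles(d$decision_conf, d$subject, k = k)
  k_eff <- max(bins, na.rm = TRUE)
  resp <- d$arm + 1L                       # R1 = chose arm0, R2 = chose arm1
  stim <- ifelse(d$accuracy == 1, resp, 3L - resp)  # better arm; ties -> chosen
  counts <- array(0L, dim = c(2L, 2L, k_eff),
                  dimnames = list(stimulus = c("S1", "S2"),
                                  response = c("R1", "R2"),
                                  bin = seq_len(k_eff)))
  for (i in seq_along(resp))
    counts[stim[i], resp[i], bins[i]] <- counts[stim[i], resp[i], bins[i]] + 1L
  structure(list(counts = counts, k = k_eff), class = "type2_counts")
}

#' Fit meta-d' by maximum likelihood
#'
#' Estimates type-1 sensitivity d' from the hit and false-alarm rates, then
#' finds the meta-d' of the equal-variance SDT observer whose
#' response-conditional confidence distributions best match the observed
#' type-2 counts, holding the type-1 criterion fixed at its empirical
#' relative position (criterion-ratio locking: the meta-level criterion is
#' `c * meta_d / d'`). Metacognitive efficiency is M-ratio = meta-d'/d'.
#' Cells are padded with `1/(2K)` before fitting to guard degenerate
#' margins; the flag is recorded.
#'
#' @param t2 A `type2_counts` object.
#' @param pad Add `1/(2K)` to every count cell (default TRUE).
#' @return An object of class `meta_result`: `d_prime`, `criterion`,
#'   `meta_d`, `m_ratio`, `log_m_ratio`, `k`, `padded`, `undefined` (TRUE
#'   when d' <= 0, in which case the ratio is not defined), and `nll`.
#' @export
fit_meta_d <- function(t2, pad = TRUE) {
  stopifnot(inherits(t2, "type2_counts"))
  k <- t2$k
  counts <- t2$counts + if (pad) 1 / (2 * k) else 0
  n_s1 <- sum(counts["S1", , ])
  n_s2 <- sum(counts["S2", , ])
  hr <- sum(counts["S2", "R2", ]) / n_s2
  far <- sum(counts["S1", "R2", ]) / n_s1
  d1 <- stats::qnorm(hr) - stats::qnorm(far)
  c1 <- -0.5 * (stats::qnorm(hr) + stats::qnorm(far))
  if (!is.finite(d1) || d1 <= 0) {
    return(structure(list(d_prime = d1, criterion = c1, meta_d = NA_real_,
                          m_ratio = NA_real_, log_m_ratio = NA_real_,
                          k = k, padded = pad, undefined = TRUE, nll = NA_real_),
                     class = "meta_result"))
  }
  c_rel <- c1 / d1
  # parameters: meta_d, then log-increments of the K-1 type-2 criteria on
  # each side of the (scaled) type-1 criterion
  nll_fun <- function(par) {
    md <- par[1L]
    cm <- c_rel * md
    t2c_r1 <- cm - rev(cumsum(exp(par[2:k])))          # below cm, ascending
    t2c_r2 <- cm + cumsum(exp(par[(k + 1):(2 * k - 1)]))  # above cm, ascending
    edges_r1 <- c(-Inf, t2c_r1, cm)   # K intervals for R1, low conf nearest cm
    edges_r2 <- c(cm, t2c_r2, Inf)    # K intervals for R2, low conf nearest cm
    nll <- 0
    for (s in 1:2) {
      mu <- if (s == 1L) -md / 2 else md / 2
      p_r1 <- stats::pnorm(cm, mu)
      p_r2 <- 1 - p_r1
      # R1: bins ordered high..low along x; reverse to low..high confidence
      pr1 <- rev(diff(stats::pnorm(edges_r1, mu)))
      pr2 <- diff(stats::pnorm(edges_r2, mu))
      pr1 <- pmax(pr1 / p_r1, 1e-10)
      pr2 <- pmax(pr2 / p_r2, 1e-10)
      nll <- nll - sum(counts[s, "R1", ] * log(pr1)) - sum(counts[s, "R2", ] * log(pr2))
    }
    if (!is.finite(nll)) 1e10 else nll  # overflowing criteria during search
  }
  start <- c(d1, rep(log(0.5), 2L * (k - 1L)))
  fit <- stats::optim(start, nll_fun, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
  fit2 <- try(stats::optim(fit$par, nll_fun, method = "BFGS",
                           control = list(maxit = 500)), silent = TRUE)
  if (!inherits(fit2, "try-error") && is.finite(fit2$value) && fit2$value < fit$value)
    fit <- fit2
  md <- fit$par[1L]
  mr <- md / d1
  structure(list(d_prime = d1, criterion = c1, meta_d = md,
                 m_ratio = mr,
                 # log M-ratio is undefined for non-positive ratios
                 log_m_ratio = if (mr > 0) log(mr) else NA_real_,
                 k = k, padded = pad, undefined = FALSE, nll = fit$value),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("d' = %.3f, meta-d' = %.3f, M-ratio = %.3f (K = %d%s)\n",
              x$d_prime, x$meta_d, x$m_ratio, x$k,
              if (x$undefined) ", undefined" else ""))
  invisible(x)
}

#' Per-subject metacognitive efficiency
#'
#' Builds type-2 counts and fits meta-d' for every subject in a labelled
#' choice-trial view.
#'
#' @param view A labelled choice-trial view (several subjects).
#' @param k Confidence bins per subject (default 4).
#' @return Data frame: subject, d_prime, meta_d, m_ratio, log_m_ratio, k,
#'   padded, undefined.
#' @export
subject_metacognition <- function(view, k = 4L) {
  subs <- unique(view$subject)
  out <- lapply(subs, function(s) {
    vs <- view[view$subject == s, , drop = FALSE]
    res <- try(fit_meta_d(build_type2_counts(vs, k = k)), silent = TRUE)
    if (inherits(res, "try-error"))
      return(data.frame(subject = s, d_prime = NA_real_, meta_d = NA_real_,
                        m_ratio = NA_real_, log_m_ratio = NA_real_,
                        k = NA_integer_, padded = NA, undefined = TRUE))
    data.frame(subject = s, d_prime = res$d_prime, meta_d = res$meta_d,
               m_ratio = res$m_ratio, log_m_ratio = res$log_m_ratio,
               k = res$k, padded = res$padded, undefined = res$undefined)
  })
  do.call(rbind, out)
}

#' Correlate uncertainty tracking with metacognitive efficiency
#'
#' Pearson correlation between each subject's belief-confidence sensitivity
#' to outcome variability (the per-subject `sig_past` slope from
#' [belief_confidence_model()]) and their log M-ratio. Subjects with an
#' undefined M-ratio are dropped.
#'
#' @param beta_sig Named numeric vector of per-subject `sig_past` slopes.
#' @param meta Data frame from [subject_metacognition()].
#' @return A `bm_stat` with r (as `statistic`), df, p, and n used.
#' @export
tracking_vs_efficiency <- function(beta_sig, meta) {
  m <- meta[!meta$undefined & is.finite(meta$log_m_ratio), , drop = FALSE]
  common <- intersect(names(beta_sig), m$subject)
  if (length(common) < 5L)
    stop("tracking_vs_efficiency: need at least 5 subjects with a defined M-ratio")
  x <- beta_sig[common]
  y <- m$log_m_ratio[match(common, m$subject)]
  ct <- stats::cor.test(x, y)
  structure(list(statistic = unname(ct$estimate), df = unname(ct$parameter),
                 p_value = ct$p.value, effect_size = unname(ct$estimate),
                 n = length(common), means = NULL),
            class = "bm_stat")
}
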
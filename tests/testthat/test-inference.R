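test_that("fit_hierarchical recovers a known fixed slope", {
  set.seed(2)
  n_subj <- 12; n_per <- 80
  d <- data.frame(subject = rep(sprintf("s%02d", 1:n_subj), each = n_per))
  d$x <- rnorm(nrow(d))
  d$y <- 0.5 * d$x + rnorm(nrow(d), 0, sqrt(1 - 0.25))
  fit <- fit_hierarchical(d, "y", "x", family = "linear")
  i <- match("x", fit$coefficients$term)
  expect_lt(abs(fit$coefficients$beta[i] - 0.5), 2 * fit$coefficients$se[i] + 0.02)
  expect_true(is.finite(fit$bic))
  expect_equal(fit$n_obs, nrow(d))
  expect_true(fit$structure %in% c("diag", "full"))
  # standardized coefficients are invariant to affine predictor rescaling
  d2 <- d
  d2$x <- 100 * d2$x + 7
  fit2 <- fit_hierarchical(d2, "y", "x", family = "linear")
  expect_equal(fit2$coefficients$beta[i], fit$coefficients$beta[i], tolerance = 1e-6)
  expect_error(fit_hierarchical(d, "y", "nope", family = "linear"), "missing column")
})

test_that("pure-noise outcomes give small coefficients and honest p-values", {
  set.seed(5)
  ps <- replicate(30, {
    d <- data.frame(subject = rep(sprintf("s%02d", 1:8), each = 40))
    d$x <- rnorm(nrow(d))
    d$y <- rnorm(nrow(d))
    fit <- fit_hierarchical(d, "y", "x", family = "linear", random = "intercept")
    fit$coefficients$p[match("x", fit$coefficients$term)]
  })
  expect_gt(mean(ps < 0.05), -0.001)  # guard against NA
  expect_lt(mean(ps < 0.05), 0.2)     # near-nominal type-I rate
  expect_gt(mean(ps), 0.3)            # p roughly uniform under the null
})

test_that("the two-stage fallback pools per-subject fits sensibly", {
  set.seed(3)
  d <- data.frame(subject = rep(c("a", "b", "c", "d"), each = 60))
  d$x <- rnorm(nrow(d))
  d$y <- 0.6 * d$x + rnorm(nrow(d), 0, 0.8)
  fit <- fit_hierarchical(d, "y", "x", family = "linear", random = "two_stage")
  i <- match("x", fit$coefficients$term)
  expect_lt(abs(fit$coefficients$beta[i] - 0.6 / sd(d$y)), 0.15)
  expect_equal(fit$structure, "two_stage")
  expect_true(is.na(fit$bic))
  expect_equal(nrow(fit$subject_coefs), 4L)
})

test_that("repeated-measures trend ANOVA matches an external oracle", {
  # 8 subjects x 5 bins; oracle values computed once with an independent
  # implementation of the GG-corrected RM-ANOVA and the per-subject linear
  # polynomial contrast
  Y <- matrix(c(-0.244873, -0.009007, 0.846151, 1.079674, 1.253937,
                -0.166488, 0.58412, 1.246397, 0.526638, 1.269938,
                -1.224749, -0.618907, -0.595005, 0.508317, 0.292139,
                -0.75496, -0.512216, -0.384057, -1.248972, 0.040062,
                -0.478921, -0.098016, -0.619739, 0.206453, 0.25607,
                -1.396065, -0.161197, -0.795414, -0.107907, 0.650548,
                -0.231657, 0.304293, 0.715376, 0.992034, 0.647616,
                1.378285, 2.319627, 1.166643, 2.669907, 2.599892),
              nrow = 8, byrow = TRUE)
  d <- data.frame(subject = rep(1:8, each = 5), bin = rep(1:5, 8),
                  y = as.vector(t(Y)))
  a <- quintile_trend_anova(d, "y", "bin")
  expect_equal(a$statistic, 10.432866, tolerance = 1e-5)
  expect_equal(a$epsilon, 0.648262, tolerance = 1e-5)
  expect_equal(a$p_value, 0.000485, tolerance = 1e-3)
  expect_equal(a$effect_size, 0.59846, tolerance = 1e-4)
  expect_equal(a$linear$statistic, 45.550979, tolerance = 1e-5)
  expect_equal(a$linear$p_value, 0.000265218, tolerance = 1e-5)
  # identical bin means (subject-only variance): F = 0
  d0 <- data.frame(subject = rep(1:6, each = 5), bin = rep(1:5, 6),
                   y = rep(c(1, 2, 3, 2.5, 0, 4), each = 5))
  a0 <- quintile_trend_anova(d0, "y", "bin")
  expect_equal(a0$statistic, 0)
  expect_equal(a0$linear$statistic, 0)
})

test_that("permuted bins give near-uniform GG-corrected p-values", {
  set.seed(11)
  ps <- replicate(60, {
    Y <- matrix(rnorm(8 * 5), 8, 5) + rnorm(8)
    d <- data.frame(subject = rep(1:8, each = 5), bin = rep(1:5, 8),
                    y = as.vector(t(Y)))
    quintile_trend_anova(d, "y", "bin")$p_value
  })
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.35)
})

test_that("estimation-error halves detect the simulator's learning", {
  # slow learner: value estimates converge over many trials, so first-half
  # errors against the running outcome mean clearly exceed second-half ones
  coh <- generate_cohort(cohort_spec(8, "exp1",
                                     base_params = agent_params("rl", learning_rate = 0.12),
                                     master_seed = 44))
  h <- halves_estimation_error(coh$log)
  expect_lt(h$means["second"], h$means["first"])
  expect_gt(h$statistic, 2)
  expect_false(h$degenerate)
  # degenerate case: a perfect rater with zero variance across subjects
  log <- random_mini_log(6)
  view_rows <- log$trial_type == "rating" & !is.na(log$outcome)
  d <- log
  # make every rating exactly equal to the running mean so both halves are 0
  res <- banditmeta:::rating_observer_table_any(d)
  for (i in seq_len(nrow(res)))
    d$value_rating[d$block == res$block[i] & d$trial == res$trial[i] &
                     d$trial_type == "rating"] <- res$mu_past[i]
  h0 <- halves_estimation_error(d)
  expect_true(h0$degenerate)
  expect_equal(unname(h0$means), c(0, 0))
})

test_that("update size and confidence change correlate as constructed", {
  # deterministic anti-monotone toy: each block has one calibration rating
  # (confidence 1) followed by one surprising outcome whose confidence drop
  # is exactly linear in the surprise, so the pooled correlation is -1
  second_outcomes <- c(80, 55, 90, 52, 95, 60)
  blocks <- lapply(seq_along(second_outcomes), function(b) {
    x <- second_outcomes[b]
    data.frame(subject = "s01", block = b, trial = 1:2, trial_type = "rating",
               arm = 0L, outcome = c(50, x), value_rating = 50,
               belief_conf = c(1, 1 - 0.005 * abs(x - 50)),
               value_rating_other = NA_real_, belief_conf_other = NA_real_,
               decision_conf = NA_real_, rt_ms = NA_real_)
  })
  r <- update_vs_confidence_correlation(do.call(rbind, blocks))
  expect_equal(nrow(r), 1L)
  expect_equal(r$r, -1, tolerance = 1e-12)
  # confidence independent of updates: r centred on zero across subjects
  set.seed(13)
  toy <- do.call(rbind, blocks)
  logs <- lapply(1:10, function(k) {
    l <- toy
    l$subject <- sprintf("s%02d", k)
    l$belief_conf <- round(runif(nrow(l)), 3)
    l
  })
  rs <- update_vs_confidence_correlation(do.call(rbind, logs))
  expect_lt(abs(mean(rs$r)), 0.45)
  # an RL-confidence cohort shows mostly negative correlations
  coh <- small_exp1_cohort()
  rc <- update_vs_confidence_correlation(coh$log)
  expect_gt(mean(rc$r < 0), 0.8)
})

test_that("the belief-confidence model tracks normative uncertainty", {
  coh <- generate_cohort(cohort_spec(8, "exp2", model_mix = c(ideal = 1),
                                     base_params = agent_params("ideal"),
                                     master_seed = 55))
  res <- belief_confidence_model(coh$log)
  b_sig <- res$coefficients$beta[match("sig_past", res$coefficients$term)]
  b_mu <- res$coefficients$beta[match("mu_past", res$coefficients$term)]
  expect_lt(b_sig, 0)
  expect_gt(abs(b_sig), abs(b_mu))
  expect_equal(length(res$beta_sig_subject), 8L)
  # confidence unrelated to outcomes: coefficients near zero
  log2 <- coh$log
  set.seed(9)
  ridx <- log2$trial_type == "rating"
  log2$belief_conf[ridx] <- round(runif(sum(ridx), 0.3, 0.9), 3)
  o2 <- !is.na(log2$belief_conf_other)
  log2$belief_conf_other[o2] <- round(runif(sum(o2), 0.3, 0.9), 3)
  res2 <- belief_confidence_model(log2)
  b2 <- res2$coefficients$beta[match(c("sig_past", "mu_past"), res2$coefficients$term)]
  expect_true(all(abs(b2) < 0.08))
})
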
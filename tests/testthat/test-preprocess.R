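test_that("RT exclusion removes exactly the injected outlier, never ratings", {
  log <- random_mini_log(3, n_blocks = 3L, len = 20L)
  choice_idx <- which(log$trial_type == "choice")
  # identical RTs: zero exclusions under the SD = 0 edge rule
  log0 <- log
  log0$rt_ms[choice_idx] <- 800
  ex0 <- exclude_rt_outliers(log0)
  expect_equal(nrow(ex0$log), nrow(log0))
  expect_equal(ex0$report$n_excluded, 0L)
  # one RT at mean + 10 SD: exactly that row removed
  log1 <- log
  rt <- log1$rt_ms[choice_idx]
  log1$rt_ms[choice_idx[5L]] <- mean(rt[-5L]) + 10 * sd(rt[-5L])
  ex1 <- exclude_rt_outliers(log1)
  expect_equal(nrow(ex1$log), nrow(log1) - 1L)
  expect_false(choice_idx[5L] %in% which(rownames(log1) %in% rownames(ex1$log)))
  expect_equal(sum(ex1$log$trial_type == "rating"), sum(log1$trial_type == "rating"))
  expect_equal(ex1$report$n_excluded, 1L)
  expect_equal(ex1$report$fraction, 1 / length(choice_idx))
  # row count conservation
  expect_equal(nrow(ex1$log) + sum(ex1$report$n_excluded), nrow(log1))
})

test_that("within-subject z-scoring uses the population SD per subject", {
  z <- zscore_within_subject(c(1, 2, 3), rep("a", 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)  # 1.2247...
  expect_warning(zc <- zscore_within_subject(rep(4, 5), rep("a", 5)), "zero variance")
  expect_equal(zc, rep(0, 5))
  # subjects standardized independently
  x <- c(1, 2, 3, 10, 20, 30)
  s <- rep(c("a", "b"), each = 3)
  z2 <- zscore_within_subject(x, s)
  expect_equal(z2[1:3], z2[4:6])
  # missing values propagate
  expect_true(is.na(zscore_within_subject(c(1, NA, 3, 5), rep("a", 4))[2L]))
})

test_that("carry-forward propagates the latest ratings and resets at blocks", {
  log <- data.frame(
    subject = "s01", block = c(1, 1, 1, 2, 2),
    trial = c(1, 2, 3, 1, 2),
    trial_type = c("rating", "choice", "choice", "choice", "rating"),
    arm = c(0L, 0L, 1L, 0L, 1L),
    outcome = c(40, 35, 60, 20, NA),
    value_rating = c(30, NA, NA, NA, 55),
    belief_conf = c(0.8, NA, NA, NA, 0.6),
    value_rating_other = NA_real_, belief_conf_other = NA_real_,
    decision_conf = c(NA, 0.7, 0.6, 0.5, NA),
    rt_ms = c(NA, 800, 900, 850, NA))
  view <- carry_forward(log)
  expect_equal(view$carried_v0, c(30, 30, NA))
  expect_equal(view$carried_c0, c(0.8, 0.8, NA))
  expect_true(all(is.na(view$carried_v1)))   # arm 1 never rated before a choice
  expect_false(any(view$usable))
  # running outcome means are causal (exclude the current trial's outcome)
  expect_equal(view$run_mean0, c(40, 37.5, NA))
  expect_equal(view$run_n1, c(0L, 0L, 0L))
  # idempotence: same view when recomputed
  expect_identical(view, carry_forward(log))
})

test_that("exploration labels use a strict inequality with ties excluded", {
  base <- data.frame(
    subject = "s01", block = 1, trial = 1:4,
    trial_type = c("rating", "rating", "choice", "choice"),
    arm = c(0L, 1L, 0L, 1L),
    outcome = c(40, 60, 35, 65),
    value_rating = c(30, 60, NA, NA), belief_conf = c(0.8, 0.5, NA, NA),
    value_rating_other = NA_real_, belief_conf_other = NA_real_,
    decision_conf = c(NA, NA, 0.7, 0.6), rt_ms = c(NA, NA, 800, 900))
  v <- label_exploration(carry_forward(base))
  expect_equal(v$explore, c(1, 0))       # chose 30-arm, then 60-arm
  expect_equal(v$conf_high, c(0.5, 0.5)) # confidence of the higher-rated arm
  expect_equal(v$abs_dv, c(30, 30))
  tie <- base
  tie$value_rating <- c(50, 50, NA, NA)
  vt <- label_exploration(carry_forward(tie))
  expect_true(all(is.na(vt$explore)))
})

test_that("objective accuracy compares running outcome means, ties correct", {
  log <- random_mini_log(4, n_blocks = 1L, len = 20L)
  v <- label_objective_accuracy(carry_forward(log))
  ref <- brute_force_view(log)
  expect_equal(v$accuracy, ref$accuracy)
  # before any outcome on one arm the row is unusable
  first_choice <- which(log$trial_type == "choice")[1L]
  if (first_choice == 1L) expect_true(is.na(v$accuracy[1L]))
})

test_that("labels match a brute-force reference on random logs", {
  for (seed in 1:40) {
    log <- random_mini_log(seed, exp2 = seed %% 2 == 0)
    v <- label_objective_accuracy(label_exploration(carry_forward(log)))
    ref <- brute_force_view(log)
    expect_equal(v$carried_v0, ref$carried_v0)
    expect_equal(v$carried_v1, ref$carried_v1)
    expect_equal(v$carried_c0, ref$carried_c0)
    expect_equal(v$explore, ref$explore)
    expect_equal(v$accuracy, ref$accuracy)
  }
})

test_that("quantile bins are balanced and subject-local", {
  x <- c(seq_len(100), seq(1000, 1990, by = 10))
  s <- rep(c("a", "b"), each = 100)
  bins <- bin_quantiles(x, s, k = 5L)
  expect_equal(as.integer(table(bins[s == "a"])), rep(20L, 5))
  expect_equal(bins[s == "a"], bins[s == "b"])  # same ranks, different scales
  expect_true(all(bins[order(x[s == "a"])][1:20] == 1L, na.rm = TRUE))
  expect_warning(bin_quantiles(rep(1, 10), rep("a", 10), k = 5L), "ties")
})
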
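test_that("ideal-observer updates track running mean and sample SD", {
  p <- agent_params("ideal")
  st <- belief_state(p)
  for (x in c(50, 50, 50)) st <- update_ideal(st, 0L, x)
  expect_equal(st$est_value[1L], 50)
  expect_equal(st$est_sd[1L], 0)
  st2 <- belief_state(p)
  st2 <- update_ideal(st2, 1L, 0)
  st2 <- update_ideal(st2, 1L, 100)
  expect_equal(st2$est_value[2L], 50)
  expect_equal(st2$est_sd[2L], sd(c(0, 100)))  # ~70.71
  # adding an outcome equal to the mean cannot increase the dispersion
  before <- st2$est_sd[2L]
  st2 <- update_ideal(st2, 1L, st2$est_value[2L])
  expect_lte(st2$est_sd[2L], before)
})

test_that("delta-rule updates move value by lr * prediction error", {
  p <- agent_params("rl", learning_rate = 0.5)
  st <- belief_state(p)
  st <- update_rl(st, 0L, 100, p)
  expect_equal(st$est_value[1L], 75)  # 50 + 0.5 * 50
  # zero prediction error shrinks the dispersion toward zero
  st2 <- belief_state(p)
  sds <- numeric(10)
  for (i in 1:10) {
    st2 <- update_rl(st2, 0L, 50, p)
    sds[i] <- st2$est_sd[1L]
  }
  expect_equal(st2$est_value[1L], 50)
  expect_true(all(diff(sds) < 0))
  expect_lt(sds[10L], 0.1)
  expect_error(update_rl(st, 0L, 50, agent_params("rl", learning_rate = 1.5)),
               "learning_rate")
})

test_that("particle posterior concentrates on repeated evidence", {
  p <- agent_params("particle")
  st <- belief_state(p)
  expect_equal(st$est_value[1L], 50, tolerance = 1e-6)  # symmetric prior
  sds <- numeric(20)
  for (i in 1:20) {
    st <- update_particle(st, 0L, 70, p)
    sds[i] <- st$est_sd[1L]
  }
  expect_lt(abs(st$est_value[1L] - 70), 3)
  expect_true(all(diff(sds) < 1e-9))  # posterior contraction on constant data
  expect_true(all(abs(colSums(exp(st$log_w)) - 1) < 1e-9))
})

test_that("rating readout is a monotone map of dispersion, clipped", {
  p <- agent_params("rl", rating_noise_sd = 0, confidence_noise_sd = 0)
  st <- belief_state(p)
  st$est_value[1L] <- 50
  st$est_sd[1L] <- 0
  r <- readout_rating(st, 0L, p)
  expect_equal(r$value_rating, 50)
  expect_equal(r$belief_confidence, 1)
  confs <- sapply(c(5, 10, 20, 30), function(s) {
    st$est_sd[1L] <- s
    readout_rating(st, 0L, p)$belief_confidence
  })
  expect_true(all(diff(confs) < 0))
})

test_that("the choice policy has the right limits and monotonicity", {
  p0 <- agent_params("rl", inverse_temperature = 0, uncertainty_bonus = 0)
  st <- belief_state(p0)
  st$est_value <- c(40, 60)
  expect_equal(banditmeta:::explore_probability(st, p0), 0.5)
  # P(explore) strictly increases as confidence in the better arm drops
  p1 <- agent_params("rl", uncertainty_bonus = 1)
  probs <- sapply(c(5, 15, 25), function(s) {
    st$est_sd <- c(10, s)
    banditmeta:::explore_probability(st, p1)
  })
  expect_true(all(diff(probs) > 0))
  # infinite value sensitivity: exploration vanishes
  p_inf <- agent_params("rl", inverse_temperature = 1e6, uncertainty_bonus = 0)
  st$est_sd <- c(10, 10)
  expect_lt(banditmeta:::explore_probability(st, p_inf), 1e-10)
})

test_that("decision confidence follows the value/confidence sign pattern", {
  p <- agent_params("rl")
  st <- belief_state(p)
  st$est_value <- c(60, 40)
  st$est_sd <- c(10, 10)
  base <- readout_decision_confidence(st, 0L, p, noiseless = TRUE)
  # raising the unchosen arm's value lowers decision confidence
  st$est_value[2L] <- 55
  expect_lt(readout_decision_confidence(st, 0L, p, noiseless = TRUE), base)
  st$est_value[2L] <- 40
  # raising the unchosen arm's belief confidence (lower dispersion) raises it
  st$est_sd[2L] <- 2
  expect_gt(readout_decision_confidence(st, 0L, p, noiseless = TRUE), base)
  # symmetric beliefs sit at the map's baseline
  st$est_value <- c(50, 50); st$est_sd <- c(10, 10)
  b1 <- readout_decision_confidence(st, 0L, p, noiseless = TRUE)
  b2 <- readout_decision_confidence(st, 1L, p, noiseless = TRUE)
  expect_equal(b1, b2)
})

test_that("simulated logs satisfy the design contracts and are deterministic", {
  p <- agent_params()
  s1 <- simulate_subject(experiment_config("exp1", seed = 6), p, seed = 7)
  s2 <- simulate_subject(experiment_config("exp1", seed = 6), p, seed = 7)
  expect_identical(s1$log, s2$log)
  rating <- s1$log[s1$log$trial_type == "rating", ]
  choice <- s1$log[s1$log$trial_type == "choice", ]
  expect_true(all(!is.na(rating$value_rating) & !is.na(rating$belief_conf)))
  expect_true(all(is.na(rating$decision_conf)))
  expect_true(all(is.na(rating$value_rating_other)))  # one arm rated
  expect_true(all(!is.na(rating$outcome)))            # outcome shown
  expect_true(all(!is.na(choice$decision_conf) & !is.na(choice$rt_ms)))
  expect_true(all(s1$log$value_rating >= 0 & s1$log$value_rating <= 100, na.rm = TRUE))
  s3 <- simulate_subject(experiment_config("exp2", seed = 6), p, seed = 7)
  rating2 <- s3$log[s3$log$trial_type == "rating", ]
  expect_true(all(!is.na(rating2$value_rating_other)))  # both arms rated
  expect_true(all(is.na(rating2$outcome)))              # no outcome shown
})

test_that("ideal-agent belief confidence rises across trial quintiles", {
  p <- agent_params("ideal", confidence_noise_sd = 0.01)
  sim <- simulate_subject(experiment_config("exp1", seed = 8), p, seed = 9)
  r <- sim$log[sim$log$trial_type == "rating", ]
  len <- aggregate(trial ~ block, sim$log, max)
  names(len)[2L] <- "len"
  r <- merge(r, len)
  q <- ceiling(5 * r$trial / r$len)
  means <- tapply(r$belief_conf, q, mean)
  expect_true(all(diff(means) > 0))
})

test_that("simulated exploration rate increases with the uncertainty bonus", {
  rates <- sapply(c(0, 0.75, 1.5), function(bn) {
    p <- agent_params("rl", uncertainty_bonus = bn)
    logs <- lapply(1:4, function(k)
      simulate_subject(experiment_config("exp2", seed = 30 + k), p, seed = 50 + k)$log)
    view <- label_exploration(carry_forward(do.call(rbind, logs)))
    mean(view$explore, na.rm = TRUE)
  })
  expect_true(all(diff(rates) > 0))
})

test_that("the compiled filter reproduces the R agents' latent trajectories", {
  for (m in c("ideal", "rl", "particle")) {
    p <- agent_params(m)
    sim <- simulate_subject(experiment_config("exp1", seed = 11), p, seed = 12)
    fd <- banditmeta:::prepare_fit_data(sim$log, "exp1")
    traj <- banditmeta:::.bm_traj_cpp(fd$block, fd$is_choice, fd$arm, fd$outcome,
                                      fd$design, banditmeta:::model_code(m),
                                      banditmeta:::params_to_vector(p),
                                      p$n_particles)
    expect_equal(traj[, "est_value0"], sim$truth$est_value0, tolerance = 1e-8)
    expect_equal(traj[, "est_sd0"], sim$truth$est_sd0, tolerance = 1e-8)
    expect_equal(traj[, "est_value1"], sim$truth$est_value1, tolerance = 1e-8)
  }
})
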
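# Independent brute-force reference implementations used to cross-check the
# preprocessing module, plus small random-log generators (deliberately not
# built on the package's simulator).

# Random but structurally valid trial log: a few short blocks, random
# ratings/choices/outcomes. Exercises carry-forward, exploration and
# accuracy labelling including ties and missing-rating edge cases.
random_mini_log <- function(seed, n_blocks = 2L, len = 15L, exp2 = FALSE) {
  set.seed(seed)
  rows <- list()
  for (b in seq_len(n_blocks)) {
    for (t in seq_len(len)) {
      is_rating <- runif(1) < 0.4
      arm <- sample(c(0L, 1L), 1L)
      if (is_rating) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = "s01", block = b, trial = t, trial_type = "rating", arm = arm,
          outcome = if (exp2) NA_real_ else round(runif(1, 0, 100)),
          value_rating = sample(c(30, 50, 70), 1L),  # coarse grid to force ties
          belief_conf = round(runif(1), 3),
          value_rating_other = if (exp2) sample(c(30, 50, 70), 1L) else NA_real_,
          belief_conf_other = if (exp2) round(runif(1), 3) else NA_real_,
          decision_conf = NA_real_, rt_ms = NA_real_)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = "s01", block = b, trial = t, trial_type = "choice", arm = arm,
          outcome = round(runif(1, 0, 100)), value_rating = NA_real_,
          belief_conf = NA_real_, value_rating_other = NA_real_,
          belief_conf_other = NA_real_, decision_conf = round(runif(1), 3),
          rt_ms = round(runif(1, 400, 1500), 1))
      }
    }
  }
  do.call(rbind, rows)
}

# O(n^2) reference: for each choice row, scan backwards within the block for
# each arm's most recent rating and count outcomes observed strictly before.
brute_force_view <- function(log) {
  out <- list()
  for (i in seq_len(nrow(log))) {
    if (log$trial_type[i] != "choice") next
    v <- c(NA_real_, NA_real_); cc <- c(NA_real_, NA_real_)
    for (j in rev(seq_len(i - 1L))) {
      if (log$subject[j] != log$subject[i] || log$block[j] != log$block[i]) break
      if (log$trial_type[j] == "rating") {
        a <- log$arm[j] + 1L
        if (is.na(v[a])) { v[a] <- log$value_rating[j]; cc[a] <- log$belief_conf[j] }
        if (!is.na(log$value_rating_other[j]) && is.na(v[3L - a])) {
          v[3L - a] <- log$value_rating_other[j]
          cc[3L - a] <- log$belief_conf_other[j]
        }
      }
      if (!is.na(v[1L]) && !is.na(v[2L])) break
    }
    sums <- c(0, 0); ns <- c(0L, 0L)
    for (j in seq_len(i - 1L)) {
      if (log$subject[j] != log$subject[i] || log$block[j] != log$block[i]) next
      if (!is.na(log$outcome[j])) {
        a <- log$arm[j] + 1L
        sums[a] <- sums[a] + log$outcome[j]
        ns[a] <- ns[a] + 1L
      }
    }
    ch <- log$arm[i] + 1L
    explore <- if (any(is.na(v)) || v[1L] == v[2L]) NA_real_ else
      as.numeric(v[ch] < v[3L - ch])
    acc <- if (any(ns == 0L)) NA_real_ else
      as.numeric(sums[ch] / ns[ch] >= sums[3L - ch] / ns[3L - ch])
    out[[length(out) + 1L]] <- data.frame(
      row = i, carried_v0 = v[1L], carried_c0 = cc[1L],
      carried_v1 = v[2L], carried_c1 = cc[2L], explore = explore, accuracy = acc)
  }
  do.call(rbind, out)
}

# A tiny default exp1 cohort reused by several tests.
small_exp1_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_spec(6, "exp1", master_seed = 101))
    cache
  }
})
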
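#' Bandit arm specification
#'
#' A single arm of the two-armed bandit pays out `100 * Beta(alpha, beta)`
#' points, so every reward is bounded between 0 and 100.
#'
#' @param alpha,beta_ Positive shape parameters of the beta distribution.
#' @param scale Points multiplier (fixed at 100 for this task).
#' @return An object of class `arm_spec`.
#' @export
#' @examples
#' arm <- arm_spec(3, 3)
#' mean(sample_reward(arm, 1000))  # close to 50
arm_spec <- function(alpha, beta_, scale = 100) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("arm_spec: 'alpha' must be a positive number")
  if (!is.numeric(beta_) || length(beta_) != 1L || !is.finite(beta_) || beta_ <= 0)
    stop("arm_spec: 'beta_' must be a positive number")
  structure(list(alpha = alpha, beta_ = beta_, scale = scale), class = "arm_spec")
}

#' The five canonical reward distributions
#'
#' The task draws each block's two arms from five fixed beta distributions,
#' (1,3), (2,3), (3,3), (3,2), (3,1): different skews, all unimodal, with
#' means 25, 40, 50, 60, 75 points.
#'
#' @return A list of five `arm_spec` objects.
#' @export
standard_arm_set <- function() {
  list(arm_spec(1, 3), arm_spec(2, 3), arm_spec(3, 3), arm_spec(3, 2), arm_spec(3, 1))
}

#' Sample rewards from a bandit arm
#'
#' @param arm An `arm_spec`.
#' @param n Number of draws.
#' @return Numeric vector of rewards in `[0, 100]`, rounded to whole points
#'   (the on-screen currency of the task).
#' @export
sample_reward <- function(arm, n = 1L) {
  stopifnot(inherits(arm, "arm_spec"))
  round(arm$scale * stats::rbeta(n, arm$alpha, arm$beta_))
}

#' Experiment configuration
#'
#' The two designs differ only in the trial-type mix and what rating trials
#' show: the rating-heavy design (`exp1`, 75% rating trials) reveals an
#' outcome from one random arm before the rating; the choice-heavy design
#' (`exp2`, 25% rating trials) shows no outcome on rating trials but asks for
#' ratings of both arms.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param total_trials Total trials per subject (default 600).
#' @param p_rating Proportion of rating trials; defaults to 0.75 (`exp1`) or
#'   0.25 (`exp2`).
#' @param seed Integer seed; the same seed yields the same block structure,
#'   trial-type sequence and pre-generated outcomes for every subject.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(design = c("exp1", "exp2"), total_trials = 600L,
                              p_rating = NULL, seed = 1L) {
  design <- match.arg(design)
  if (is.null(p_rating)) p_rating <- if (design == "exp1") 0.75 else 0.25
  if (!is.numeric(p_rating) || p_rating < 0 || p_rating > 1)
    stop("experiment_config: 'p_rating' must lie in [0, 1]")
  total_trials <- as.integer(total_trials)
  if (total_trials < 20L)
    stop("experiment_config: 'total_trials' cannot be partitioned into blocks of 20-60 trials")
  structure(list(design = design, total_trials = total_trials,
                 p_rating = p_rating,
                 rating_shows_outcome = design == "exp1",
                 rating_rates_both_arms = design == "exp2",
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Partition n trials into block lengths, each in [20, 60].
partition_blocks <- function(n) {
  lens <- integer(0)
  remaining <- n
  while (remaining > 60L) {
    l <- sample(20:60, 1L)
    if (remaining - l < 20L && remaining - l > 0L) next
    lens <- c(lens, l)
    remaining <- remaining - l
  }
  if (remaining > 0L) {
    if (remaining >= 20L) {
      lens <- c(lens, remaining)
    } else if (length(lens) > 0L) {
      # fold the leftover into the last block, splitting if that exceeds 60
      r <- lens[length(lens)] + remaining
      lens <- lens[-length(lens)]
      if (r <= 60L) lens <- c(lens, r) else lens <- c(lens, r %/% 2L, r - r %/% 2L)
    } else stop("partition_blocks: total trials not reachable with block lengths 20-60")
  }
  if (any(lens < 20L | lens > 60L) || sum(lens) != n)
    stop("partition_blocks: total trials not reachable with block lengths 20-60")
  lens
}

#' Build an experiment schedule
#'
#' Generates the blocked trial schedule shared by every subject: block
#' lengths drawn uniformly from 20-60 trials (the final remainder adjusted so
#' lengths stay in range and sum exactly to `total_trials`), two of the five
#' canonical beta distributions per block (without replacement within a
#' block), i.i.d. Bernoulli trial types, a uniformly chosen first-rated arm
#' for each rating trial, and pre-generated outcomes for both arms on every
#' trial so that all subjects face identical gambles.
#'
#' @param config An `experiment_config`.
#' @return An object of class `experiment_schedule`: a list with `schedule`
#'   (one row per trial: `block`, `trial` (within block), `trial_type`,
#'   `rating_arm`, `outcome0`, `outcome1`), `blocks` (per-block arm shape
#'   parameters and lengths), and the `config`.
#' @export
build_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  lens <- partition_blocks(config$total_trials)
  arm_set <- standard_arm_set()
  blocks <- data.frame(block = seq_along(lens), length = lens,
                       alpha0 = NA_real_, beta0 = NA_real_,
                       alpha1 = NA_real_, beta1 = NA_real_)
  rows <- vector("list", length(lens))
  for (b in seq_along(lens)) {
    pair <- sample.int(5L, 2L)  # without replacement
    a0 <- arm_set[[pair[1L]]]; a1 <- arm_set[[pair[2L]]]
    blocks$alpha0[b] <- a0$alpha; blocks$beta0[b] <- a0$beta_
    blocks$alpha1[b] <- a1$alpha; blocks$beta1[b] <- a1$beta_
    nb <- lens[b]
    rows[[b]] <- data.frame(
      block = b,
      trial = seq_len(nb),
      trial_type = ifelse(stats::runif(nb) < config$p_rating, "rating", "choice"),
      rating_arm = sample(c(0L, 1L), nb, replace = TRUE),
      outcome0 = sample_reward(a0, nb),
      outcome1 = sample_reward(a1, nb))
  }
  schedule <- do.call(rbind, rows)
  structure(list(schedule = schedule, blocks = blocks, config = config),
            class = "experiment_schedule")
}

trial_log_columns <- c("subject", "block", "trial", "trial_type", "arm",
                       "outcome", "value_rating", "belief_conf",
                       "value_rating_other", "belief_conf_other",
                       "decision_conf", "rt_ms")

empty_trial_log <- function() {
  data.frame(subject = character(0), block = integer(0), trial = integer(0),
             trial_type = character(0), arm = integer(0), outcome = numeric(0),
             value_rating = numeric(0), belief_conf = numeric(0),
             value_rating_other = numeric(0), belief_conf_other = numeric(0),
             decision_conf = numeric(0), rt_ms = numeric(0),
             stringsAsFactors = FALSE)
}

validate_trial_log <- function(log, where = "trial log") {
  missing_cols <- setdiff(trial_log_columns, names(log))
  if (length(missing_cols))
    stop(sprintf("%s: missing mandatory column(s): %s", where,
                 paste(missing_cols, collapse = ", ")))
  # vectorized checks; the first violating row is reported with its file line
  # number (+1 for the header)
  first_bad <- function(bad, msg) {
    i <- which(bad)
    if (length(i)) stop(sprintf("%s: line %d: %s", where, i[1L] + 1L, msg))
  }
  out01 <- function(x) !is.na(x) & (x < 0 | x > 1)
  out0100 <- function(x) !is.na(x) & (x < 0 | x > 100)
  is_rating <- log$trial_type == "rating"
  first_bad(is.na(log$trial_type) | !(log$trial_type %in% c("rating", "choice")),
            "trial_type must be 'rating' or 'choice'")
  first_bad(is.na(log$arm) | !(log$arm %in% c(0L, 1L)), "arm must be 0 or 1")
  first_bad(out0100(log$outcome), "outcome outside [0, 100]")
  first_bad(out0100(log$value_rating), "value_rating outside [0, 100]")
  first_bad(out0100(log$value_rating_other), "value_rating_other outside [0, 100]")
  first_bad(out01(log$belief_conf), "belief_conf outside [0, 1]")
  first_bad(out01(log$belief_conf_other), "belief_conf_other outside [0, 1]")
  first_bad(out01(log$decision_conf), "decision_conf outside [0, 1]")
  first_bad(!is.na(log$rt_ms) & log$rt_ms <= 0, "rt_ms must be positive")
  first_bad(is_rating & (is.na(log$value_rating) | is.na(log$belief_conf)),
            "rating row lacks value_rating or belief_conf")
  first_bad(is_rating & !is.na(log$decision_conf), "rating row carries decision_conf")
  first_bad(!is_rating & is.na(log$decision_conf), "choice row lacks decision_conf")
  first_bad(!is_rating & !is.na(log$value_rating), "choice row carries value_rating")
  invisible(log)
}

#' Write a trial log to CSV
#'
#' The on-disk format is a plain UTF-8 CSV with the fixed header
#' `subject,block,trial,trial_type,arm,outcome,value_rating,belief_conf,`
#' `value_rating_other,belief_conf_other,decision_conf,rt_ms`; absent fields
#' are empty cells.
#'
#' @param log A trial-log data frame (see [read_trial_log()]).
#' @param path Output file path.
#' @export
write_trial_log <- function(log, path) {
  validate_trial_log(log, where = "write_trial_log")
  out <- log[, trial_log_columns]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Parse a plain-text key = value column-mapping file (standard_name = file_name).
read_column_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[:=]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop(sprintf("column map '%s': malformed line '%s'", path, lines[bad][1L]))
  stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
}

#' Read a trial log from CSV
#'
#' Reads and validates a trial log. Each row is one trial: rating rows must
#' carry `value_rating` and `belief_conf` (and, for designs that rate both
#' arms, the `_other` columns) and no `decision_conf`; choice rows carry
#' `decision_conf` and no `value_rating`. Malformed rows raise an error
#' naming the offending line.
#'
#' @param path CSV file path.
#' @param col_map Optional mapping from the standard column names to the
#'   file's column names: a named character vector
#'   (`c(value_rating = "rating")`) or the path of a plain-text `key = value`
#'   file. Unmapped standard columns absent from the file are filled with NA.
#' @return A validated trial-log data frame.
#' @export
read_trial_log <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    if (is.character(col_map) && is.null(names(col_map)) && length(col_map) == 1L)
      col_map <- read_column_map(col_map)
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(df))
        stop(sprintf("read_trial_log: mapped column '%s' not found in '%s'", src, path))
      df[[std]] <- df[[src]]
    }
  }
  structural <- c("subject", "block", "trial", "trial_type", "arm")
  absent <- setdiff(structural, names(df))
  if (length(absent))
    stop(sprintf("read_trial_log('%s'): missing mandatory column(s): %s", path,
                 paste(absent, collapse = ", ")))
  for (col in trial_log_columns) if (!col %in% names(df)) df[[col]] <- NA
  df <- df[, trial_log_columns]
  df$subject <- as.character(df$subject)
  df$block <- as.integer(df$block)
  df$trial <- as.integer(df$trial)
  df$trial_type <- as.character(df$trial_type)
  df$arm <- as.integer(df$arm)
  for (col in c("outcome", "value_rating", "belief_conf", "value_rating_other",
                "belief_conf_other", "decision_conf", "rt_ms"))
    df[[col]] <- as.numeric(df[[col]])
  validate_trial_log(df, where = sprintf("read_trial_log('%s')", path))
  df
}
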
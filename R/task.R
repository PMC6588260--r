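#' Build a block schedule for the two-armed bandit task
#'
#' The task is divided into blocks; within each block one action ("better"
#' side) has a higher reward probability than the other, whose probability is
#' fixed at a low baseline. Each (better probability, better side) pair is
#' repeated `repeats` times and the resulting blocks are shuffled uniformly
#' under `seed`. The default arguments give the standard 12-block layout:
#' better probabilities {0.25, 0.125, 0.08} against a 0.05 baseline, each
#' pair appearing once with L better and once with R better, twice over.
#'
#' @param better_probs probabilities of reward on the better action.
#' @param baseline_prob reward probability of the other action (default 0.05).
#' @param repeats how many times each (probability, side) pair appears.
#' @param trials_per_block either a single integer (default 110, matching the
#'   average of roughly 110 self-paced trials per 40-s block), an integer
#'   vector with one entry per block, or a function `f(n_blocks)` returning
#'   such a vector (a seeded sampler).
#' @param seed integer seed controlling the block order (and the sampler, if
#'   `trials_per_block` is a function). `NULL` leaves the global RNG in charge.
#' @return A `bandit_schedule`: a data frame with columns `block`, `p_left`,
#'   `p_right`, `n_trials`.
#' @examples
#' sched <- build_schedule(seed = 1)
#' nrow(sched)   # 12
#' @export
build_schedule <- function(better_probs = c(0.25, 0.125, 0.08),
                           baseline_prob = 0.05,
                           repeats = 2L,
                           trials_per_block = 110L,
                           seed = NULL) {
  if (length(better_probs) < 1) stop("better_probs must be non-empty")
  check_prob(better_probs, "better_probs")
  check_prob(baseline_prob, "baseline_prob")
  if (repeats < 1) stop("repeats must be >= 1")

  # one block per (probability, side, repeat)
  grid <- expand.grid(p = better_probs, side = c("L", "R"),
                      rep = seq_len(repeats), stringsAsFactors = FALSE)
  n_blocks <- nrow(grid)

  with_seed(seed, {
    ord <- sample.int(n_blocks)
    grid <- grid[ord, , drop = FALSE]
    nt <- if (is.function(trials_per_block)) {
      as.integer(trials_per_block(n_blocks))
    } else if (length(trials_per_block) == 1L) {
      rep(as.integer(trials_per_block), n_blocks)
    } else {
      as.integer(trials_per_block)
    }
    if (length(nt) != n_blocks || any(nt < 1)) {
      stop("trials_per_block must yield one count >= 1 per block")
    }
    sched <- data.frame(
      block = seq_len(n_blocks),
      p_left = ifelse(grid$side == "L", grid$p, baseline_prob),
      p_right = ifelse(grid$side == "R", grid$p, baseline_prob),
      n_trials = nt
    )
    class(sched) <- c("bandit_schedule", "data.frame")
    sched
  })
}

#' Draw a reward from the schedule
#'
#' Returns 1 with the probability the current block assigns to the chosen
#' action, advancing the global RNG by one uniform draw per reward.
#'
#' @param schedule a `bandit_schedule`.
#' @param block_index block number(s), 1-based.
#' @param action `"L"`/`"R"` (or integer codes 1/2); recycled against
#'   `block_index`.
#' @return integer vector of 0/1 rewards.
#' @export
sample_reward <- function(schedule, block_index, action) {
  if (any(block_index < 1L | block_index > nrow(schedule))) {
    stop("block_index out of range")
  }
  a <- action_to_int(action)
  p <- ifelse(a == 1L, schedule$p_left[block_index],
              schedule$p_right[block_index])
  as.integer(stats::runif(length(p)) < p)
}

# The higher-probability action of each block (1 = L, 2 = R); ties -> NA.
best_action <- function(schedule) {
  ifelse(schedule$p_left > schedule$p_right, 1L,
         ifelse(schedule$p_right > schedule$p_left, 2L, NA_integer_))
}

#' Validate a cohort of behavioural sessions
#'
#' A cohort is a data frame with one row per trial and columns `subject_id`,
#' `group`, `block`, `trial`, `action` ("L"/"R") and `reward` (0/1). Within
#' each subject, `block` must be non-decreasing.
#'
#' @param sessions cohort data frame.
#' @return the validated data frame, invisibly standardised (character
#'   actions, integer rewards).
#' @export
validate_sessions <- function(sessions) {
  needed <- c("subject_id", "group", "block", "trial", "action", "reward")
  missing <- setdiff(needed, names(sessions))
  if (length(missing)) {
    stop("sessions missing columns: ", paste(missing, collapse = ", "))
  }
  action_to_int(sessions$action)
  check_reward(sessions$reward)
  for (sid in unique(sessions$subject_id)) {
    b <- sessions$block[sessions$subject_id == sid]
    if (is.unsorted(b)) {
      stop(sprintf("subject %s: block indices are not non-decreasing", sid))
    }
  }
  sessions$action <- as.character(sessions$action)
  sessions$reward <- as.integer(sessions$reward)
  invisible(sessions)
}

# Split a cohort data frame into a list of per-subject data frames, keeping
# the subject order of first appearance.
split_sessions <- function(sessions) {
  ids <- unique(sessions$subject_id)
  lapply(stats::setNames(ids, ids),
         function(sid) sessions[sessions$subject_id == sid, , drop = FALSE])
}
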
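# Behavioural summary statistics. All consecutive-pair and run statistics
# are computed within blocks (blocks are separated by rating screens, so a
# stay/switch across a block boundary is not meaningful).

# Map a function over subjects, binding results into one tidy data frame.
per_subject <- function(sessions, fn, ...) {
  sessions <- validate_sessions(sessions)
  res <- lapply(split_sessions(sessions), fn, ...)
  out <- do.call(rbind, Map(function(sid, df) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    cbind(subject_id = sid, df, row.names = NULL)
  }, names(res), res))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Probability of choosing the better action
#'
#' The fraction of trials on which the subject chose the action with the
#' higher reward probability in the current block.
#'
#' @param sessions cohort data frame.
#' @param schedule a `bandit_schedule` shared by all subjects, or a named
#'   list of schedules keyed by subject id.
#' @return data frame `subject_id`, `p_best`.
#' @export
p_best_action <- function(sessions, schedule) {
  per_subject(sessions, function(ses) {
    sch <- if (inherits(schedule, "bandit_schedule")) schedule else
      schedule[[ses$subject_id[1]]]
    if (is.null(sch)) stop("no schedule for subject ", ses$subject_id[1])
    best <- best_action(sch)[ses$block]
    keep <- !is.na(best)
    data.frame(p_best = mean(action_to_int(ses$action)[keep] == best[keep]))
  })
}

#' Stay probability conditioned on the previous trial's reward
#'
#' Over consecutive trial pairs within blocks, the probability of repeating
#' the previous action given that it was (respectively was not) rewarded.
#'
#' @param sessions cohort data frame.
#' @return data frame `subject_id`, `p_stay_reward`, `p_stay_noreward`.
#' @export
stay_prob_given_reward <- function(sessions) {
  per_subject(sessions, function(ses) {
    a <- action_to_int(ses$action)
    n <- length(a)
    if (n < 2) return(NULL)
    same_block <- ses$block[-1] == ses$block[-n]
    stay <- (a[-1] == a[-n])[same_block]
    prev_r <- ses$reward[-n][same_block]
    data.frame(p_stay_reward = mean(stay[prev_r == 1]),
               p_stay_noreward = mean(stay[prev_r == 0]))
  })
}

# Per-trial run bookkeeping within one block: position in the current run
# (0-based) and rewards earned since the run began, before the current trial.
run_position <- function(a, r) {
  n <- length(a)
  pos <- integer(n)
  rew_since <- integer(n)
  for (t in seq_len(n)) {
    if (t == 1L || a[t] != a[t - 1L]) {
      pos[t] <- 0L
      rew_since[t] <- 0L
    } else {
      pos[t] <- pos[t - 1L] + 1L
      rew_since[t] <- rew_since[t - 1L] + r[t - 1L]
    }
  }
  list(pos = pos, rew_since = rew_since)
}

#' Stay probability after reward, by rewards earned since switching
#'
#' For every *rewarded* trial, counts the rewards earned since the current
#' run of the action began (excluding the current trial's reward), bins the
#' count as 0 / 1 / 2 / >2, and averages the indicator of staying on the
#' next trial.
#'
#' @param sessions cohort data frame.
#' @return data frame `subject_id`, `bin`, `p_stay`, `n`.
#' @export
stay_by_rewards_since_switch <- function(sessions) {
  per_subject(sessions, function(ses) {
    rows <- list()
    for (blk in split(seq_len(nrow(ses)), ses$block)) {
      a <- action_to_int(ses$action)[blk]
      r <- ses$reward[blk]
      n <- length(a)
      if (n < 2) next
      rp <- run_position(a, r)
      for (t in seq_len(n - 1L)) {
        if (r[t] != 1L) next
        rows[[length(rows) + 1]] <- c(rp$rew_since[t],
                                      as.integer(a[t + 1L] == a[t]))
      }
    }
    if (!length(rows)) return(NULL)
    m <- do.call(rbind, rows)
    bin <- cut(m[, 1], breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
               labels = c("0", "1", "2", ">2"))
    agg <- stats::aggregate(list(p_stay = m[, 2]), list(bin = bin), mean)
    agg$n <- as.integer(table(bin)[as.character(agg$bin)])
    agg
  })
}

#' Stay probability by repeats since switching (no-reward trials)
#'
#' Includes only trials on which (i) no reward was earned on the trial and
#' (ii) no reward has been earned since switching to the current action.
#' For those trials, the stay indicator is averaged as a function of how
#' many times the action has been repeated since the switch (0 =
#' immediately after switching).
#'
#' @param sessions cohort data frame.
#' @param max_repeats largest repeat count reported (default 15).
#' @return data frame `subject_id`, `repeats`, `p_stay`, `n`.
#' @export
stay_by_repeats_since_switch <- function(sessions, max_repeats = 15L) {
  per_subject(sessions, function(ses) {
    rows <- list()
    for (blk in split(seq_len(nrow(ses)), ses$block)) {
      a <- action_to_int(ses$action)[blk]
      r <- ses$reward[blk]
      n <- length(a)
      if (n < 2) next
      rp <- run_position(a, r)
      for (t in seq_len(n - 1L)) {
        if (r[t] != 0L || rp$rew_since[t] > 0L) next   # the reward filter
        if (rp$pos[t] > max_repeats) next
        rows[[length(rows) + 1]] <- c(rp$pos[t],
                                      as.integer(a[t + 1L] == a[t]))
      }
    }
    if (!length(rows)) return(NULL)
    m <- do.call(rbind, rows)
    agg <- stats::aggregate(list(p_stay = m[, 2]),
                            list(repeats = m[, 1]), mean)
    agg$n <- as.integer(table(factor(m[, 1],
                                     levels = agg$repeats)))
    agg
  })
}

#' Run-length decomposition of an action sequence
#'
#' A run is a maximal streak of identical consecutive actions; e.g.
#' L, R, R, L decomposes into runs of lengths 1, 2, 1.
#'
#' @param actions action vector (`"L"`/`"R"` or 1/2).
#' @return data frame `action`, `length`; concatenating the runs reproduces
#'   the sequence.
#' @export
runs <- function(actions) {
  if (length(actions) == 0) stop("empty action sequence")
  rl <- rle(action_to_int(actions))
  data.frame(action = int_to_action(rl$values), length = rl$lengths)
}

# Runs per subject, never crossing block boundaries.
runs_by_block <- function(ses) {
  do.call(rbind, lapply(split(seq_len(nrow(ses)), ses$block),
                        function(idx) runs(ses$action[idx])))
}

#' Median current run length by previous run length
#'
#' For every pair of consecutive runs (within a block), records
#' (previous length, current length); takes each subject's *median* current
#' length per previous length, then averages the medians over subjects.
#'
#' @param sessions cohort data frame.
#' @param max_prev largest previous-run length reported.
#' @return data frame `prev_length`, `median_current` (subject-averaged),
#'   `n_subjects`.
#' @export
next_vs_prev_run <- function(sessions, max_prev = 10L) {
  per_sub <- per_subject(sessions, function(ses) {
    rr <- runs_by_block(ses)
    if (nrow(rr) < 2) return(NULL)
    prev <- rr$length[-nrow(rr)]
    cur <- rr$length[-1]
    keep <- prev <= max_prev
    if (!any(keep)) return(NULL)
    agg <- stats::aggregate(list(median_current = cur[keep]),
                            list(prev_length = prev[keep]),
                            stats::median)
    agg
  })
  out <- stats::aggregate(list(median_current = per_sub$median_current),
                          list(prev_length = per_sub$prev_length), mean)
  out$n_subjects <- stats::aggregate(
    list(n = per_sub$median_current),
    list(prev_length = per_sub$prev_length), length)$n
  out
}

#' Fraction of runs of length 1
#'
#' The share of runs that consist of a single press, a marker of immediate
#' switching back (oscillation).
#'
#' @param sessions cohort data frame.
#' @return data frame `subject_id`, `frac_length1`.
#' @export
fraction_length1_runs <- function(sessions) {
  per_subject(sessions, function(ses) {
    rr <- runs_by_block(ses)
    data.frame(frac_length1 = mean(rr$length == 1L))
  })
}
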
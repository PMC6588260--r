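#' Define a simulation scenario
#'
#' A scenario is a forced (off-policy) prefix of (action, reward) pairs,
#' optionally followed by an on-policy continuation in which the model picks
#' its own actions, either greedily (argmax of its policy, ties to L) or by
#' sampling.
#'
#' @param forced_actions actions fed to the model, `"L"`/`"R"`.
#' @param forced_rewards matching 0/1 rewards.
#' @param n_on_policy length of the self-generated continuation (0 for a
#'   pure off-policy probe).
#' @param on_policy_mode `"greedy"` or `"sample"`.
#' @return a `scenario` object.
#' @export
scenario <- function(forced_actions, forced_rewards = 0L,
                     n_on_policy = 0L,
                     on_policy_mode = c("greedy", "sample")) {
  forced_actions <- action_to_int(forced_actions)
  forced_rewards <- rep_len(as.integer(forced_rewards),
                            length(forced_actions))
  check_reward(forced_rewards)
  if (n_on_policy < 0) stop("n_on_policy must be >= 0")
  structure(list(forced_actions = forced_actions,
                 forced_rewards = forced_rewards,
                 n_on_policy = as.integer(n_on_policy),
                 on_policy_mode = match.arg(on_policy_mode)),
            class = "scenario")
}

#' Reward-switch probe: forced R block then forced L block
#'
#' The 30-trial interrogation design: the model is fed action R for
#' `n_pre = 10` trials, then action L for `n_post = 20` trials, with rewards
#' delivered on the trials listed in `reward_trials`. Varying the reward
#' placement while reading out the predicted policy reveals how reward
#' history moves the probability of staying. The bundled defaults
#' (`reward_probe_library()`) place one, two or three rewards on the L run
#' at matched late positions so that the same trial can be compared across
#' different prior reward counts; the exact placements are illustrative
#' configuration values.
#'
#' @param reward_trials trial indices (1-based over the 30 trials) that are
#'   rewarded.
#' @param n_pre,n_post lengths of the forced R and L phases.
#' @return a pure off-policy `scenario`.
#' @export
probe_reward_switch <- function(reward_trials = c(15L), n_pre = 10L,
                                n_post = 20L) {
  n <- n_pre + n_post
  r <- integer(n)
  r[reward_trials] <- 1L
  scenario(c(rep(2L, n_pre), rep(1L, n_post)), r, n_on_policy = 0L)
}

#' @rdname probe_reward_switch
#' @export
reward_probe_library <- function() {
  list(one_reward = probe_reward_switch(c(19L)),
       two_rewards = probe_reward_switch(c(15L, 19L)),
       three_rewards = probe_reward_switch(c(13L, 15L, 19L)))
}

#' Oscillation probe: forced R,R,R,R,R,R,L,R,L then greedy continuation
#'
#' The mixed probe used to test whether a model sustains length-1
#' oscillations: nine forced trials ending in two alternations (R, L, R, L
#' at the tail), then `n_on_policy` greedy self-generated trials with no
#' rewards delivered.
#'
#' @param n_on_policy greedy continuation length (default 11, for 20 trials
#'   in total).
#' @return a mixed `scenario`.
#' @export
probe_oscillation <- function(n_on_policy = 11L) {
  scenario(c("R", "R", "R", "R", "R", "R", "L", "R", "L"), 0L,
           n_on_policy = n_on_policy, on_policy_mode = "greedy")
}

#' Run a pure off-policy probe
#'
#' Feeds the scenario's forced actions and rewards into the (frozen) model,
#' recording the predicted policy *before* each forced observation. The
#' trace depends only on the forced inputs and the parameters, never on the
#' model's own predictions.
#'
#' @param model a `bandit_model`.
#' @param scen a `scenario` with `n_on_policy = 0` (a scenario with a
#'   continuation is delegated to [run_mixed()]).
#' @return data frame: `trial`, `p_L`, `p_R`, `fed_action`, `fed_reward`,
#'   `phase`.
#' @export
run_off_policy <- function(model, scen) {
  if (length(scen$forced_actions) == 0) stop("empty scenario")
  if (scen$n_on_policy > 0) return(run_mixed(model, scen))
  run_mixed(model, scen)
}

#' Run a mixed off-policy / on-policy probe
#'
#' The forced prefix is fed verbatim; the continuation actions are chosen by
#' the model itself (greedy argmax by default, ties to L) and paired with
#' `continuation_reward` (default 0: the probe delivers nothing unless told
#' otherwise).
#'
#' @param model a `bandit_model`.
#' @param scen a `scenario`.
#' @param continuation_reward reward fed on each self-generated trial
#'   (scalar or vector, 0/1).
#' @return data frame: `trial`, `p_L`, `p_R`, `fed_action`, `fed_reward`,
#'   `phase` (`"forced"` or `"on"`).
#' @export
run_mixed <- function(model, scen, continuation_reward = 0L) {
  agent <- make_agent(model)
  agent$reset()
  n_f <- length(scen$forced_actions)
  n_total <- n_f + scen$n_on_policy
  cont_r <- rep_len(as.integer(continuation_reward),
                    max(scen$n_on_policy, 1L))
  out <- data.frame(trial = seq_len(n_total), p_L = NA_real_,
                    p_R = NA_real_, fed_action = NA_character_,
                    fed_reward = NA_integer_,
                    phase = rep(c("forced", "on"),
                                c(n_f, scen$n_on_policy)))
  for (t in seq_len(n_total)) {
    p <- agent$predict()
    out$p_L[t] <- p[1]; out$p_R[t] <- p[2]
    if (t <= n_f) {
      a <- scen$forced_actions[t]
      r <- scen$forced_rewards[t]
    } else {
      a <- if (scen$on_policy_mode == "greedy") {
        if (p[2] > p[1]) 2L else 1L            # exact tie -> L
      } else {
        if (stats::runif(1) < p[1]) 1L else 2L
      }
      r <- cont_r[t - n_f]
    }
    out$fed_action[t] <- int_to_action(a)
    out$fed_reward[t] <- r
    agent$observe(a, r)
  }
  out
}

#' Simulate a model on-policy through the task
#'
#' The model completes the task on its own: on each trial it predicts,
#' selects an action (sampled from its policy by default, or greedy),
#' receives a reward drawn from the schedule, and observes the outcome.
#' State is reset at block starts when the model resets per block.
#'
#' @param model a `bandit_model`.
#' @param schedule a `bandit_schedule`.
#' @param seed integer seed making the session reproducible.
#' @param mode `"sample"` (default) or `"greedy"`.
#' @param subject_id,group labels written into the session.
#' @return a session data frame (`subject_id`, `group`, `block`, `trial`,
#'   `action`, `reward`).
#' @export
run_on_policy <- function(model, schedule, seed = NULL,
                          mode = c("sample", "greedy"),
                          subject_id = "sim", group = "simulated") {
  mode <- match.arg(mode)
  agent <- make_agent(model)
  with_seed(seed, {
    n_total <- sum(schedule$n_trials)
    block <- rep(schedule$block, schedule$n_trials)
    action <- integer(n_total)
    reward <- integer(n_total)
    pos <- 0L
    for (b in seq_len(nrow(schedule))) {
      if (model$reset_per_block || b == 1L) agent$reset()
      for (k in seq_len(schedule$n_trials[b])) {
        pos <- pos + 1L
        p <- agent$predict()
        a <- if (mode == "greedy") {
          if (p[2] > p[1]) 2L else 1L
        } else {
          if (stats::runif(1) < p[1]) 1L else 2L
        }
        r <- sample_reward(schedule, b, a)
        agent$observe(a, r)
        action[pos] <- a
        reward[pos] <- r
      }
    }
    data.frame(subject_id = subject_id, group = group, block = block,
               trial = seq_len(n_total), action = int_to_action(action),
               reward = reward)
  })
}
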
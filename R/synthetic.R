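# Synthetic cohorts. The clinical dataset behind the original analyses is
# not redistributable, so the package ships generative phenotypes whose
# on-policy behaviour carries the qualitative structure those analyses rely
# on: above-chance choice of the better action, a *decrease* in staying
# immediately after reward (the reward-switch "dip") that weakens with the
# number of rewards accumulated on the action, slowly decaying
# perseveration, and (for the bipolar-like phenotype) self-sustaining
# length-1 oscillations.

#' Specify a synthetic behavioural phenotype
#'
#' @param label cohort label (written into the `group` column).
#' @param params generating parameters (typically [gql_params()]; any model
#'   family with an agent works).
#' @param family model family of `params`.
#' @param n_subjects subjects to generate (default 34, a typical group
#'   size).
#' @param trials_per_block fixed trials per block (default 110) or a
#'   sampler function, as in [build_schedule()].
#' @param jitter between-subject spread: each subject's unconstrained
#'   parameter vector is multiplied elementwise by `1 + U(-jitter, jitter)`.
#'   The logistic/exponential transforms keep constrained parameters inside
#'   their supports.
#' @param seed master seed; subject-level seeds are derived from it.
#' @param expectations named list of signature expectations consumed by
#'   [verify_phenotype()].
#' @return a `phenotype_spec`.
#' @export
phenotype_spec <- function(label, params, family = "gql",
                           n_subjects = 34L, trials_per_block = 110L,
                           jitter = 0.1, seed = 1L,
                           expectations = list(reward_dip = TRUE)) {
  structure(list(label = label, family = family, params = params,
                 n_subjects = as.integer(n_subjects),
                 trials_per_block = trials_per_block, jitter = jitter,
                 seed = as.integer(seed), expectations = expectations),
            class = "phenotype_spec")
}

#' Built-in behavioural phenotypes
#'
#' Three generalised-Q-learning (d = 2) phenotypes:
#' \describe{
#'   \item{healthy}{The reward-switch dip is carried by a negative
#'     interaction between the fast value trace and the fast history trace
#'     (plus a mildly negative fast-value weight): a just-rewarded,
#'     just-taken action is transiently penalised, but the penalty fades
#'     once the action is left, because the fast history decays for untaken
#'     actions while their values are frozen. A strong positive weight on
#'     the slow value trace accumulates reward evidence (above-chance
#'     choice of the better action, dips shrinking with reward count), and
#'     positive history weights give perseveration.}
#'   \item{depression}{The same architecture with weaker value weights and
#'     weaker perseveration: flatter reward sensitivity and more length-1
#'     runs.}
#'   \item{bipolar}{A strongly negative weight on a fast history trace makes
#'     one alternation raise the probability of alternating again
#'     (self-sustaining symmetric oscillations, a high fraction of length-1
#'     runs); reward weights are weak and the immediate reward effect is
#'     not reliably negative.}
#' }
#' The numerical settings are the package's own choices, validated by
#' [verify_phenotype()]; they are not estimates from any clinical data.
#'
#' @return named list of `phenotype_spec` objects.
#' @export
phenotype_presets <- function() {
  list(
    healthy = phenotype_spec(
      "healthy",
      gql_params(Phi = c(0.6, 0.08), Psi = c(0.5, 0.02),
                 B = c(-1, 12), K = c(2, 1.5),
                 C = matrix(c(-3.5, 0, 0, 0), 2, 2)),
      seed = 101L,
      expectations = list(reward_dip = TRUE, p_best_min = 0.5,
                          reward_count_monotone = TRUE)),
    depression = phenotype_spec(
      "depression",
      gql_params(Phi = c(0.6, 0.08), Psi = c(0.5, 0.02),
                 B = c(-1, 6), K = c(0.5, 0.8),
                 C = matrix(c(-3, 0, 0, 0), 2, 2)),
      seed = 102L,
      expectations = list(reward_dip = TRUE, p_best_min = 0.5)),
    bipolar = phenotype_spec(
      "bipolar",
      gql_params(Phi = c(0.45, 0.05), Psi = c(0.85, 0.015),
                 B = c(-0.8, 4), K = c(-1.4, 1.2), C = 0),
      seed = 103L,
      expectations = list(reward_dip = NA, p_best_min = 0.5,
                          high_length1 = TRUE)))
}

#' Generate a labelled synthetic cohort
#'
#' Each subject gets an independently shuffled 12-block schedule and a
#' jittered copy of the generating parameters, and completes the task
#' on-policy (sampling from their own policy). Everything is derived
#' deterministically from the spec's seed.
#'
#' @param spec a `phenotype_spec`.
#' @param schedule_args arguments passed to [build_schedule()] besides the
#'   per-subject seed and `trials_per_block`.
#' @return a `bandit_cohort`: list with `sessions` (one data frame for the
#'   whole cohort), `schedules` (named per-subject list) and
#'   `subject_params` (the jittered generating parameters).
#' @export
generate_cohort <- function(spec, schedule_args = list()) {
  sessions <- list()
  schedules <- list()
  subject_params <- list()
  u0 <- inverse_transform_params(spec$params)
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("%s_%02d", spec$label, i)
    s_seed <- derive_seed(spec$seed, i)
    u <- with_seed(s_seed, u0 * (1 + stats::runif(length(u0), -spec$jitter,
                                                  spec$jitter)))
    params <- transform_params(
      spec$family, u,
      d = if (spec$family == "gql") spec$params$d else NULL,
      J = if (spec$family == "lin") spec$params$J else NULL,
      n_cells = if (spec$family == "rnn") spec$params$n_cells else NULL)
    sched <- do.call(build_schedule, c(
      list(trials_per_block = spec$trials_per_block,
           seed = derive_seed(s_seed, 1L)), schedule_args))
    model <- bandit_model(spec$family, params)
    ses <- run_on_policy(model, sched, seed = derive_seed(s_seed, 2L),
                         subject_id = sid, group = spec$label)
    sessions[[sid]] <- ses
    schedules[[sid]] <- sched
    subject_params[[sid]] <- params
  }
  structure(list(sessions = do.call(rbind, c(sessions,
                                             make.row.names = FALSE)),
                 schedules = schedules, subject_params = subject_params,
                 spec = spec),
            class = "bandit_cohort")
}

#' @export
print.bandit_cohort <- function(x, ...) {
  cat(sprintf("<bandit_cohort: %s, %d subjects, %d trials>\n",
              x$spec$label, length(x$schedules), nrow(x$sessions)))
  invisible(x)
}

#' Check a cohort against its phenotype's behavioural signatures
#'
#' Evaluates, with Monte-Carlo tolerances, whether the cohort expresses the
#' signatures its phenotype promises: above-chance choice of the better
#' action; the sign of the immediate reward effect on staying (dip);
#' monotone growth of post-reward staying with the number of rewards earned
#' since switching; and an elevated fraction of length-1 runs.
#'
#' @param cohort a `bandit_cohort` (or a list with `sessions` and
#'   `schedules`).
#' @param expectations overrides for the spec's expectation list.
#' @return list with `pass` (logical) and `checks` (one row per evaluated
#'   signature: value, requirement, pass).
#' @export
verify_phenotype <- function(cohort, expectations = NULL) {
  exp <- if (!is.null(expectations)) expectations else
    cohort$spec$expectations
  sessions <- cohort$sessions
  checks <- list()
  add <- function(name, value, requirement, pass) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, value = value, requirement = requirement, pass = pass)
  }

  pb <- p_best_action(sessions, cohort$schedules)
  p_best_min <- if (is.null(exp$p_best_min)) 0.5 else exp$p_best_min
  add("p_best_action", mean(pb$p_best),
      sprintf("> %.2f", p_best_min), mean(pb$p_best) > p_best_min)

  st <- stay_prob_given_reward(sessions)
  diff <- mean(st$p_stay_reward, na.rm = TRUE) -
    mean(st$p_stay_noreward, na.rm = TRUE)
  if (!is.null(exp$reward_dip) && !is.na(exp$reward_dip)) {
    req <- if (exp$reward_dip) "stay|reward < stay|no reward" else
      "stay|reward >= stay|no reward"
    add("reward_effect_on_stay", diff, req,
        if (exp$reward_dip) diff < 0 else diff >= 0)
  }

  if (isTRUE(exp$reward_count_monotone)) {
    sb <- stay_by_rewards_since_switch(sessions)
    pooled <- stats::aggregate(list(p_stay = sb$p_stay),
                               list(bin = sb$bin), mean)
    lo <- pooled$p_stay[pooled$bin == "0"]
    hi <- pooled$p_stay[pooled$bin == ">2"]
    add("stay_increases_with_rewards", hi - lo, "> 0",
        length(lo) == 1 && length(hi) == 1 && hi > lo)
  }

  if (isTRUE(exp$high_length1)) {
    fl <- fraction_length1_runs(sessions)
    add("fraction_length1_runs", mean(fl$frac_length1), "> 0.30",
        mean(fl$frac_length1) > 0.30)
  }

  checks <- do.call(rbind, checks)
  list(pass = all(checks$pass), checks = checks)
}
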
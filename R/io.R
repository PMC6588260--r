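# File formats: plain CSV for sessions, schedules, scenarios and traces;
# JSON for model parameters. Everything round-trips exactly enough to make
# a run reproducible from its files.

#' Read and write behavioural sessions
#'
#' Sessions are stored as comma-separated text with header
#' `subject_id,group,block,trial,action,reward`, actions as literal `L`/`R`.
#' Reading validates every row and reports the first offending line number.
#'
#' @param path file path.
#' @param sessions cohort data frame.
#' @return `read_sessions()`: validated cohort data frame.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "block", "trial", "action", "reward")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("malformed session file, missing columns: ",
         paste(missing, collapse = ", "))
  }
  bad_action <- which(!df$action %in% .ACTIONS)
  if (length(bad_action)) {
    stop(sprintf("unknown action symbol '%s' at line %d",
                 df$action[bad_action[1]], bad_action[1] + 1L))
  }
  bad_reward <- which(!df$reward %in% c(0L, 1L))
  if (length(bad_reward)) {
    stop(sprintf("invalid reward '%s' at line %d",
                 df$reward[bad_reward[1]], bad_reward[1] + 1L))
  }
  for (sid in unique(df$subject_id)) {
    rows <- which(df$subject_id == sid)
    b <- df$block[rows]
    if (is.unsorted(b)) {
      first_bad <- rows[which(diff(b) < 0)[1] + 1L]
      stop(sprintf("blocks out of order for subject %s at line %d", sid,
                   first_bad + 1L))
    }
  }
  validate_sessions(df)
}

#' @rdname read_sessions
#' @export
write_sessions <- function(sessions, path) {
  sessions <- validate_sessions(sessions)
  utils::write.csv(sessions[, c("subject_id", "group", "block", "trial",
                                "action", "reward")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write block schedules
#'
#' One row per block with columns `block`, `p_left`, `p_right`, `n_trials`.
#'
#' @param schedule a `bandit_schedule`.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  check_prob(df$p_left, "p_left")
  check_prob(df$p_right, "p_right")
  class(df) <- c("bandit_schedule", "data.frame")
  df
}

#' Read and write simulation scenarios
#'
#' Delimited text with columns `trial`, `action`, `reward`, `phase`
#' (`forced` rows define the off-policy prefix; the number of `on` rows
#' sets the continuation length).
#'
#' @param scen a `scenario`.
#' @param path file path.
#' @export
write_scenario <- function(scen, path) {
  n_f <- length(scen$forced_actions)
  df <- data.frame(
    trial = seq_len(n_f + scen$n_on_policy),
    action = c(int_to_action(scen$forced_actions),
               rep(NA_character_, scen$n_on_policy)),
    reward = c(scen$forced_rewards, rep(NA_integer_, scen$n_on_policy)),
    phase = rep(c("forced", "on"), c(n_f, scen$n_on_policy)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scenario
#' @param on_policy_mode continuation mode for the reconstructed scenario.
#' @export
read_scenario <- function(path, on_policy_mode = "greedy") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  forced <- df[df$phase == "forced", , drop = FALSE]
  scenario(forced$action, forced$reward,
           n_on_policy = sum(df$phase == "on"),
           on_policy_mode = on_policy_mode)
}

#' Serialise and restore a fitted model
#'
#' Models are written as JSON: family tag, parameter arrays (with their
#' shapes), and the reset convention. Network weight matrices are stored
#' column-major with explicit dimensions.
#'
#' @param model a `bandit_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  p <- model$params
  ser <- switch(model$family,
    ql = list(phi = p$phi, beta = p$beta),
    qlp = list(phi = p$phi, beta = p$beta, kappa = p$kappa),
    gql = list(Phi = p$Phi, Psi = p$Psi, B = p$B, K = p$K,
               C = as.numeric(p$C), d = p$d),
    lin = list(J = p$J, mu0 = p$mu0, mu = p$mu, gamma = p$gamma,
               zeta = p$zeta),
    rnn = list(n_cells = p$n_cells, n_actions = p$n_actions,
               flat = rnn_flatten(p)))
  jsonlite::write_json(list(family = model$family,
                            reset_per_block = model$reset_per_block,
                            params = ser),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  params <- switch(obj$family,
    ql = ql_params(p$phi, p$beta),
    qlp = qlp_params(p$phi, p$beta, p$kappa),
    gql = gql_params(p$Phi, p$Psi, p$B, p$K, matrix(p$C, p$d, p$d)),
    lin = lin_params(p$J, p$mu0, p$mu, p$gamma, p$zeta),
    rnn = rnn_unflatten(p$flat, p$n_cells, p$n_actions),
    stop("unknown model family in file"))
  bandit_model(obj$family, params, reset_per_block = obj$reset_per_block)
}
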
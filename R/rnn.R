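#' LSTM imitation-network parameters
#'
#' The network is a single LSTM layer of `n_cells` cells followed by a
#' bias-free softmax readout over the actions. On each trial it receives the
#' previous trial's action (one-hot) and reward (raw scalar), so the input
#' dimension is `n_actions + 1`. The parameter set is
#' `{V, W_f, W_i, W_o, W_c, U_f, U_i, U_o, U_c, b_f, b_i, b_o, b_c}`:
#' input weights `W` are `n_cells x (n_actions + 1)`, recurrent weights `U`
#' are `n_cells x n_cells`, biases `b` are length `n_cells`, and the readout
#' `V` is `n_cells x n_actions`. There is no output bias and no peephole
#' connections. Weights are initialised i.i.d. uniform on `[-scale, scale]`
#' under `seed`, so a single fixed starting network per size can be reused
#' across fits. All biases, including the forget gate's, share the same
#' initialisation.
#'
#' @param n_cells number of LSTM cells.
#' @param n_actions number of actions (2 for the bandit task).
#' @param seed integer seed for the weight initialisation.
#' @param scale half-width of the uniform initial-weight distribution.
#' @return an `rnn_params` object (a named list of matrices/vectors).
#' @export
rnn_params <- function(n_cells, n_actions = 2L, seed = 1L, scale = 0.1) {
  if (n_cells < 1 || n_actions < 1) stop("invalid network size")
  n_in <- n_actions + 1L
  with_seed(seed, {
    m <- function(r, c) matrix(stats::runif(r * c, -scale, scale), r, c)
    p <- list(
      W_f = m(n_cells, n_in), W_i = m(n_cells, n_in),
      W_o = m(n_cells, n_in), W_c = m(n_cells, n_in),
      U_f = m(n_cells, n_cells), U_i = m(n_cells, n_cells),
      U_o = m(n_cells, n_cells), U_c = m(n_cells, n_cells),
      b_f = stats::runif(n_cells, -scale, scale),
      b_i = stats::runif(n_cells, -scale, scale),
      b_o = stats::runif(n_cells, -scale, scale),
      b_c = stats::runif(n_cells, -scale, scale),
      V = m(n_cells, n_actions),
      n_cells = as.integer(n_cells), n_actions = as.integer(n_actions))
    class(p) <- "rnn_params"
    p
  })
}

#' Number of free parameters of the imitation network
#'
#' Four gates each contribute an input matrix (`n_cells * (n_actions + 1)`),
#' a recurrent matrix (`n_cells^2`) and a bias (`n_cells`); the softmax
#' readout adds `n_cells * n_actions` with no bias. For two actions this
#' gives 190, 580 and 1960 parameters at 5, 10 and 20 cells.
#'
#' @param n_cells number of LSTM cells.
#' @param n_actions number of actions.
#' @return integer parameter count.
#' @export
count_rnn_params <- function(n_cells, n_actions = 2L) {
  if (any(n_cells < 1) || any(n_actions < 1)) stop("invalid network size")
  as.integer(4L * (n_cells * (n_actions + 1L) + n_cells^2 + n_cells) +
               n_cells * n_actions)
}

# Zero initial state: cell states and outputs start at zero.
rnn_state <- function(params) {
  list(c = numeric(params$n_cells), h = numeric(params$n_cells))
}

#' One-hot input encoding
#'
#' The input vector for a trial is the one-hot code of the previous action
#' (L in slot 1, R in slot 2) concatenated with the previous reward as a raw
#' scalar. The first trial after a reset has no previous observation and
#' feeds the all-zero vector.
#'
#' @param prev_action previous action (`"L"`/`"R"`/1/2) or `NULL`.
#' @param prev_reward previous reward (0/1) or `NULL`.
#' @param n_actions number of actions.
#' @return numeric vector of length `n_actions + 1`.
#' @export
encode_input <- function(prev_action, prev_reward, n_actions = 2L) {
  x <- numeric(n_actions + 1L)
  if (!is.null(prev_action) && !is.na(prev_action)) {
    x[action_to_int(prev_action)] <- 1
    x[n_actions + 1L] <- as.numeric(prev_reward)
  }
  x
}

#' Single LSTM update
#'
#' Standard LSTM cell dynamics: forget, input and output gates
#' `f, i, o = sigmoid(W x + U h + b)`, candidate `g = tanh(W_c x + U_c h +
#' b_c)`, cell state `c' = f * c + i * g`, output `h' = o * tanh(c')`
#' (all products elementwise).
#'
#' @param x input vector of length `n_actions + 1`.
#' @param state list with cell state `c` and output `h`.
#' @param params an `rnn_params`.
#' @return updated state list.
#' @export
lstm_step <- function(x, state, params) {
  if (anyNA(unlist(params[c("W_f", "U_f", "b_f")]))) {
    stop("NaN in network weights")
  }
  f <- sigmoid(drop(params$W_f %*% x) + drop(params$U_f %*% state$h) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% x) + drop(params$U_i %*% state$h) + params$b_i)
  o <- sigmoid(drop(params$W_o %*% x) + drop(params$U_o %*% state$h) + params$b_o)
  g <- tanh(drop(params$W_c %*% x) + drop(params$U_c %*% state$h) + params$b_c)
  c_new <- f * state$c + i * g
  list(c = c_new, h = o * tanh(c_new))
}

#' Softmax readout of the network state
#'
#' @param state an LSTM state (list with `h`), or a plain `h` vector.
#' @param V `n_cells x n_actions` readout weight matrix.
#' @return per-action probability vector.
#' @export
rnn_policy <- function(state, V) {
  h <- if (is.list(state)) state$h else state
  softmax_policy(drop(crossprod(V, h)))
}

#' Run the network across one session
#'
#' Produces the strictly causal per-trial policy trace: the prediction at
#' trial `t` consumes only inputs up to trial `t - 1`. With
#' `reset_per_block` the state is cleared (and the zero input fed) at the
#' first trial of every block.
#'
#' @param session one subject's trials (data frame with `block`, `action`,
#'   `reward`).
#' @param params an `rnn_params`.
#' @param reset_per_block logical.
#' @return matrix with one row per trial and columns `p_L`, `p_R`.
#' @export
rnn_forward_session <- function(session, params, reset_per_block = TRUE) {
  n <- nrow(session)
  if (n == 0) stop("empty session")
  model <- bandit_model("rnn", params, reset_per_block)
  policy_trace(model, session)
}

# Flatten rnn params to a named numeric vector (fixed order) and back.
rnn_flatten <- function(params) {
  fields <- c("W_f", "W_i", "W_o", "W_c", "U_f", "U_i", "U_o", "U_c",
              "b_f", "b_i", "b_o", "b_c", "V")
  unlist(lapply(params[fields], as.numeric))
}

rnn_unflatten <- function(vec, n_cells, n_actions = 2L) {
  n_in <- n_actions + 1L
  sizes <- c(W_f = n_cells * n_in, W_i = n_cells * n_in,
             W_o = n_cells * n_in, W_c = n_cells * n_in,
             U_f = n_cells^2, U_i = n_cells^2, U_o = n_cells^2,
             U_c = n_cells^2,
             b_f = n_cells, b_i = n_cells, b_o = n_cells, b_c = n_cells,
             V = n_cells * n_actions)
  stopifnot(length(vec) == sum(sizes))
  out <- list()
  pos <- 0L
  for (nm in names(sizes)) {
    vals <- vec[pos + seq_len(sizes[[nm]])]
    pos <- pos + sizes[[nm]]
    out[[nm]] <- if (startsWith(nm, "b")) {
      as.numeric(vals)
    } else if (startsWith(nm, "W")) {
      matrix(vals, n_cells, n_in)
    } else if (nm == "V") {
      matrix(vals, n_cells, n_actions)
    } else {
      matrix(vals, n_cells, n_cells)
    }
  }
  out$n_cells <- as.integer(n_cells)
  out$n_actions <- as.integer(n_actions)
  class(out) <- "rnn_params"
  out
}
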
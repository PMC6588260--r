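#' Parameter containers for the value-based choice models
#'
#' `ql_params()` holds the plain Q-learning model: one value per action,
#' updated with learning rate `phi`, read out through a softmax with inverse
#' temperature `beta > 0`. `qlp_params()` adds a perseveration weight `kappa`
#' that is added to the logit of whichever action was taken on the previous
#' trial; `kappa = 0` recovers QL exactly. `gql_params()` is the generalised
#' model: `d` values and `d` action-history traces per action, with learning
#' rates `Phi`/`Psi` (each in \[0,1\]), readout weights `B` (values), `K`
#' (histories) and a `d x d` interaction matrix `C`, for `4d + d^2` free
#' parameters in total.
#'
#' @param phi,Phi value learning rate(s) in \[0,1\].
#' @param beta inverse temperature, > 0.
#' @param kappa perseveration weight (any real; negative values favour
#'   alternation).
#' @param Psi history learning rate(s) in \[0,1\].
#' @param B,K value / history readout weights, length `d`.
#' @param C `d x d` interaction weight matrix (a scalar 0 is expanded).
#' @return a parameter list with class `ql_params`, `qlp_params` or
#'   `gql_params`.
#' @export
ql_params <- function(phi, beta) {
  check_prob(phi, "phi")
  if (beta <= 0) stop("beta must be > 0")
  structure(list(phi = phi, beta = beta), class = "ql_params")
}

#' @rdname ql_params
#' @export
qlp_params <- function(phi, beta, kappa) {
  p <- ql_params(phi, beta)
  structure(c(p, list(kappa = kappa)), class = "qlp_params")
}

#' @rdname ql_params
#' @export
gql_params <- function(Phi, Psi, B, K, C = 0) {
  d <- length(Phi)
  if (d < 1) stop("d must be >= 1")
  check_prob(Phi, "Phi")
  check_prob(Psi, "Psi")
  if (length(Psi) != d || length(B) != d || length(K) != d) {
    stop("Phi, Psi, B, K must all have length d")
  }
  if (length(C) == 1L) C <- matrix(C, d, d)
  C <- as.matrix(C)
  if (!all(dim(C) == c(d, d))) stop("C must be a d x d matrix")
  structure(list(Phi = Phi, Psi = Psi, B = B, K = K, C = C, d = d),
            class = "gql_params")
}

#' Canonical trace ordering for a generalised Q-learning model
#'
#' The GQL likelihood is invariant under any permutation of the trace
#' indices (permuting `Phi`, `Psi`, `B`, `K` and the rows and columns of
#' `C` jointly leaves every policy unchanged). To make fitted parameters
#' identifiable and comparable, fits are reported in the canonical order:
#' traces sorted by decreasing value learning rate `Phi` (ties broken by
#' decreasing `Psi`).
#'
#' @param params a `gql_params`.
#' @return the same model with traces in canonical order.
#' @export
canonicalize_gql <- function(params) {
  ord <- order(params$Phi, params$Psi, decreasing = TRUE)
  gql_params(params$Phi[ord], params$Psi[ord], params$B[ord],
             params$K[ord], params$C[ord, ord, drop = FALSE])
}

#' Number of free parameters of the generalised Q-learning model
#'
#' `Phi`, `Psi`, `B`, `K` contribute `d` scalars each and the interaction
#' matrix `C` contributes `d^2`, so the total is `4d + d^2` (5, 12 and 140
#' for d = 1, 2, 10).
#'
#' @param d number of value/history traces per action, >= 1.
#' @return integer parameter count.
#' @export
count_gql_params <- function(d) {
  if (any(d < 1)) stop("d must be >= 1")
  as.integer(4L * d + d^2)
}

# --- agent state -----------------------------------------------------------

# Fresh state for a value-based agent. For QL/QLP, Q is a length-2 vector
# (L, R); for GQL, Q and H are 2 x d matrices (row 1 = L, row 2 = R). States
# start at zero and last_action is NA until the first observation.
agent_state <- function(params) {
  if (inherits(params, "gql_params")) {
    list(Q = matrix(0, 2, params$d), H = matrix(0, 2, params$d),
         last_action = NA_integer_)
  } else {
    list(Q = c(0, 0), last_action = NA_integer_)
  }
}

#' Q-learning value update
#'
#' Moves the taken action's value toward the reward:
#' `Q(a) <- (1 - phi) Q(a) + phi r`. The other action's value is untouched.
#'
#' @param state agent state as produced by the agents' `reset()`.
#' @param action taken action, `"L"`/`"R"` or 1/2.
#' @param reward 0 or 1.
#' @param params a `ql_params` or `qlp_params`.
#' @return updated state (with `last_action` recorded).
#' @export
ql_update <- function(state, action, reward, params) {
  a <- action_to_int(action)
  check_reward(reward)
  state$Q[a] <- (1 - params$phi) * state$Q[a] + params$phi * reward
  state$last_action <- a
  state
}

#' QLP action logits
#'
#' `logit(a) = beta * Q(a) + kappa * 1[a == last action]`; on the first trial
#' after a reset the perseveration kernel is zero for both actions.
#'
#' @inheritParams ql_update
#' @return length-2 numeric vector of logits (L, R).
#' @export
qlp_logits <- function(state, params) {
  kernel <- c(0, 0)
  kappa <- if (is.null(params$kappa)) 0 else params$kappa
  if (!is.na(state$last_action)) kernel[state$last_action] <- kappa
  params$beta * state$Q + kernel
}

#' Generalised Q-learning state update
#'
#' The taken action's value vector moves elementwise toward the reward with
#' rates `Phi`. Every action's history vector is updated with rates `Psi`:
#' the taken action's histories move toward 1, all other actions' histories
#' decay toward 0, so each history entry stays in \[0,1\].
#'
#' @inheritParams ql_update
#' @param params a `gql_params`.
#' @export
gql_update <- function(state, action, reward, params) {
  a <- action_to_int(action)
  check_reward(reward)
  state$Q[a, ] <- (1 - params$Phi) * state$Q[a, ] + params$Phi * reward
  target <- c(0, 0); target[a] <- 1
  for (act in 1:2) {
    state$H[act, ] <- (1 - params$Psi) * state$H[act, ] +
      params$Psi * target[act]
  }
  state$last_action <- a
  state
}

#' Generalised Q-learning action logits
#'
#' `logit(a) = B . Q(a) + K . H(a) + H(a)' C Q(a)`.
#'
#' @inheritParams gql_update
#' @return length-2 numeric vector of logits (L, R).
#' @export
gql_logits <- function(state, params) {
  vapply(1:2, function(a) {
    q <- state$Q[a, ]; h <- state$H[a, ]
    sum(params$B * q) + sum(params$K * h) +
      drop(h %*% params$C %*% q)
  }, numeric(1))
}

# --- model objects and the agent contract ----------------------------------

#' Bundle a model family with its parameters
#'
#' A `bandit_model` pairs a family tag with its parameter container and the
#' block-reset convention; it is the object all evaluation and simulation
#' functions consume. `reset_per_block = TRUE` (the default everywhere) means
#' internal state is cleared at every block boundary, so predictions are
#' conditioned only on the actions and rewards of the current block.
#'
#' @param family one of `"ql"`, `"qlp"`, `"gql"`, `"lin"`, `"rnn"`.
#' @param params the matching parameter container (`ql_params()`,
#'   `qlp_params()`, `gql_params()`, `lin_params()`, `rnn_params()`).
#' @param reset_per_block logical; reset agent state at block starts.
#' @return an object of class `bandit_model`.
#' @export
bandit_model <- function(family = c("ql", "qlp", "gql", "lin", "rnn"),
                         params, reset_per_block = TRUE) {
  family <- match.arg(family)
  expected <- paste0(family, "_params")
  if (!inherits(params, expected)) {
    stop(sprintf("family '%s' requires params of class '%s'", family, expected))
  }
  structure(list(family = family, params = params,
                 reset_per_block = reset_per_block),
            class = "bandit_model")
}

#' @export
print.bandit_model <- function(x, ...) {
  cat(sprintf("<bandit_model: %s, %d free parameters, reset_per_block=%s>\n",
              x$family, n_free_params(x), x$reset_per_block))
  invisible(x)
}

# Number of free scalars in a model's parameter container.
n_free_params <- function(model) {
  p <- model$params
  switch(model$family,
         ql = 2L, qlp = 3L,
         gql = count_gql_params(p$d),
         lin = 1L + 3L * p$J,
         rnn = count_rnn_params(p$n_cells, p$n_actions))
}

#' Create a stateful agent implementing the observe/predict contract
#'
#' Returns a list of three closures sharing mutable state:
#' `reset()` clears internal state (called automatically at block starts when
#' the model resets per block), `predict()` returns the probability vector
#' for the upcoming trial using only what has been observed so far, and
#' `observe(action, reward)` feeds the trial's outcome into the state.
#' Every higher-level routine (traces, simulation, fitting diagnostics)
#' drives models exclusively through this contract.
#'
#' @param model a `bandit_model`.
#' @return list with elements `reset`, `predict`, `observe`.
#' @export
make_agent <- function(model) {
  params <- model$params
  switch(
    model$family,
    ql = , qlp = {
      st <- agent_state(params)
      list(
        reset = function() st <<- agent_state(params),
        predict = function() softmax_policy(qlp_logits(st, params)),
        observe = function(action, reward) {
          st <<- ql_update(st, action, reward, params)
          invisible(NULL)
        })
    },
    gql = {
      st <- agent_state(params)
      list(
        reset = function() st <<- agent_state(params),
        predict = function() softmax_policy(gql_logits(st, params)),
        observe = function(action, reward) {
          st <<- gql_update(st, action, reward, params)
          invisible(NULL)
        })
    },
    lin = {
      hist_a <- integer(0); hist_r <- integer(0)
      list(
        reset = function() { hist_a <<- integer(0); hist_r <<- integer(0) },
        predict = function() {
          f <- lin_features(hist_a, hist_r, params$J)
          lin_policy(f, params)
        },
        observe = function(action, reward) {
          hist_a <<- c(hist_a, action_to_int(action))
          hist_r <<- c(hist_r, as.integer(reward))
          invisible(NULL)
        })
    },
    rnn = {
      # the network consumes one input per trial: at trial t it is fed the
      # previous trial's (action, reward); the first trial after a reset
      # feeds the zero vector. reset() therefore performs the zero-input
      # step at once so that predict() is a pure readout of the state.
      st <- NULL
      do_reset <- function() {
        st <<- lstm_step(encode_input(NULL, NULL, params$n_actions),
                         rnn_state(params), params)
      }
      do_reset()
      list(
        reset = do_reset,
        predict = function() rnn_policy(st, params$V),
        observe = function(action, reward) {
          x <- encode_input(action_to_int(action), as.integer(reward),
                            params$n_actions)
          st <<- lstm_step(x, st, params)
          invisible(NULL)
        })
    })
}
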
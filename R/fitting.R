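#' Map between unconstrained and constrained parameter spaces
#'
#' Optimisation runs in an unconstrained space; learning rates are mapped
#' through the logistic function to \[0,1\], inverse temperatures through the
#' exponential to (0, Inf), and unbounded weights (kappa, B, K, C, all LIN
#' and network weights) through the identity. `transform_params()` maps an
#' unconstrained vector to the family's parameter container;
#' `inverse_transform_params()` is its exact inverse.
#'
#' @param family model family tag.
#' @param u unconstrained numeric vector (layouts: ql `(phi, beta)`; qlp
#'   `(phi, beta, kappa)`; gql `(Phi, Psi, B, K, C)` with `C` column-major;
#'   lin `(mu0, a/r/ar weights by lag)`; rnn the flat weight vector).
#' @param d,J,n_cells,n_actions family hyperparameters fixing the layout.
#' @return the constrained parameter container (resp. unconstrained vector).
#' @export
transform_params <- function(family, u, d = NULL, J = NULL, n_cells = NULL,
                             n_actions = 2L) {
  switch(family,
    ql = {
      stopifnot(length(u) == 2)
      ql_params(sigmoid(u[1]), exp(u[2]))
    },
    qlp = {
      stopifnot(length(u) == 3)
      qlp_params(sigmoid(u[1]), exp(u[2]), u[3])
    },
    gql = {
      stopifnot(length(u) == count_gql_params(d))
      gql_unflatten(u, d)
    },
    lin = {
      stopifnot(length(u) == 1 + 3 * J)
      if (J > 0) {
        lag <- matrix(u[-1], nrow = 3)
        lin_params(J, u[1], lag[1, ], lag[2, ], lag[3, ])
      } else lin_params(0L, u[1])
    },
    rnn = rnn_unflatten(u, n_cells, n_actions),
    stop("unknown family"))
}

#' @rdname transform_params
#' @param params a constrained parameter container.
#' @export
inverse_transform_params <- function(params) {
  if (inherits(params, "gql_params")) return(gql_flatten(params))
  if (inherits(params, "rnn_params")) return(rnn_flatten(params))
  if (inherits(params, "lin_params")) {
    return(c(params$mu0,
             as.numeric(rbind(params$mu, params$gamma, params$zeta))))
  }
  if (inherits(params, "qlp_params")) {
    return(c(stats::qlogis(params$phi), log(params$beta), params$kappa))
  }
  if (inherits(params, "ql_params")) {
    return(c(stats::qlogis(params$phi), log(params$beta)))
  }
  stop("unknown parameter container")
}

#' Fitting configuration
#'
#' @param optimizer `"auto"` (L-BFGS-B for the value models, Adam for the
#'   network), `"lbfgs"`, or `"adam"`.
#' @param step_size Adam step size.
#' @param max_iterations maximum full-cohort gradient steps (Adam).
#' @param checkpoint_every store a parameter snapshot every this many
#'   iterations; the snapshots form the early-stopping grid.
#' @param seed seed for restarts and the network's initial weights.
#' @param reset_per_block reset model state at block boundaries.
#' @param n_restarts random restarts for the value models (first start is
#'   always the neutral origin).
#' @return a `fit_config` list.
#' @export
fit_config <- function(optimizer = c("auto", "lbfgs", "adam"),
                       step_size = 0.01, max_iterations = 2000L,
                       checkpoint_every = 100L, seed = 1L,
                       reset_per_block = TRUE, n_restarts = 5L) {
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(optimizer = match.arg(optimizer), step_size = step_size,
                 max_iterations = as.integer(max_iterations),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed), reset_per_block = reset_per_block,
                 n_restarts = as.integer(n_restarts)),
            class = "fit_config")
}

# Full-batch Adam with iteration checkpointing.
adam_optim <- function(fn, u0, step_size, max_iterations, checkpoint_every) {
  u <- u0
  m <- v <- numeric(length(u))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  checkpoints <- list(`0` = u0)
  log <- data.frame(iteration = integer(0), nll = numeric(0))
  res <- fn(u)
  log <- rbind(log, data.frame(iteration = 0L, nll = res$nll))
  for (it in seq_len(max_iterations)) {
    g <- res$grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^it)
    vh <- v / (1 - b2^it)
    u <- u - step_size * mh / (sqrt(vh) + eps)
    res <- fn(u)
    if (!is.finite(res$nll)) {
      stop(sprintf("optimisation diverged at iteration %d (NLL not finite)",
                   it))
    }
    if (it %% checkpoint_every == 0L || it == max_iterations) {
      checkpoints[[as.character(it)]] <- u
      log <- rbind(log, data.frame(iteration = it, nll = res$nll))
    }
  }
  list(par = u, value = res$nll, checkpoints = checkpoints, log = log)
}

# L-BFGS-B with cached objective/gradient (optim calls fn and gr separately).
lbfgs_optim <- function(fn, u0, bound = 25) {
  cache_u <- NULL; cache <- NULL
  eval_at <- function(u) {
    if (is.null(cache_u) || !identical(u, cache_u)) {
      cache_u <<- u
      cache <<- fn(u)
    }
    cache
  }
  res <- stats::optim(u0,
                      fn = function(u) eval_at(u)$nll,
                      gr = function(u) eval_at(u)$grad,
                      method = "L-BFGS-B",
                      lower = rep(-bound, length(u0)),
                      upper = rep(bound, length(u0)),
                      control = list(maxit = 500L))
  list(par = res$par, value = res$value,
       checkpoints = list(`0` = u0, final = res$par),
       log = data.frame(iteration = c(0L, NA_integer_),
                        nll = c(fn(u0)$nll, res$value)))
}

#' Maximum-likelihood fit of a model family to a cohort
#'
#' Minimises the cohort negative log-likelihood in the unconstrained
#' parameter space using the exact analytic gradient. One model is fitted to
#' all subjects in the cohort (a single parameter set per group). The LIN
#' family is fitted by binomial logistic regression on its lagged design
#' matrix; the value models (QL/QLP/GQL) default to L-BFGS-B with seeded
#' random restarts; the network always uses Adam, starting from the fixed
#' seeded initial network of its size, with parameter snapshots stored every
#' `checkpoint_every` iterations as the early-stopping grid.
#'
#' @param family `"ql"`, `"qlp"`, `"gql"`, `"lin"` or `"rnn"`.
#' @param sessions cohort data frame.
#' @param config a [fit_config()].
#' @param d GQL trace count.
#' @param J LIN lag depth.
#' @param n_cells LSTM cell count.
#' @param init optional initial parameter container (overrides the default
#'   start).
#' @return a `bandit_fit`: list with the fitted `model`, `train_nll`, the
#'   `checkpoints` map, the iteration `log` and the `config` echo.
#' @export
fit_ml <- function(family = c("ql", "qlp", "gql", "lin", "rnn"), sessions,
                   config = fit_config(), d = 2L, J = 18L, n_cells = 10L,
                   init = NULL) {
  family <- match.arg(family)
  if (nrow(sessions) == 0) stop("empty cohort")
  sessions <- validate_sessions(sessions)

  if (family == "lin") {
    model <- fit_lin_glm(sessions, J = J,
                         reset_per_block = config$reset_per_block)
    nll <- cohort_negative_log_likelihood(model, sessions)
    return(structure(list(family = family, model = model, train_nll = nll,
                          checkpoints = list(), config = config,
                          log = data.frame(iteration = 0L, nll = nll),
                          hyper = list(J = J)),
                     class = "bandit_fit"))
  }

  tensors <- cohort_tensors(sessions)
  obj <- switch(family,
    ql = function(u) nll_qlp(u, tensors, perseveration = FALSE,
                             reset_per_block = config$reset_per_block),
    qlp = function(u) nll_qlp(u, tensors, perseveration = TRUE,
                              reset_per_block = config$reset_per_block),
    gql = function(u) nll_gql(u, tensors, d = d,
                              reset_per_block = config$reset_per_block),
    rnn = function(u) nll_rnn(u, tensors, n_cells = n_cells,
                              reset_per_block = config$reset_per_block))
  npar <- switch(family, ql = 2L, qlp = 3L, gql = count_gql_params(d),
                 rnn = count_rnn_params(n_cells, 2L))
  use_adam <- config$optimizer == "adam" ||
    (config$optimizer == "auto" && family == "rnn")

  if (family == "rnn") {
    u0 <- if (is.null(init)) rnn_flatten(rnn_params(n_cells, 2L,
                                                    seed = config$seed))
          else rnn_flatten(init)
    res <- if (use_adam) {
      adam_optim(obj, u0, config$step_size, config$max_iterations,
                 config$checkpoint_every)
    } else lbfgs_optim(obj, u0)
  } else {
    # Neutral first start. For GQL the exact origin is a fixed point of the
    # trace-permutation symmetry (identical learning rates keep all traces
    # identical under gradient flow), so its learning rates are staggered.
    neutral <- numeric(npar)
    if (family == "gql" && d > 1) {
      stag <- stats::qlogis(seq(0.6, 0.15, length.out = d))
      neutral[seq_len(d)] <- stag
      neutral[d + seq_len(d)] <- stag
    }
    starts <- list(if (is.null(init)) neutral else
      inverse_transform_params(init))
    if (config$n_restarts > 1L && is.null(init)) {
      extra <- with_seed(config$seed, lapply(
        seq_len(config$n_restarts - 1L),
        function(i) stats::rnorm(npar)))
      starts <- c(starts, extra)
    }
    runs <- lapply(starts, function(u0) {
      if (use_adam) {
        adam_optim(obj, u0, config$step_size, config$max_iterations,
                   config$checkpoint_every)
      } else lbfgs_optim(obj, u0)
    })
    res <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  }

  params <- transform_params(family, res$par, d = d, J = J,
                             n_cells = n_cells)
  if (family == "gql") params <- canonicalize_gql(params)
  model <- bandit_model(family, params,
                        reset_per_block = config$reset_per_block)
  structure(list(family = family, model = model, train_nll = res$value,
                 checkpoints = res$checkpoints, config = config,
                 log = res$log,
                 hyper = list(d = d, n_cells = n_cells)),
            class = "bandit_fit")
}

#' @export
print.bandit_fit <- function(x, ...) {
  cat(sprintf("<bandit_fit: %s, train NLL %.3f, %d checkpoint(s)>\n",
              x$family, x$train_nll, length(x$checkpoints)))
  invisible(x)
}

#' Rebuild the model at a stored training checkpoint
#'
#' Used for early stopping: a fit trained for many iterations can be
#' evaluated at any stored iteration count.
#'
#' @param fit a `bandit_fit` with checkpoints.
#' @param iteration stored iteration number.
#' @return a `bandit_model`.
#' @export
fit_at_iteration <- function(fit, iteration) {
  key <- as.character(iteration)
  if (!key %in% names(fit$checkpoints)) {
    stop(sprintf("no checkpoint at iteration %s (stored: %s)", key,
                 paste(names(fit$checkpoints), collapse = ", ")))
  }
  params <- transform_params(fit$family, fit$checkpoints[[key]],
                             d = fit$hyper$d, J = fit$hyper$J,
                             n_cells = fit$hyper$n_cells)
  bandit_model(fit$family, params,
               reset_per_block = fit$config$reset_per_block)
}
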
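#' Lagged logistic-regression model parameters
#'
#' The LIN model sets the log-odds of choosing L over R at trial `t` to
#' `mu0 + sum_j (mu_j a_{t-j} + gamma_j r_{t-j} + zeta_j a_{t-j} r_{t-j})`
#' over lags `j = 1..J`. Actions are coded L = +1, R = -1 so that trials
#' before the start of the conditioning window contribute 0 and `mu0` is a
#' pure side bias; rewards are the raw 0/1. The coding convention is
#' harmless: relabelling L and R maps a fit to its mirror image (negate
#' `mu0` and `gamma`; `mu` and `zeta` are unchanged) without altering the
#' predicted probabilities of the relabelled actions.
#' `J = 0` leaves only the intercept. The model has `1 + 3J` free
#' parameters; `J = 18` is the default lag depth.
#'
#' @param J non-negative lag depth.
#' @param mu0 intercept (side bias).
#' @param mu,gamma,zeta length-`J` weights on lagged actions, rewards and
#'   their interactions.
#' @return a `lin_params` object.
#' @export
lin_params <- function(J, mu0 = 0, mu = numeric(J), gamma = numeric(J),
                       zeta = numeric(J)) {
  J <- as.integer(J)
  if (J < 0) stop("J must be >= 0")
  if (length(mu) != J || length(gamma) != J || length(zeta) != J) {
    stop("mu, gamma, zeta must have length J")
  }
  structure(list(J = J, mu0 = mu0, mu = mu, gamma = gamma, zeta = zeta),
            class = "lin_params")
}

#' Lagged feature vector for one trial
#'
#' Given the actions and rewards observed so far in the current conditioning
#' window (a block, under the default reset convention), returns the length
#' `3J` vector `(a_{t-1}, r_{t-1}, a_{t-1} r_{t-1}, a_{t-2}, ...)` with
#' actions coded +1 (L) / -1 (R). Lags reaching past the start of the window
#' are zero.
#'
#' @param hist_actions integer/character actions already observed, oldest
#'   first.
#' @param hist_rewards matching 0/1 rewards.
#' @param J lag depth.
#' @return numeric vector of length `3J` (feature order: a, r, a*r per lag).
#' @export
lin_features <- function(hist_actions, hist_rewards, J) {
  n <- length(hist_actions)
  feats <- numeric(3L * J)
  if (J == 0L || n == 0L) return(feats)
  a_pm <- ifelse(action_to_int(hist_actions) == 1L, 1, -1)
  r <- as.numeric(hist_rewards)
  for (j in seq_len(min(J, n))) {
    idx <- n - j + 1L
    feats[3L * (j - 1L) + 1:3] <- c(a_pm[idx], r[idx], a_pm[idx] * r[idx])
  }
  feats
}

#' LIN choice probabilities
#'
#' @param features length `3J` feature vector from [lin_features()].
#' @param params a `lin_params`.
#' @return probability vector `c(p_L, p_R)`.
#' @export
lin_policy <- function(features, params) {
  if (length(features) != 3L * params$J) stop("feature length must be 3J")
  w <- as.numeric(rbind(params$mu, params$gamma, params$zeta))
  p_l <- sigmoid(params$mu0 + sum(features * w))
  c(p_l, 1 - p_l)
}

# Lagged design matrix for a cohort: one row per trial, response = 1 if L.
# Lags never cross block boundaries when reset_per_block (zero padding).
lin_design <- function(sessions, J, reset_per_block = TRUE) {
  sessions <- validate_sessions(sessions)
  rows <- vector("list", length(unique(sessions$subject_id)))
  X <- matrix(0, nrow(sessions), 3L * J)
  y <- integer(nrow(sessions))
  pos <- 0L
  for (ses in split_sessions(sessions)) {
    a <- action_to_int(ses$action)
    r <- as.integer(ses$reward)
    windows <- if (reset_per_block) split(seq_len(nrow(ses)), ses$block) else
      list(seq_len(nrow(ses)))
    for (idx in windows) {
      for (k in seq_along(idx)) {
        pos <- pos + 1L
        prior <- idx[seq_len(k - 1L)]
        if (J > 0L) X[pos, ] <- lin_features(a[prior], r[prior], J)
        y[pos] <- as.integer(a[idx[k]] == 1L)
      }
    }
  }
  if (J > 0L) {
    colnames(X) <- as.vector(vapply(
      seq_len(J), function(j) paste0(c("a", "r", "ar"), j), character(3)))
  }
  list(X = X[seq_len(pos), , drop = FALSE], y = y[seq_len(pos)])
}

# Fit LIN by binomial logistic regression (the glm route). Coefficients are
# capped at +/- cap to keep separation cases finite.
fit_lin_glm <- function(sessions, J = 18L, reset_per_block = TRUE, cap = 15) {
  dm <- lin_design(sessions, J, reset_per_block)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, dm$X), dm$y,
                   family = stats::binomial()))
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0
  coefs <- pmin(pmax(coefs, -cap), cap)
  if (J > 0L) {
    lag_mat <- matrix(coefs[-1], nrow = 3L) # rows: a, r, ar
    params <- lin_params(J, mu0 = coefs[1], mu = lag_mat[1, ],
                         gamma = lag_mat[2, ], zeta = lag_mat[3, ])
  } else {
    params <- lin_params(0L, mu0 = coefs[1])
  }
  bandit_model("lin", params, reset_per_block)
}
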
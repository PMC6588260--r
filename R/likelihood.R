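# Batched likelihood machinery.
#
# All fitting-path likelihoods run over a cohort laid out as S x T matrices
# (subjects x trials, right-padded with NA for unequal session lengths) so
# that the per-trial recursions vectorise across subjects. Each nll_* routine
# returns the cohort negative log-likelihood, its exact analytic gradient in
# the unconstrained parameter space (forward-mode accumulation for the value
# models, backpropagation through time for the LSTM), and optionally the full
# S x T matrix of predicted P(L) used for policy traces. Predicted
# probabilities are floored at PROB_FLOOR before taking logs.

PROB_FLOOR <- 1e-12

# Lay a cohort data frame out as padded S x T matrices.
cohort_tensors <- function(sessions) {
  sessions <- validate_sessions(sessions)
  per <- split_sessions(sessions)
  S <- length(per)
  Tmax <- max(vapply(per, nrow, integer(1)))
  A <- matrix(NA_integer_, S, Tmax)
  R <- matrix(NA_real_, S, Tmax)
  newblock <- matrix(FALSE, S, Tmax)
  for (s in seq_len(S)) {
    ses <- per[[s]]
    n <- nrow(ses)
    A[s, seq_len(n)] <- action_to_int(ses$action)
    R[s, seq_len(n)] <- as.numeric(ses$reward)
    nb <- c(TRUE, ses$block[-1] != ses$block[-n])
    newblock[s, seq_len(n)] <- nb
  }
  list(A = A, R = R, newblock = newblock, mask = !is.na(A),
       subjects = names(per), n_trials = vapply(per, nrow, integer(1)))
}

log_floor <- function(p) log(pmax(p, PROB_FLOOR))

# --- QL / QLP --------------------------------------------------------------

# Unconstrained layout: c(phi_u, beta_u[, kappa]); phi = sigmoid(phi_u),
# beta = exp(beta_u), kappa unbounded.
nll_qlp <- function(u, tensors, perseveration = TRUE, reset_per_block = TRUE,
                    grad = TRUE, trace = FALSE) {
  phi <- sigmoid(u[1]); beta <- exp(u[2])
  kappa <- if (perseveration) u[3] else 0
  A <- tensors$A; R <- tensors$R; mask <- tensors$mask
  S <- nrow(A); Tmax <- ncol(A)

  QL <- QR <- dQL <- dQR <- numeric(S)
  prev <- integer(S)                       # 0 = no previous action
  nll <- 0
  g_phi <- g_beta <- g_kappa <- 0
  pmat <- if (trace) matrix(NA_real_, S, Tmax) else NULL

  for (t in seq_len(Tmax)) {
    if (reset_per_block) {
      rs <- tensors$newblock[, t]
      if (any(rs)) {
        QL[rs] <- 0; QR[rs] <- 0; dQL[rs] <- 0; dQR[rs] <- 0; prev[rs] <- 0L
      }
    }
    kdiff <- (prev == 1L) - (prev == 2L)
    delta <- QL - QR
    logitdiff <- beta * delta + kappa * kdiff
    pL <- sigmoid(logitdiff)
    if (trace) pmat[, t] <- ifelse(mask[, t], pL, NA_real_)

    v <- mask[, t]
    a <- A[, t]
    ind <- as.numeric(a == 1L)
    p_taken <- ifelse(ind == 1, pL, 1 - pL)
    nll <- nll - sum(log_floor(p_taken[v]))
    if (grad) {
      e <- (ind - pL)[v]                  # d log p(a) / d logitdiff
      g_beta <- g_beta - sum(e * delta[v])
      g_phi <- g_phi - sum(e * beta * (dQL - dQR)[v])
      if (perseveration) g_kappa <- g_kappa - sum(e * kdiff[v])
    }

    i1 <- which(v & a == 1L)
    if (length(i1)) {
      r1 <- R[i1, t]
      dQL[i1] <- (1 - phi) * dQL[i1] + (r1 - QL[i1])
      QL[i1] <- (1 - phi) * QL[i1] + phi * r1
    }
    i2 <- which(v & a == 2L)
    if (length(i2)) {
      r2 <- R[i2, t]
      dQR[i2] <- (1 - phi) * dQR[i2] + (r2 - QR[i2])
      QR[i2] <- (1 - phi) * QR[i2] + phi * r2
    }
    prev[v] <- a[v]
  }

  gr <- NULL
  if (grad) {
    gr <- c(g_phi * phi * (1 - phi), g_beta * beta)
    if (perseveration) gr <- c(gr, g_kappa)
  }
  list(nll = nll, grad = gr, pL = pmat)
}

# --- GQL -------------------------------------------------------------------

gql_unflatten <- function(u, d) {
  Phi <- sigmoid(u[seq_len(d)])
  Psi <- sigmoid(u[d + seq_len(d)])
  B <- u[2 * d + seq_len(d)]
  K <- u[3 * d + seq_len(d)]
  C <- matrix(u[4 * d + seq_len(d * d)], d, d)
  gql_params(Phi, Psi, B, K, C)
}

gql_flatten <- function(params) {
  c(stats::qlogis(params$Phi), stats::qlogis(params$Psi),
    params$B, params$K, as.numeric(params$C))
}

nll_gql <- function(u, tensors, d, reset_per_block = TRUE,
                    grad = TRUE, trace = FALSE) {
  p <- gql_unflatten(u, d)
  Phi <- p$Phi; Psi <- p$Psi; B <- p$B; K <- p$K; C <- p$C
  A <- tensors$A; R <- tensors$R; mask <- tensors$mask
  S <- nrow(A); Tmax <- ncol(A)

  zero <- matrix(0, S, d)
  QLm <- QRm <- HLm <- HRm <- zero                  # states
  dQLm <- dQRm <- dHLm <- dHRm <- zero              # d/dPhi_i, d/dPsi_i
  nll <- 0
  gPhi <- gPsi <- gB <- gK <- numeric(d)
  gC <- matrix(0, d, d)
  pmat <- if (trace) matrix(NA_real_, S, Tmax) else NULL
  tC <- t(C)

  # row-broadcast copies of the rate/weight vectors, built once
  PhiR <- matrix(Phi, S, d, byrow = TRUE); omPhiR <- 1 - PhiR
  PsiR <- matrix(Psi, S, d, byrow = TRUE); omPsiR <- 1 - PsiR
  BR <- matrix(B, S, d, byrow = TRUE)
  KR <- matrix(K, S, d, byrow = TRUE)

  for (t in seq_len(Tmax)) {
    if (reset_per_block) {
      rs <- tensors$newblock[, t]
      if (any(rs)) {
        QLm[rs, ] <- 0; QRm[rs, ] <- 0; HLm[rs, ] <- 0; HRm[rs, ] <- 0
        dQLm[rs, ] <- 0; dQRm[rs, ] <- 0; dHLm[rs, ] <- 0; dHRm[rs, ] <- 0
      }
    }
    HLC <- HLm %*% C; HRC <- HRm %*% C              # rows: sum_i H_i C_i.
    lL <- drop(QLm %*% B) + drop(HLm %*% K) + rowSums(HLC * QLm)
    lR <- drop(QRm %*% B) + drop(HRm %*% K) + rowSums(HRC * QRm)
    pL <- sigmoid(lL - lR)
    if (trace) pmat[, t] <- ifelse(mask[, t], pL, NA_real_)

    v <- mask[, t]
    a <- A[, t]
    ind <- as.numeric(!is.na(a) & a == 1L)
    p_taken <- ifelse(ind == 1, pL, 1 - pL)
    nll <- nll - sum(log_floor(p_taken[v]))

    if (grad) {
      e <- ifelse(v, ind - pL, 0)
      gB <- gB - drop(crossprod(QLm - QRm, e))
      gK <- gK - drop(crossprod(HLm - HRm, e))
      gC <- gC - (crossprod(HLm * e, QLm) - crossprod(HRm * e, QRm))
      # value learning rates: d logit / d Q_i = B_i + sum_j H_j C_ji
      gPhi <- gPhi - drop(crossprod((BR + HLC) * dQLm - (BR + HRC) * dQRm,
                                    e))
      # history learning rates: d logit / d H_i = K_i + sum_j C_ij Q_j
      gPsi <- gPsi - drop(crossprod((KR + QLm %*% tC) * dHLm -
                                      (KR + QRm %*% tC) * dHRm, e))
    }

    # indicator columns: 1 where the subject validly took L (resp. R)
    v1 <- as.numeric(v & !is.na(a) & a == 1L)
    v2 <- as.numeric(v & !is.na(a) & a == 2L)
    r0 <- ifelse(v, R[, t], 0); r0[is.na(r0)] <- 0

    # value update (taken action only); dQ uses the pre-update Q
    dQLm <- dQLm + v1 * (omPhiR * dQLm - dQLm + (r0 - QLm))
    QLm <- QLm + v1 * (PhiR * (r0 - QLm))
    dQRm <- dQRm + v2 * (omPhiR * dQRm - dQRm + (r0 - QRm))
    QRm <- QRm + v2 * (PhiR * (r0 - QRm))

    # history update (all actions: taken toward 1, untaken toward 0)
    vv <- v1 + v2
    tgtL <- v1; tgtR <- v2
    dHLm <- dHLm + vv * (omPsiR * dHLm - dHLm + (tgtL - HLm))
    HLm <- HLm + vv * (PsiR * (tgtL - HLm))
    dHRm <- dHRm + vv * (omPsiR * dHRm - dHRm + (tgtR - HRm))
    HRm <- HRm + vv * (PsiR * (tgtR - HRm))
  }

  gr <- NULL
  if (grad) {
    gr <- c(gPhi * Phi * (1 - Phi), gPsi * Psi * (1 - Psi), gB, gK,
            as.numeric(gC))
  }
  list(nll = nll, grad = gr, pL = pmat)
}

# --- RNN (LSTM) ------------------------------------------------------------

# Batched forward + backpropagation through time. `u` is the flat parameter
# vector in rnn_flatten() order (all parameters unbounded, so constrained and
# unconstrained coordinates coincide).
nll_rnn <- function(u, tensors, n_cells, n_actions = 2L,
                    reset_per_block = TRUE, grad = TRUE, trace = FALSE) {
  p <- rnn_unflatten(u, n_cells, n_actions)
  A <- tensors$A; R <- tensors$R; mask <- tensors$mask
  S <- nrow(A); Tmax <- ncol(A)
  Nc <- n_cells
  n_in <- n_actions + 1L

  tW_f <- t(p$W_f); tW_i <- t(p$W_i); tW_o <- t(p$W_o); tW_c <- t(p$W_c)
  tU_f <- t(p$U_f); tU_i <- t(p$U_i); tU_o <- t(p$U_o); tU_c <- t(p$U_c)
  bfR <- matrix(p$b_f, S, Nc, byrow = TRUE)
  biR <- matrix(p$b_i, S, Nc, byrow = TRUE)
  boR <- matrix(p$b_o, S, Nc, byrow = TRUE)
  bcR <- matrix(p$b_c, S, Nc, byrow = TRUE)

  Cst <- Hst <- matrix(0, S, Nc)
  store <- vector("list", Tmax)
  nll <- 0
  pmat <- if (trace) matrix(NA_real_, S, Tmax) else NULL

  for (t in seq_len(Tmax)) {
    reset_rows <- if (reset_per_block) tensors$newblock[, t] else
      rep(t == 1L, S)
    if (any(reset_rows)) {
      Cst[reset_rows, ] <- 0; Hst[reset_rows, ] <- 0
    }
    # input: one-hot previous action + previous reward, zero after a reset
    X <- matrix(0, S, n_in)
    if (t > 1L) {
      pa <- A[, t - 1L]; pr <- R[, t - 1L]
      ok <- !reset_rows & !is.na(pa)
      if (any(ok)) {
        X[cbind(which(ok), pa[ok])] <- 1
        X[ok, n_in] <- pr[ok]
      }
    }
    Cprev <- Cst; Hprev <- Hst
    F_ <- sigmoid(X %*% tW_f + Hprev %*% tU_f + bfR)
    I_ <- sigmoid(X %*% tW_i + Hprev %*% tU_i + biR)
    O_ <- sigmoid(X %*% tW_o + Hprev %*% tU_o + boR)
    G_ <- tanh(X %*% tW_c + Hprev %*% tU_c + bcR)
    Cst <- F_ * Cprev + I_ * G_
    tC <- tanh(Cst)
    Hst <- O_ * tC

    Z <- Hst %*% p$V
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z)
    P <- P / rowSums(P)
    if (trace) pmat[, t] <- ifelse(mask[, t], P[, 1], NA_real_)

    v <- mask[, t]
    idx <- cbind(which(v), A[v, t])
    nll <- nll - sum(log_floor(P[idx]))
    store[[t]] <- list(X = X, Cprev = Cprev, Hprev = Hprev, F = F_, I = I_,
                       O = O_, G = G_, tC = tC, H = Hst, P = P,
                       reset = reset_rows, v = v, idx = idx)
  }

  if (!grad) return(list(nll = nll, grad = NULL, pL = pmat))

  gW_f <- matrix(0, Nc, n_in); gW_i <- gW_f; gW_o <- gW_f; gW_c <- gW_f
  gU_f <- matrix(0, Nc, Nc); gU_i <- gU_f; gU_o <- gU_f; gU_c <- gU_f
  gb_f <- numeric(Nc); gb_i <- gb_f; gb_o <- gb_f; gb_c <- gb_f
  gV <- matrix(0, Nc, n_actions)
  dH_carry <- dC_carry <- matrix(0, S, Nc)

  for (t in rev(seq_len(Tmax))) {
    st <- store[[t]]
    dZ <- st$P
    dZ[!st$v, ] <- 0
    dZ[st$idx] <- dZ[st$idx] - 1
    gV <- gV + crossprod(st$H, dZ)
    dH <- tcrossprod(dZ, p$V) + dH_carry      # dZ %*% t(V)
    dC <- dC_carry + dH * st$O * (1 - st$tC^2)
    dO <- dH * st$tC
    dF <- dC * st$Cprev
    dI <- dC * st$G
    dG <- dC * st$I

    zF <- dF * st$F * (1 - st$F)
    zI <- dI * st$I * (1 - st$I)
    zO <- dO * st$O * (1 - st$O)
    zG <- dG * (1 - st$G^2)

    gW_f <- gW_f + crossprod(zF, st$X); gU_f <- gU_f + crossprod(zF, st$Hprev)
    gW_i <- gW_i + crossprod(zI, st$X); gU_i <- gU_i + crossprod(zI, st$Hprev)
    gW_o <- gW_o + crossprod(zO, st$X); gU_o <- gU_o + crossprod(zO, st$Hprev)
    gW_c <- gW_c + crossprod(zG, st$X); gU_c <- gU_c + crossprod(zG, st$Hprev)
    gb_f <- gb_f + colSums(zF); gb_i <- gb_i + colSums(zI)
    gb_o <- gb_o + colSums(zO); gb_c <- gb_c + colSums(zG)

    dH_carry <- zF %*% p$U_f + zI %*% p$U_i + zO %*% p$U_o + zG %*% p$U_c
    dC_carry <- dC * st$F
    # no gradient flows across a state reset
    if (any(st$reset)) {
      dH_carry[st$reset, ] <- 0
      dC_carry[st$reset, ] <- 0
    }
  }

  gr <- c(as.numeric(gW_f), as.numeric(gW_i), as.numeric(gW_o),
          as.numeric(gW_c), as.numeric(gU_f), as.numeric(gU_i),
          as.numeric(gU_o), as.numeric(gU_c), gb_f, gb_i, gb_o, gb_c,
          as.numeric(gV))
  list(nll = nll, grad = gr, pL = pmat)
}

# --- LIN -------------------------------------------------------------------

# P(L) for every trial of a cohort under a lin model, as an S x T matrix.
lin_trace_matrix <- function(model, tensors, sessions) {
  dm <- lin_design(sessions, model$params$J, model$reset_per_block)
  w <- c(model$params$mu0,
         as.numeric(rbind(model$params$mu, model$params$gamma,
                          model$params$zeta)))
  pl <- sigmoid(drop(cbind(1, dm$X) %*% w))
  pmat <- matrix(NA_real_, nrow(tensors$A), ncol(tensors$A))
  pos <- 0L
  for (s in seq_len(nrow(tensors$A))) {
    n <- tensors$n_trials[s]
    pmat[s, seq_len(n)] <- pl[pos + seq_len(n)]
    pos <- pos + n
  }
  pmat
}

# --- shared front ends -----------------------------------------------------

# Dispatch a (constrained) bandit_model to its batched likelihood.
model_nll_impl <- function(model, tensors, sessions = NULL, grad = FALSE,
                           trace = FALSE) {
  switch(
    model$family,
    ql = nll_qlp(c(stats::qlogis(model$params$phi), log(model$params$beta)),
                 tensors, perseveration = FALSE,
                 reset_per_block = model$reset_per_block, grad = grad,
                 trace = trace),
    qlp = nll_qlp(c(stats::qlogis(model$params$phi), log(model$params$beta),
                    model$params$kappa),
                  tensors, perseveration = TRUE,
                  reset_per_block = model$reset_per_block, grad = grad,
                  trace = trace),
    gql = nll_gql(gql_flatten(model$params), tensors, d = model$params$d,
                  reset_per_block = model$reset_per_block, grad = grad,
                  trace = trace),
    rnn = nll_rnn(rnn_flatten(model$params), tensors,
                  n_cells = model$params$n_cells,
                  n_actions = model$params$n_actions,
                  reset_per_block = model$reset_per_block, grad = grad,
                  trace = trace),
    lin = {
      pmat <- lin_trace_matrix(model, tensors, sessions)
      p_taken <- ifelse(tensors$A == 1L, pmat, 1 - pmat)
      list(nll = -sum(log_floor(p_taken[tensors$mask])), grad = NULL,
           pL = pmat)
    })
}

#' Cohort negative log-likelihood
#'
#' The summed negative log-probability a model assigns to every action every
#' subject actually took, the quantity minimised during maximum-likelihood
#' fitting. Probabilities are floored at 1e-12 before the log.
#'
#' @param model a `bandit_model`.
#' @param sessions cohort data frame (see [validate_sessions()]).
#' @return non-negative scalar.
#' @export
cohort_negative_log_likelihood <- function(model, sessions) {
  if (nrow(sessions) == 0) stop("empty cohort")
  tensors <- cohort_tensors(sessions)
  model_nll_impl(model, tensors, sessions)$nll
}

#' Per-trial policy trace for one session
#'
#' The strictly causal sequence of predicted action probabilities: the
#' prediction for trial `t` depends only on the actions and rewards observed
#' before `t` (within the current block, under the per-block reset
#' convention).
#'
#' @param model a `bandit_model`.
#' @param session one subject's trials.
#' @return data frame with columns `p_L`, `p_R`, one row per trial.
#' @export
policy_trace <- function(model, session) {
  if (nrow(session) == 0) stop("empty session")
  if (!"subject_id" %in% names(session)) session$subject_id <- "s1"
  if (!"group" %in% names(session)) session$group <- "unknown"
  if (!"trial" %in% names(session)) session$trial <- seq_len(nrow(session))
  tensors <- cohort_tensors(session)
  res <- model_nll_impl(model, tensors, session, trace = TRUE)
  p_l <- res$pL[1, seq_len(nrow(session))]
  data.frame(p_L = p_l, p_R = 1 - p_l)
}
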
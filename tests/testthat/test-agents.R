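test_that("softmax policy matches closed forms and is shift/overflow safe", {
  expect_equal(softmax_policy(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_policy(c(1, 0)), c(0.7310586, 0.2689414),
               tolerance = 1e-6)
  shifted <- softmax_policy(c(1, 0) + 123.4)
  expect_equal(shifted, softmax_policy(c(1, 0)), tolerance = 1e-12)
  big <- softmax_policy(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  expect_error(softmax_policy(c(NaN, 0)), "finite")
})

test_that("QL value update follows the learning rule", {
  p <- ql_params(phi = 0.1, beta = 1)
  st <- list(Q = c(0.5, 0.2), last_action = NA_integer_)
  st2 <- ql_update(st, "L", 1, p)
  expect_equal(st2$Q, c(0.55, 0.2))   # (1-0.1)*0.5 + 0.1*1
  # phi = 0: no learning; phi = 1: full replacement
  expect_equal(ql_update(st, "L", 1, ql_params(0, 2))$Q, st$Q)
  expect_equal(ql_update(st, "R", 0, ql_params(1, 2))$Q[2], 0)
})

test_that("QLP logits add the perseveration kernel", {
  p <- qlp_params(0.1, beta = 1, kappa = 2)
  st <- list(Q = c(0, 0), last_action = 1L)
  expect_equal(softmax_policy(qlp_logits(st, p))[1], plogis(2),
               tolerance = 1e-10)   # 0.8808
  p$kappa <- -2
  expect_equal(softmax_policy(qlp_logits(st, p))[1], plogis(-2),
               tolerance = 1e-10)   # alternation, 0.1192
  # first trial: no kernel
  st$last_action <- NA_integer_
  expect_equal(softmax_policy(qlp_logits(st, p)), c(0.5, 0.5))
})

test_that("GQL free-parameter count is 4d + d^2", {
  expect_identical(count_gql_params(1), 5L)
  expect_identical(count_gql_params(2), 12L)
  expect_identical(count_gql_params(10), 140L)
  expect_error(count_gql_params(0), "d must be")
  # oracle: enumerate the scalars in the container itself
  for (d in c(1, 2, 10)) {
    p <- gql_params(rep(0.5, d), rep(0.5, d), rnorm(d), rnorm(d),
                    matrix(rnorm(d * d), d, d))
    n_scalars <- length(p$Phi) + length(p$Psi) + length(p$B) +
      length(p$K) + length(p$C)
    expect_identical(count_gql_params(d), as.integer(n_scalars))
  }
})

test_that("GQL update moves values and histories as specified", {
  p <- gql_params(Phi = c(0.1, 0.05), Psi = c(0.2, 0.1),
                  B = c(1, 1), K = c(0, 0))
  st <- agent_state(p)
  st2 <- gql_update(st, "L", 1, p)
  expect_equal(st2$Q[1, ], c(0.1, 0.05))   # worked example: Phi = [0.1, 0.05]
  expect_equal(st2$Q[2, ], c(0, 0))        # other action untouched
  expect_equal(st2$H[1, ], c(0.2, 0.1))    # taken action's history grows
  expect_equal(st2$H[2, ], c(0, 0))
  # Psi = 1: history becomes the last-action indicator
  p1 <- gql_params(0.5, 1, 1, 1)
  st <- gql_update(agent_state(p1), "L", 0, p1)
  expect_equal(c(st$H), c(1, 0))
  st <- gql_update(st, "R", 0, p1)
  expect_equal(c(st$H), c(0, 1))
})

test_that("GQL histories stay in [0,1] for arbitrary action sequences", {
  set.seed(5)
  p <- gql_params(runif(3), runif(3), rnorm(3), rnorm(3),
                  matrix(rnorm(9), 3, 3))
  st <- agent_state(p)
  for (t in 1:200) {
    st <- gql_update(st, sample(c("L", "R"), 1), rbinom(1, 1, 0.5), p)
    expect_true(all(st$H >= 0 & st$H <= 1))
  }
})

test_that("repeated reward drives the Q value to 1 geometrically", {
  p <- ql_params(0.3, 1)
  st <- agent_state(p)
  for (t in 1:40) st <- ql_update(st, "L", 1, p)
  expect_equal(st$Q[1], 1 - (1 - 0.3)^40, tolerance = 1e-12)
  expect_lt(abs(st$Q[1] - 1), 1e-5)
})

test_that("model nesting: QLP(kappa=0) is QL, GQL(d=1,Psi=1,C=0) is QLP", {
  for (rep in 1:10) {
    ses <- random_session(50, seed = 300 + rep)
    phi <- runif(1); beta <- exp(rnorm(1)); kappa <- rnorm(1)
    tr_ql <- policy_trace(bandit_model("ql", ql_params(phi, beta)), ses)
    tr_qlp0 <- policy_trace(bandit_model("qlp", qlp_params(phi, beta, 0)),
                            ses)
    expect_equal(tr_qlp0, tr_ql, tolerance = 1e-12)
    tr_qlp <- policy_trace(bandit_model("qlp", qlp_params(phi, beta, kappa)),
                           ses)
    tr_gql <- policy_trace(
      bandit_model("gql", gql_params(phi, 1, B = beta, K = kappa, C = 0)),
      ses)
    expect_equal(tr_gql, tr_qlp, tolerance = 1e-10)
  }
})

test_that("policies from every agent sum to one", {
  ses <- random_session(30, seed = 9, n_blocks = 3)
  models <- list(
    bandit_model("ql", ql_params(0.2, 2)),
    bandit_model("qlp", qlp_params(0.2, 2, -1)),
    bandit_model("gql", gql_params(c(0.3, 0.05), c(0.4, 0.02),
                                   c(-1, 5), c(1, 1),
                                   matrix(rnorm(4), 2, 2))),
    bandit_model("lin", lin_params(2, 0.3, c(0.5, 0.1), c(-0.2, 0),
                                   c(0.1, 0))),
    bandit_model("rnn", rnn_params(4, seed = 2)))
  for (m in models) {
    tr <- policy_trace(m, ses)
    expect_true(all(abs(tr$p_L + tr$p_R - 1) < 1e-12))
    expect_true(all(tr$p_L > 0 & tr$p_R > 0))
  }
})

test_that("zero GQL readout weights give a uniform policy", {
  m <- bandit_model("gql", gql_params(c(0.3, 0.1), c(0.3, 0.1),
                                      c(0, 0), c(0, 0), 0))
  tr <- policy_trace(m, random_session(20, seed = 4))
  expect_true(all(abs(tr$p_L - 0.5) < 1e-12))
})

test_that("canonical trace ordering leaves GQL policies unchanged", {
  set.seed(77)
  p <- gql_params(Phi = c(0.1, 0.7, 0.4), Psi = runif(3), B = rnorm(3),
                  K = rnorm(3), C = matrix(rnorm(9), 3, 3))
  pc <- canonicalize_gql(p)
  expect_equal(pc$Phi, sort(p$Phi, decreasing = TRUE))
  ses <- random_session(60, seed = 78, n_blocks = 2)
  expect_equal(policy_trace(bandit_model("gql", pc), ses),
               policy_trace(bandit_model("gql", p), ses),
               tolerance = 1e-12)
})
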
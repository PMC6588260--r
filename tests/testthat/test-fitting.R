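test_that("cohort negative log-likelihood matches hand-computed values", {
  ses <- random_cohort(3, 20, seed = 40)
  uniform <- bandit_model("gql", gql_params(0.5, 0.5, B = 0, K = 0, C = 0))
  expect_equal(cohort_negative_log_likelihood(uniform, ses), 60 * log(2),
               tolerance = 1e-10)
  # two trials with p(taken) = 0.8 and 0.5
  two <- toy_session(c("L", "L"), c(0, 0))
  mu0 <- qlogis(0.8)
  m <- bandit_model("lin", lin_params(0L, mu0))
  tr <- data.frame(p_L = c(0.8, 0.5), p_R = c(0.2, 0.5))
  expect_equal(-sum(log(c(0.8, 0.5))), 0.9162907, tolerance = 1e-6)
  expect_equal(nlp(tr, two) * 2, -(log(0.8) + log(0.5)), tolerance = 1e-12)
  expect_error(cohort_negative_log_likelihood(uniform, ses[0, ]), "empty")
})

test_that("parameter transforms invert exactly and map the origin sensibly", {
  p0 <- transform_params("ql", c(0, 0))
  expect_equal(p0$phi, 0.5)
  expect_equal(p0$beta, 1)
  # large negative rate coordinate stays strictly positive
  p_small <- transform_params("ql", c(-30, 0))
  expect_gt(p_small$phi, 0)
  set.seed(50)
  for (fam in c("ql", "qlp")) {
    n <- if (fam == "ql") 2 else 3
    u <- rnorm(n)
    expect_equal(inverse_transform_params(transform_params(fam, u)), u,
                 tolerance = 1e-10)
  }
  u <- rnorm(count_gql_params(3))
  expect_equal(inverse_transform_params(transform_params("gql", u, d = 3)),
               u, tolerance = 1e-10)
  u <- rnorm(1 + 3 * 4)
  expect_equal(inverse_transform_params(transform_params("lin", u, J = 4)),
               u, tolerance = 1e-12)
})

test_that("analytic likelihood gradients match central differences", {
  tens <- cohort_tensors(random_cohort(3, 30, seed = 60, n_blocks = 3))
  set.seed(61)
  expect_lt(grad_vs_fd(function(u, grad) {
    nll_qlp(u, tens, perseveration = FALSE, grad = grad)
  }, c(qlogis(0.4), log(2))), 1e-6)
  expect_lt(grad_vs_fd(function(u, grad) {
    nll_qlp(u, tens, perseveration = TRUE, grad = grad)
  }, c(qlogis(0.4), log(2), 0.7)), 1e-6)
  expect_lt(grad_vs_fd(function(u, grad) {
    nll_gql(u, tens, d = 2, grad = grad)
  }, rnorm(12, 0, 0.5)), 1e-6)
  expect_lt(grad_vs_fd(function(u, grad) {
    nll_rnn(u, tens, n_cells = 3, grad = grad)
  }, rnn_flatten(rnn_params(3, 2, seed = 62))), 1e-5)
})

test_that("Adam reduces the objective and stores the checkpoint grid", {
  ses <- random_cohort(2, 40, seed = 70)
  fit <- fit_ml("qlp", ses,
                config = fit_config(optimizer = "adam", step_size = 0.05,
                                    max_iterations = 120L,
                                    checkpoint_every = 40L, n_restarts = 1L))
  expect_lte(fit$train_nll, fit$log$nll[1])   # final <= initial
  expect_setequal(names(fit$checkpoints), c("0", "40", "80", "120"))
  m40 <- fit_at_iteration(fit, 40)
  expect_s3_class(m40, "bandit_model")
  expect_error(fit_at_iteration(fit, 37), "no checkpoint")
})

test_that("QL fitting recovers generating parameters", {
  truth <- ql_params(0.3, 3)
  sch <- build_schedule(seed = 5, trials_per_block = 80)
  ses <- do.call(rbind, lapply(1:8, function(i) {
    run_on_policy(bandit_model("ql", truth), sch, seed = 500 + i,
                  subject_id = paste0("s", i))
  }))
  fit <- fit_ml("ql", ses, config = fit_config(n_restarts = 2L))
  expect_lt(abs(fit$model$params$phi - 0.3), 0.07)
  expect_lt(abs(fit$model$params$beta - 3) / 3, 0.25)
})

test_that("richer nested models attain at least the nested model's fit", {
  ses <- random_cohort(3, 60, seed = 80, n_blocks = 2)
  f_ql <- fit_ml("ql", ses, config = fit_config(n_restarts = 2L))
  f_qlp <- fit_ml("qlp", ses, config = fit_config(n_restarts = 2L))
  f_gql <- fit_ml("gql", ses, config = fit_config(n_restarts = 2L), d = 1)
  expect_lte(f_qlp$train_nll, f_ql$train_nll + 1e-4)
  expect_lte(f_gql$train_nll, f_qlp$train_nll + 0.05)
})

test_that("fitting the generating model beats a mis-specified nested one", {
  truth <- qlp_params(0.25, 2.5, 1.5)
  sch <- build_schedule(seed = 6, trials_per_block = 60)
  ses <- do.call(rbind, lapply(1:6, function(i) {
    run_on_policy(bandit_model("qlp", truth), sch, seed = 600 + i,
                  subject_id = paste0("s", i))
  }))
  f_ql <- fit_ml("ql", ses, config = fit_config(n_restarts = 2L))
  f_qlp <- fit_ml("qlp", ses, config = fit_config(n_restarts = 2L))
  expect_lt(f_qlp$train_nll, f_ql$train_nll)
})
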
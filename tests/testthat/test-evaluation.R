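test_that("nlp and percent_correct follow their definitions", {
  ses <- toy_session(c("L", "R", "L", "L"), c(0, 1, 0, 0))
  uniform <- data.frame(p_L = rep(0.5, 4), p_R = rep(0.5, 4))
  expect_equal(nlp(uniform, ses), log(2), tolerance = 1e-12)
  expect_equal(percent_correct(uniform, ses), 0)   # exact ties incorrect
  oracle <- data.frame(p_L = c(1, 0, 1, 1), p_R = c(0, 1, 0, 0))
  expect_equal(nlp(oracle, ses), 0)
  expect_equal(percent_correct(oracle, ses), 100)
  # argmax right on 3 of 4 trials
  part <- data.frame(p_L = c(0.9, 0.2, 0.6, 0.3), p_R = c(0.1, 0.8, 0.4, 0.7))
  expect_equal(percent_correct(part, ses), 75)
  # mixed probabilities: mean of -log(0.8), -log(0.5)
  two <- toy_session(c("L", "L"), 0)
  tr <- data.frame(p_L = c(0.8, 0.5), p_R = c(0.2, 0.5))
  expect_equal(nlp(tr, two), 0.45814537, tolerance = 1e-7)
  expect_error(nlp(tr, ses), "mismatch")
})

test_that("cohort nlp equals the total NLL over total trials", {
  ses <- random_cohort(3, 25, seed = 90)
  m <- bandit_model("qlp", qlp_params(0.3, 2, 0.5))
  expect_equal(cohort_nlp(m, ses),
               cohort_negative_log_likelihood(m, ses) / nrow(ses),
               tolerance = 1e-12)
  # and it is the trial-weighted mean of the per-subject nlp values
  per <- vapply(unique(ses$subject_id), function(sid) {
    s <- ses[ses$subject_id == sid, ]
    nlp(policy_trace(m, s), s)
  }, numeric(1))
  expect_equal(cohort_nlp(m, ses), mean(per), tolerance = 1e-12)
})

test_that("the empirical-majority predictor scores at least 50 percent", {
  for (seed in 91:95) {
    ses <- random_session(51, seed = seed)
    maj <- if (mean(ses$action == "L") > 0.5) 0.9 else 0.1
    tr <- data.frame(p_L = rep(maj, 51), p_R = rep(1 - maj, 51))
    expect_gte(percent_correct(tr, ses), 50)
  }
})

test_that("leave-one-out cross-validation is hand-checkable on a toy cohort", {
  # three subjects; intercept-only LIN: the fold model predicts the pooled
  # L-rate of the two training subjects
  coh <- rbind(toy_session(rep("L", 10), 0, subject_id = "a"),
               toy_session(c(rep("L", 5), rep("R", 5)), 0, subject_id = "b"),
               toy_session(rep("R", 10), 0, subject_id = "c"))
  cv <- loo_cv("lin", coh, J = 0)
  expect_equal(nrow(cv), 3L)             # fold count = cohort size
  # fold a: train on b+c -> p_L = 5/20; nlp on all-L subject = -log(0.25)
  expect_equal(cv$nlp[cv$subject_id == "a"], -log(0.25), tolerance = 1e-6)
  # fold b: train on a+c -> p_L = 0.5 exactly -> nlp = log 2
  expect_equal(cv$nlp[cv$subject_id == "b"], log(2), tolerance = 1e-6)
  # fold c: train on a+b -> p_L = 15/20; nlp on all-R subject = -log(0.25)
  expect_equal(cv$nlp[cv$subject_id == "c"], -log(0.25), tolerance = 1e-6)
})

test_that("identical subjects give near-zero fold variance", {
  one <- random_session(40, seed = 96)
  coh <- do.call(rbind, lapply(c("a", "b", "c", "d"), function(id) {
    s <- one; s$subject_id <- id; s
  }))
  cv <- loo_cv("ql", coh, config = fit_config(n_restarts = 1L))
  expect_lt(stats::sd(cv$nlp), 1e-6)
})

test_that("hyperparameter selection picks the grid point with lowest nlp", {
  # data generated with genuine lag-2 dependence: J = 2 must beat J = 0
  truth <- lin_params(2, 0, c(1.5, 1), c(0, 0), c(0, 0))
  sch <- build_schedule(seed = 7, trials_per_block = 60)
  ses <- do.call(rbind, lapply(1:6, function(i) {
    run_on_policy(bandit_model("lin", truth), sch, seed = 700 + i,
                  subject_id = paste0("s", i))
  }))
  sel <- select_hyperparams("lin", ses, grid = list(J = c(0L, 2L)))
  expect_equal(sel$best$J, 2L)
  expect_equal(nrow(sel$table), 2L)
  # single-point grid returns that point
  sel1 <- select_hyperparams("lin", ses, grid = list(J = 2L))
  expect_equal(sel1$best$J, 2L)
  expect_error(select_hyperparams("lin", ses, grid = list()), "empty grid")
})

test_that("label prediction picks the best-fitting group model", {
  gen_a <- bandit_model("qlp", qlp_params(0.4, 4, 2))    # strong stayer
  gen_b <- bandit_model("qlp", qlp_params(0.4, 4, -2))   # alternator
  sch <- build_schedule(seed = 8, trials_per_block = 50)
  ses_a <- run_on_policy(gen_a, sch, seed = 1, subject_id = "x", group = "A")
  models <- list(A = gen_a, B = gen_b)
  expect_equal(as.character(classify_subject(ses_a, models)), "A")
  # identical models: deterministic first-label tie-break
  expect_equal(as.character(classify_subject(ses_a,
                                             list(Z = gen_a, Y = gen_a))),
               "Z")
  expect_error(classify_subject(ses_a, list(A = gen_a)), "at least 2")
})

test_that("diagnostic LOO classification separates distinct phenotypes", {
  sch <- build_schedule(seed = 9, trials_per_block = 40)
  mk <- function(m, lab, n) do.call(rbind, lapply(seq_len(n), function(i) {
    run_on_policy(m, sch, seed = 1000 + 10 * i,
                  subject_id = sprintf("%s%d", lab, i), group = lab)
  }))
  groups <- list(
    stay = mk(bandit_model("qlp", qlp_params(0.3, 3, 2.5)), "p", 4),
    alt = mk(bandit_model("qlp", qlp_params(0.3, 3, -2.5)), "a", 4))
  cm <- diagnostic_cv(groups, "qlp",
                      config = fit_config(n_restarts = 1L))
  expect_equal(rowSums(cm$counts), c(stay = 4, alt = 4))
  expect_gte(cm$accuracy, 75)   # diagonal dominance for separated groups
})
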
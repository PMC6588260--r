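# Shared fixtures. Heavy objects (cohorts, fits) are built lazily and cached
# for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A hand-written session: single subject, explicit actions/rewards/blocks.
toy_session <- function(actions, rewards, blocks = 1L, subject_id = "s1",
                        group = "toy") {
  n <- length(actions)
  data.frame(subject_id = subject_id, group = group,
             block = rep_len(blocks, n), trial = seq_len(n),
             action = actions, reward = rep_len(rewards, n))
}

# Random session(s) under a fixed seed: uniform actions, Bernoulli rewards.
random_session <- function(n_trials, seed, n_blocks = 1L, subject_id = "s1",
                           p_reward = 0.3) {
  set.seed(seed)
  blocks <- sort(rep_len(seq_len(n_blocks), n_trials))
  toy_session(sample(c("L", "R"), n_trials, replace = TRUE),
              rbinom(n_trials, 1, p_reward), blocks, subject_id)
}

random_cohort <- function(n_subjects, n_trials, seed, n_blocks = 1L) {
  do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    random_session(n_trials, seed + i, n_blocks,
                   subject_id = sprintf("s%02d", i))
  }))
}

# Scaled-down study cohorts used by the heavier end-to-end tests: the preset
# phenotypes with 16 subjects and 12 blocks of 60 trials.
scaled_cohort <- function(label) {
  cached(paste0("cohort_", label), {
    spec <- phenotype_presets()[[label]]
    spec$n_subjects <- 16L
    spec$trials_per_block <- 60L
    generate_cohort(spec)
  })
}

# RNN imitation fit (5 cells, 300 Adam iterations) on the first 12 subjects
# of a scaled cohort; the remaining 4 subjects are the held-out set.
scaled_rnn_fit <- function(label) {
  cached(paste0("rnn_fit_", label), {
    co <- scaled_cohort(label)
    ids <- unique(co$sessions$subject_id)
    train <- co$sessions[co$sessions$subject_id %in% ids[1:12], ]
    fit_ml("rnn", train,
           config = fit_config(optimizer = "adam", step_size = 0.02,
                               max_iterations = 300L,
                               checkpoint_every = 100L, seed = 11L),
           n_cells = 5L)
  })
}

heldout_sessions <- function(label) {
  co <- scaled_cohort(label)
  ids <- unique(co$sessions$subject_id)
  co$sessions[co$sessions$subject_id %in% ids[13:16], ]
}

# Norm-wise comparison of an analytic gradient against central differences.
grad_vs_fd <- function(fn, u, h = 1e-5) {
  an <- fn(u, grad = TRUE)$grad
  fd <- vapply(seq_along(u), function(i) {
    up <- u; um <- u
    up[i] <- u[i] + h; um[i] <- u[i] - h
    (fn(up, grad = FALSE)$nll - fn(um, grad = FALSE)$nll) / (2 * h)
  }, numeric(1))
  sqrt(sum((an - fd)^2)) / sqrt(sum(fd^2))
}
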
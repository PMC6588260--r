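# banditlearn

Computational models of human trial-by-trial decision-making in a
two-armed bandit task, for researchers in computational psychiatry and
cognitive modelling. The package fits a spectrum of choice models to
per-trial behavioural records — from classic reinforcement learning to a
recurrent network that imitates choice sequences — then compares them by
cross-validated prediction and interrogates them with controlled
simulations.

The task: subjects choose between left (L) and right (R) presses across 12
blocks; within a block one action is rewarded with probability 0.25, 0.125
or 0.08 and the other with 0.05, the better side varying over blocks.

The models, all behind one observe/predict agent contract:

* **ql** — Q-learning: `Q(a) ← (1−φ)Q(a) + φr`, softmax policy
  `P(L) = σ(β(Q(L) − Q(R)))`.
* **qlp** — Q-learning plus a perseveration kernel κ on the previous
  action.
* **gql** — generalised Q-learning: `d` value traces and `d` action-history
  traces per action with separate learning rates (Φ, Ψ), combined as
  `B·Q(a) + K·H(a) + H(a)ᵀC Q(a)`; `4d + d²` parameters.
* **lin** — logistic regression on the last J actions, rewards and
  interactions.
* **rnn** — an LSTM (5/10/20 cells) with a softmax readout, trained by
  maximum likelihood to predict each next choice from the previous action
  and reward; exact analytic BPTT gradients, Adam training, early stopping
  by cross-validation.

Around the models: leave-one-out cross-validation (mean negative
log-probability and %correct), hyperparameter selection, on-policy /
off-policy / mixed greedy simulation probes, behavioural statistics (stay
probabilities, reward-conditioned staying, run-length structure), LOO
diagnostic-label classification, and a seeded synthetic-cohort generator
with healthy-like, depression-like and bipolar-like phenotypes.

## Worked example

```r
library(banditlearn)

# a synthetic healthy-like cohort: 8 subjects, 12 blocks x 60 trials
spec <- phenotype_presets()$healthy
spec$n_subjects <- 8L; spec$trials_per_block <- 60L
co <- generate_cohort(spec)

# behavioural signatures
mean(p_best_action(co$sessions, co$schedules)$p_best)
st <- stay_prob_given_reward(co$sessions)
c(reward = mean(st$p_stay_reward), no_reward = mean(st$p_stay_noreward))

# fit Q-learning and the generalised model to the cohort
f_ql  <- fit_ml("ql",  co$sessions, config = fit_config(n_restarts = 2))
f_gql <- fit_ml("gql", co$sessions, config = fit_config(n_restarts = 2), d = 2)
c(ql = cohort_nlp(f_ql$model, co$sessions),
  gql = cohort_nlp(f_gql$model, co$sessions))

# off-policy probe: policy around a forced reward at trial 19
tr <- run_off_policy(f_gql$model, probe_reward_switch(c(19)))
round(tr$p_L[18:21], 3)
```

Printed on one run (seeds are fixed in the preset):

```
[1] 0.5623264            # p(best action): above chance
   reward no_reward
0.7121957 0.8558644      # staying drops after a reward (the "dip")
       ql       gql
0.5026926 0.3439406      # gql predicts the choices far better
[1] 0.870 0.875 0.542 0.816   # the dip at trial 20, right after the reward
```

The fitted GQL model reproduces the cohort's signature: a reward briefly
*lowers* the probability of staying (p_L drops from ~0.87 to ~0.54 on the
trial after the forced reward, then recovers), something ql/qlp cannot
express, and its training nlp is accordingly much lower.

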
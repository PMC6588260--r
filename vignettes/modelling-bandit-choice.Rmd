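---
title: "Modelling trial-by-trial choice in a two-armed bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trial-by-trial choice in a two-armed bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

banditlearn fits computational models of how people choose between two
probabilistically rewarded actions, and provides the machinery to compare,
interrogate and stress-test those models. This vignette explains the models,
the fitting and validation procedures, the synthetic-data generator, and the
numerical and design choices behind them.

## The task

Subjects repeatedly press a left (L) or right (R) button for probabilistic
rewards. The session is divided into 12 blocks; within a block one action is
better, with reward probability 0.25, 0.125 or 0.08, while the other stays
at 0.05. Each (probability, better side) pair appears twice, in an order
shuffled per subject. Trials are self-paced; the package models a fixed
count per block (default 110, close to the observed per-block averages) or
accepts a seeded sampler, because response timing carries no information the
models use. Blocks are separated by rating screens, so by default every
model's internal state is reset at block boundaries and no statistic or lag
crosses a boundary; the reset is a flag (`reset_per_block`) on every model.

## The models

All models expose the same contract — `reset()`, `predict()` (a probability
over {L, R} using only data observed so far), `observe(action, reward)` —
so fitting, cross-validation and simulation treat them interchangeably.

**QL.** One value per action, updated after each choice by
$Q(a) \leftarrow (1-\phi)\,Q(a) + \phi\, r$, read out through a softmax with
inverse temperature $\beta$: $P(L) = \sigma(\beta(Q(L) - Q(R)))$.

**QLP.** Adds a perseveration kernel: the previous trial's action receives
an extra logit $\kappa$ (negative $\kappa$ favours alternation). With
$\kappa = 0$ QLP is exactly QL.

**GQL.** Generalises both: $d$ value traces per action with learning-rate
vector $\Phi$, plus $d$ action-history traces with rates $\Psi$ — the taken
action's histories move toward 1, the other action's decay toward 0, so
histories always lie in $[0,1]$. The logit of action $a$ is
$B \cdot Q(a) + K \cdot H(a) + H(a)^\top C\, Q(a)$, giving $4d + d^2$ free
parameters (5, 12, 140 at $d = 1, 2, 10$). GQL($d{=}1$, $\Psi{=}1$,
$C{=}0$) reproduces QLP trial-by-trial, a nesting the tests verify to
1e-10. A key structural point: only the *taken* action's values are
updated, so an untaken action's value is frozen until it is chosen again —
this matters for the synthetic phenotypes below.

**LIN.** Logistic regression of the choice on the last $J$ actions, rewards
and their interactions (default $J = 18$, selectable by cross-validation),
with actions coded $\pm 1$ so that missing lags pad with zero and the
intercept is a pure side bias. The coding convention is immaterial:
relabelling L/R maps a fit to its mirror image. LIN is fitted by ordinary
binomial logistic regression (`glm`); coefficients are capped at $\pm 15$ so
separated data (e.g. a subject who always presses L) yield finite
parameters with predictions within 3e-7 of the boundary.

**RNN.** A single LSTM layer of $N_c$ cells (standard
forget/input/output-gate dynamics, no peepholes, no forget-gate bias trick)
feeding a bias-free softmax readout; the input at each trial is the one-hot
previous action plus the raw previous reward, and the first trial of a
(reset) sequence feeds the zero vector. Parameter count is
$4(N_c(N_a{+}1) + N_c^2 + N_c) + N_c N_a$: 190, 580, 1960 at 5, 10, 20
cells. The network is the flexible end of the model spectrum: it imitates
whatever strategy produced the training choices rather than assuming one.

## Fitting

All families are fitted by maximum likelihood on the summed cohort
log-likelihood — one parameter set per group of subjects, matching the
prediction protocol (a group model must predict a held-out subject).
Constrained parameters are optimised through transforms (logistic for
learning rates, exponential for $\beta$); predicted probabilities are
floored at 1e-12 before logs purely as numerical armour.

The package computes exact analytic gradients for every likelihood:
forward-mode accumulation through the value/history recursions for QL, QLP
and GQL, and full backpropagation through time for the LSTM, all batched
across subjects. The test suite checks every gradient against central
finite differences (norm-wise relative error below 1e-4 at step 1e-5; in
practice ~1e-8).

The network is trained with Adam (default step size 0.01), with parameter
snapshots stored every `checkpoint_every` iterations (default 100, grid up
to `max_iterations` = 2000 — wide enough to bracket typical optimal
stopping points of a few hundred to ~1200 iterations). Early stopping picks
the checkpoint with the best cross-validated nlp. The value models default
to L-BFGS-B instead: with 2–12 parameters it reaches the optimum in an
order of magnitude fewer likelihood evaluations than a first-order method,
and the choice is exposed (`fit_config(optimizer = "adam")` trains any
family with Adam). Two further wrinkles:

* **Restarts.** Value-model fits use seeded random restarts (default 5)
  because the GQL likelihood is multi-modal. The neutral first start
  staggers the learning rates across traces: the exact origin is a fixed
  point of the trace-permutation symmetry (identical rates receive
  identical gradients forever) and would silently collapse $d$ traces into
  one.
* **Initial values.** Q, H, and the LSTM state all start at zero after a
  reset — the symmetric, uninformative choice; no prior is placed on
  values.

## Evaluation

Two metrics: **nlp**, the per-trial mean negative log-probability assigned
to the actions actually taken (log 2 ≈ 0.693 for a uniform predictor, 0 for
an oracle), and **%correct**, the percentage of trials whose most probable
action was taken, with exact ties counted as incorrect (a deliberate,
documented convention — a uniform model scores 0, not 50). nlp is the
primary measure; it rewards calibrated confidence rather than bare
argmaxes.

Model comparison uses leave-one-out cross-validation over subjects: fit on
all but one, freeze the parameters, record both metrics on the withheld
subject, rotate. Hyperparameters (cell count and stopping iteration for the
network, $J$ for LIN, $d$ for GQL) are chosen by the same CV, by default
in-sample (grid point with lowest mean held-out nlp); selection from the
two *other* groups' data is available as `mode = "other_groups"`.

Diagnostic-label prediction applies the same logic across groups: each
subject is assigned the label of whichever group model fits them best
(lowest nlp), with their own group's model refitted without them. Ties —
in argmax predictions and in label scores — break deterministically toward
the first candidate in a fixed order, so runs are exactly reproducible.

## Simulation and probes

Fitted models are interrogated three ways. *On-policy*: the model plays the
task, sampling (or argmaxing) its own policy and receiving scheduled
rewards. *Off-policy*: a forced action/reward sequence is fed in while only
the predictions are recorded — the trace depends on nothing but the forced
inputs and the parameters. *Mixed*: a forced prefix, then a greedy
continuation with no rewards delivered (configurable), used to ask what the
model would do next.

Two probe designs ship with the package (also as scenario files under
`inst/extdata/`): a 30-trial reward-switch probe (10 forced R, 20 forced L,
rewards at configurable positions — the bundled one/two/three-reward
placements are illustrative, chosen so a late trial can be compared across
prior reward counts) and the 9-trial oscillation probe
(R,R,R,R,R,R,L,R,L then 11 greedy trials) that asks whether two forced
alternations ignite self-sustained oscillation.

## The synthetic cohorts

The package is exercised end-to-end on generated data, so the generator is
first-class code. Three GQL($d{=}2$) phenotypes mimic the qualitative
signatures of healthy, depressed and bipolar choice behaviour:
above-chance choice of the better action; a *decrease* in staying
immediately after a reward (the reward-switch "dip") that weakens as
rewards accumulate on an action; decaying perseveration; and, for the
bipolar-like phenotype, a high fraction of length-1 runs with
self-sustaining alternation.

One design choice deserves explanation. A purely negative weight on a fast
value trace produces a dip but *cannot* coexist with above-chance
performance here: because untaken actions' values are frozen, a strong
negative fast-value weight leaves a lasting penalty on the just-rewarded
action and the agent never profitably returns to it (simulation during
development put p(best) well below 0.5). The presets therefore carry the
dip mainly on a negative fast-history × fast-value interaction
($C_{11} < 0$): the penalty is gated by the fast history trace, which
decays within a couple of trials of leaving the action. The slow value
trace (large positive weight, small learning rate) accumulates reward
evidence and steers overall choice.

Between-subject heterogeneity is emulated by multiplicative jitter (±10%)
on each subject's unconstrained parameter vector; the transforms keep rates
inside [0,1] by construction. Every subject also receives an independently
shuffled schedule. All preset numbers are the package's own choices,
validated by `verify_phenotype()` against the signature checklist — they
are not estimates from any clinical population, and passing these checks
shows the pipeline works on data *with* this structure, not that real
patients have it. Real data differ in ways the generator does not emulate:
response times, within-session drift, outcome-magnitude effects, and
individual differences richer than parameter jitter.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at deliberately modest sizes:
signature and imitation checks run on 16-subject cohorts with 12 blocks of
60 trials and a 5-cell network trained for 300 Adam iterations (step 0.02),
sizes at which every qualitative effect above is already stable;
parameter-recovery checks for QL run at the full 34-subject, 12 × 110
layout across 10 seeds. Monte-Carlo tolerances scale as binomial standard
errors ($3\sqrt{p(1-p)/N}$ for reward-rate checks). Gradient checks use
central differences at step 1e-5 with norm-wise comparison, since
elementwise relative error is meaningless for near-zero coordinates.

## Known limitations

* Group-level fits only by default; per-subject fitting is available by
  calling `fit_ml` per subject but there is no hierarchical sharing.
* The LSTM runs on CPU in batched base-R linear algebra: ample for the
  cohort sizes here, not for thousands of subjects.
* State-dependence is out of scope: values are functions of actions only,
  as appropriate for a bandit.
* The two snack reward types are collapsed into a binary reward, as the
  models only consume 0/1.
* Reward-cross placements in the bundled reward-switch probes are
  illustrative defaults, not calibrated quantities.
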
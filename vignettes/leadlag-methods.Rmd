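---
title: "Windowed lead-lag decision models during motor learning: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed lead-lag decision models during motor learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadlag)
```

## The scientific problem

During motor learning, errors shrink across trials. Any reward-bearing
choice whose consequences extend into future trials — committing to a
smaller, more valuable target; locking in a reward schedule for a block of
upcoming reaches — is therefore only optimal if it anticipates performance
that does not exist yet. This package implements the analysis machinery for
two such situations: a throwing task with an irreversible ladder of
shrinking targets, and a visuomotor-rotation reaching task in which a
reward schedule is chosen for exploitation horizons of different lengths.

## The windowed lead-lag model

The model family evaluates, at decision `j` (taken on trial `5j` of 200),
each admissible target `i` by the points it would have earned over a window
of past and future trials:

$$V(i, j, \mathrm{lag}, \mathrm{lead}) =
  \sum_{k=\max(1,\,5j-\mathrm{lag})}^{\min(5j+\mathrm{lead},\,200)}
  i \cdot H[r_i - e_k]$$

with $H$ the Heaviside step function and $e_k$ the session's actual error
on trial $k$. The selection is $q^*_j = \arg\max_{q \ge i} V(q, j)$, where
$q \ge i$ encodes the task rule that the target can never grow again.

Design choices in this core, and why:

* **Window bounds.** The sum runs from `max(1, 5j − lag)` to
  `min(5j + lead, 200)`, so the decision trial `5j` itself is always
  included and the window holds `lag + lead + 1` trials away from the
  session edges. Near the edges the window is clamped, never reflected or
  padded: the model should only ever see trials that exist.
* **Tie-breaking.** `argmax` ties go to the smallest admissible index
  (the largest target). Under the irreversible-commitment rule this is the
  conservative choice — with no evidence favouring a smaller target, the
  model stays where it is. In particular, on an all-miss session every
  `V` is zero and the model never leaves the largest target.
* **Hit conventions.** The model equations reward a trial when the error
  fits the radius exactly (`error ≤ r`). The task as displayed to players
  was slightly more lenient: a 5 mm-radius puck counted as a hit when any
  part of it came within 1 mm of the target edge, i.e. `error ≤ r + 6`.
  Both conventions are supported through `target_set(hit_margin =)`;
  model fitting and the solvers default to margin 0 (the model
  convention), and nothing in the pipeline hard-codes either choice.

## Solvers

`global_optimal_dp()` maximizes total points over all admissible scenarios
by dynamic programming on the state (block, current target). Enumeration
(`global_optimal_bruteforce()`) is retained purely as an independent test
oracle: the two must agree exactly, and the test suite checks this on
randomized sessions. Ties are resolved to the lexicographically smallest
sequence so results are reproducible.

`scenario_distribution()` computes the *exact* count of scenarios at every
achievable point total by a convolution dynamic program (block × current
target × running total). This gives ranks, percentiles, and z-scores of any
particular scenario against all 1,086,008 without materializing them; the
percentile of a total is defined as the percentage of scenarios scoring no
more than it.

`local_optimal_search()` and `fit_policy()` are exhaustive grid searches —
the objective (realized points, or SSE against observed choices) is a step
function of the integer windows, so gradient methods are inapplicable and
the grid is the honest search. Fitting restricts to `lead + lag ≥ 5` for
robustness (windows shorter than one block are dominated by noise); the
one-parameter lead and lag models pin the other window at zero. Fit ties go
to the smaller `lead + lag`, then the smaller lead, so the simplest window
wins.

**Identifiability caveat.** Different windows can generate identical
rollouts on a given error sequence (e.g. when errors are flat over a
stretch, widening the window changes nothing). Recovery of a generating
agent is therefore guaranteed only up to this equivalence class: the fitted
SSE reaches 0 and the fitted window's rollout matches the agent's choices
exactly, but the fitted (lead, lag) pair need not equal the generating
pair. Tests assert the rollout identity, not parameter identity.

## Statistics

* **Nested F tests** compare pooled fits:
  $F = \frac{(SSE_r - SSE_f)/(p_f - p_r)}{SSE_f/(n - p_f)}$ with
  per-participant parameters pooled (8 participants give 8 vs 16
  parameters over 312 choices, hence $F_{(8,296)}$). Printed p-values are
  exact machine-precision tail probabilities.
* **Variance explained** for the sensitivity surface is
  $R^2 = 1 - SSE/SST$ with SST about each participant's mean observed
  target index; this definition of "variance of the choices" is a
  reconstruction, recorded here because no canonical definition exists for
  ordinal choice sequences. Offsets of equal magnitude and opposite sign
  are averaged; offsets that would drive a window negative are dropped for
  that participant.
* **Moving-window decomposition.** Windows of 9 trials, centred, full
  windows only (centres 5..196 on a 200-trial session), sample SD
  (n − 1). The bias fraction is $\mu^2/(\mu^2 + \sigma^2)$, the share of
  windowed mean squared error carried by the systematic offset. Whether
  such a window should be centred or trailing is not determined by the
  task; centred is the default and the window is a parameter.
* **Exponential fits** use Levenberg–Marquardt with multi-start
  (`b0 ∈ {−0.1, −0.03, −0.01}`, amplitude and asymptote seeded from the
  data); with flat data the rate is unidentifiable and flagged rather than
  guessed.
* **Repeated-measures ANOVA** is computed from within-subject sums of
  squares with df $(k-1, (k-1)(n-1))$; `stats::aov` with an error stratum
  is the independent oracle in the tests, not the implementation, because
  the pipeline needs plain numeric fields.
* **Cross-validated predictive correlation.** Repeated random 10-fold
  splits; out-of-fold SSE of the linear model against a mean-only model;
  $r_{pred} = \mathrm{sign}(b)\sqrt{\max(0, 1 - SSE_{lin}/SSE_{mean})}$
  with SSEs summed over folds and repetitions. The p-value permutes the
  response across points and recomputes the statistic (two-sided on the
  signed statistic); a permutation scheme is used because the statistic's
  null distribution is not analytic. Internally the per-fold regressions
  are evaluated from fold-wise sufficient statistics, which is
  algebraically identical to refitting `lm` per fold (tested) and makes
  the permutation and null-calibration studies affordable. Degenerate
  splits (a training fold with constant predictor) are resampled.
* **Horizon adjustment.** Per-horizon means are removed from both the
  reward-slope and the selected hit value and the grand mean restored, so
  the pooled correlation reflects within-horizon, across-participant
  association. Hit/miss/fault proportions keep faults in the denominator
  by default (`h + m + f = 1`); an exclude-faults option exists because
  the alternative convention is defensible.

## The simulators

The synthetic layer exists so that every downstream stage has inputs with
known ground truth; its defaults emulate the study conditions.

**Puck.** Explicit Euler at 1 ms on `m·a + b·v = F` (mass 0.010 kg,
viscosity 0.035 N·s/m — the viscosity is a force per velocity), force
zeroed beyond 10 cm of travel, rest declared below 1 mm/s. The printed
speed at the window crossing is linearly interpolated within the step, so
the closed-form coasting distance `m·v/b` is matched within a fraction of
a percent and improves as the timestep shrinks (tested at two timesteps).
A calibrated brief impulse that lands the puck at the 300 mm target
crosses the force window around 120 ms, inside the 92–126 ms band the
apparatus produced.

**Throwing sessions.** The error magnitude follows
`e_k = max(0, a·e^{b·k} + c + η_k)` with `η_k ~ N(0, σ_k)`,
`σ_k = σ_a·e^{b·k} + σ_c`: the deterministic curve *is* the generating
learning curve, so curve-fit recovery is unbiased and exactly testable at
zero noise. The endpoint direction is a unit vector drawn from an
anisotropic Gaussian whose y-mean decays with its own rate, then scaled by
`e_k` — this yields, by construction, (i) resultant error equal to the
endpoint norm, (ii) an early overshoot bias in y that washes out (the
default direction-bias decay leaves the bias negligible after ~20 trials),
and (iii) larger dispersion in y than x. Defaults (`a = 105`,
`b = −0.025`, `c = 30` mm, jitter SD decaying 35 → 10 mm) put first-block
errors near 135 mm and last-block errors near 35 mm. Gaussian,
trial-independent noise is an assumption of this generator, not an
empirical claim; x–y correlation defaults to zero.

**Agents and cohorts.** Agents roll out the deterministic policy with
known windows; cohort windows are drawn around a population mean of
(lead 38, lag 46) trials. Because deterministic agents reproduce their own
rollouts exactly, cohorts destined for the fitting-and-F-test pipeline can
be passed through `perturb_choices()`, which nudges individual decisions
and re-monotonizes — otherwise the full model fits with zero residual and
the F statistics degenerate to infinity. The perturbation probability used
in the reproduction script (0.3) makes the synthetic cohorts' fit
residuals imperfect in the way human choice sequences are.

**Reaching sessions.** Angular error starts at the 45° rotation and
decays exponentially over rotated trials with Gaussian noise; faults are
an independent Bernoulli process (the task's fault criterion is a
reaction-time threshold, unrelated to reach direction). The simulated
chooser anticipates its own future: for each horizon it computes its
expected hit proportion from its generating curve and selects
`60 + 40·p̂` plus selection noise, clamped to the 60–100 slider. This
produces horizon-increasing hit values and a positive slope–selection
correlation as emergent properties of anticipation, without hand-placing
either result.

What passing tests on these generators do **not** show: that real
participants' noise is Gaussian or trial-independent, that real choice
noise looks like single-step nudges, or that the real data's fitted
windows equal the generator's population values. They show that the
estimators recover known ground truth under the stated conditions and that
every structural invariant of the task is enforced.

## Data formats

Sessions round-trip through a documented two-file CSV dialect (trials +
choices or selections, UTF-8, header row). A minimal reader for Level-5
MAT containers (numeric/logical/char arrays, cells, structs, compressed
elements) is included and validated against files produced by an external
MAT writer; the expected container layout for a full study file is
documented at `read_study_data()`. The internal structure of the original
deposited container is not described in print, so the documented layout is
this package's own; the reproduction test that consumes the deposited
file reports exactly which field fails if a differently-arranged container
is supplied.

## Problem sizes

The shipped tests and the reproduction script use desk-scale sizes chosen
to exercise every code path with exact oracles: brute-force solver
comparisons on 25-trial sessions (56–2,002 scenarios), full scenario
distributions on complete 200-trial sessions (1,086,008 scenarios, exact),
fitting grids of 0–60 to 0–120 trials per window, cohorts of 8 throwing
and 17 reaching participants, 1,000 Monte-Carlo repetitions for the
cross-validated correlation, and 1,000 null datasets at 199 permutations
each for its type-I calibration. All are package choices and are
parameters of the corresponding functions.

## Known limitations

* Deterministic argmax policies only; no stochastic-choice (softmax)
  variant is fitted, so choice noise is absorbed into SSE.
* The target-size design procedure (`design_targets_minimax()`) documents
  an objective and constraint whose original search procedure is not
  described in print; the implementation (quantile-seeded random search
  plus coordinate refinement) is a reconstruction and is labelled as such.
* Window identifiability depends on the error sequence, as discussed
  above.
* The MAT reader covers the element classes behavioural tables need, not
  sparse/complex/object classes.
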
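---
title: "Measuring cooperation and costly punishment with a multinomial processing tree model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cooperation and costly punishment with a multinomial processing tree model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmpt)
```

## The measurement problem

In a simultaneous one-shot Prisoner's Dilemma with a costly punishment
option, the observable data per test trial are three bits: the partner's
preprogrammed behavior, the participant's decision, and whether the
participant invested anything in punishment. Raw punishment rates mix
qualitatively different processes — punishment of exploitation, punishment
by fellow defectors, punishment of cooperators, and punishing regardless
of outcome — and all of them are entangled with the cooperation rate,
because which punishment type *can* occur on a trial depends on both
players' choices. A multinomial processing tree (MPT) model resolves this
by writing the eight observable category probabilities as branch products
of five latent probabilities.

## Model structure and assumptions

Two trees, one per partner behavior. In each, the participant first
cooperates with probability `C` (the same `C` in both trees — the
decisions are simultaneous, so the participant's choice cannot be
conditioned on the partner's). Then, per outcome cell, a type-specific
punishment process fires with its own probability (`P_moral` after
unilateral cooperation, `P_hypocritical` after mutual defection,
`P_antisocial` after unilateral defection, none after mutual cooperation);
if it does not fire, an unspecific bias `b` may still produce punishment.
So, e.g., P(punish | cooperated, partner defected) =
`P_moral + (1 − P_moral) · b`, and P(punish | mutual cooperation) = `b`.

The key identifying assumptions, which the simulator reproduces and a user
should keep in mind with real data:

* **Independence across trials and participants.** Counts are aggregated
  over participants and trials into one frequency table per group; the
  multinomial likelihood treats every test decision as exchangeable.
  Individual differences are absorbed into the group-level probabilities.
* **Punishment is binary.** Any positive investment counts as "punished";
  the magnitude (1–9 cents or 1–3 points) affects only payoffs.
* **The bias is a residual branch,** reachable from every outcome cell, so
  `b` is identified primarily by punishment after mutual cooperation,
  where no type-specific process exists.

## Estimation

`fit_cp()` maximizes the summed multinomial log-likelihood over all
groups. Numerical choices, all deliberate:

* **Scale.** Free parameters are optimized on the log-odds scale
  (bounded box [−30, 30], i.e. probabilities within ~1e-13 of the
  boundary are representable), which keeps the optimizer off hard bounds
  while allowing effectively-boundary solutions. Estimates are reported on
  the probability scale, as-is; boundary estimates are *not* jittered.
* **Starts.** One moment-based start (cooperation and conditional
  punishment shares inverted through the branch equations) plus
  `n_restarts = 10` random starts drawn uniformly in [0.02, 0.98] from a
  seeded stream (`seed = 42` by default). Fits are bit-identical given the
  same options; the caller's RNG state is untouched.
* **Tolerances.** Convergence at relative tolerance 1e-10 on the
  log-likelihood, 500 iterations per start; the best converged start wins.
  Non-convergence from every start is an error; a best point that did not
  formally converge is returned with `converged = FALSE`, never silently.
* **Degenerate cells.** Probabilities are clipped at 1e-12 inside
  logarithms; observed zero cells contribute exactly 0 to `G²`.

Goodness of fit is `G² = 2 Σ obs · ln(obs/exp)` with
`df = 6 · n_groups − n_free`: each group contributes two independent
4-category trees, hence 6 free category probabilities, and the
unconstrained model spends 5 parameters per group — so 2 groups give
df = 2 and 3 groups give df = 3.

Hypotheses are tested by adding one equality constraint (one parameter,
a set of ≥ 2 groups) and refitting: `ΔG²` is χ²-distributed with
df = (groups in the constraint − 1). Negative `ΔG²` within 1e-6 is
optimizer noise and is clipped to zero; anything more negative raises an
error, because it means the base fit missed its maximum. The effect size
is Cohen's `w = √(ΔG²/N)` where `N` is the **total number of test
decisions of all groups in the fitted model**, not only the compared
groups — this convention is validated in the test suite against the full
set of published effect sizes it must reproduce. p values are upper-tail
central χ², unadjusted (a report option can annotate Bonferroni-adjusted
values without changing the primary output).

Standard errors are square roots of the diagonal of the inverse
**expected** Fisher information, assembled from hand-derived analytic
derivatives of the branch probabilities (the test suite checks them
against a finite-difference Hessian). A useful structural fact: `C` is
information-orthogonal to all punishment parameters, so
`SE(Ĉ) = √(Ĉ(1−Ĉ)/N)` exactly — a closed form the tests exploit as an
oracle. Parameters estimated within 1e-6 of 0 or 1 get `NA` standard
errors rather than a misleading Wald number.

## Power analysis

`chi2_power()`, `sensitivity_w()` and `a_priori_n()` implement the
standard noncentral-χ² machinery with noncentrality `λ = w² · N`. The
crucial convention is that **N counts observations, not participants**:
participants × decisions per participant (20 test-phase punishment
decisions in the standard design). With this convention, 203 participants
× 20 decisions yield a minimal detectable effect of `w = 0.06` at power
0.95 (df = 1, α = 0.05, required λ ≈ 12.995), and detecting `w = 0.02`
requires 1625 participants. For the a-priori computation df = 1 is the
natural choice (a single pairwise equality constraint) and reproduces the
published sample size exactly; we adopt it as a documented inference since
sample-size reports rarely state df explicitly. `sensitivity_w()` inverts
the power function by bisection to 1e-8; `a_priori_n()` brackets by
doubling and then scans for the exact minimal integer, so the returned
`n` achieves the target power while `n − 1` does not.

## What the simulator does and does not emulate

`simulate_trials()` generates the study structure: 26 rounds per
participant, the first 6 training, partner behavior preprogrammed half
cooperating / half defecting, trial order randomized per participant, and
per-trial punishment drawn by traversing the matching tree branch.
Decisions about details the design leaves open:

* **Training split.** The 13/13 partner split is stated for all 26
  trials; how it divides between training and test is not. We split
  training 3/3 and test 10/10, so every participant contributes exactly
  10 decisions per tree — the cleanest factorial version of the design.
  Other splits are configurable through `trial_schedule()`.
* **Punishment magnitude.** Punished trials draw an investment uniformly
  from 1..`max_punishment` (9 in the cents variant, 3 in the points
  variant). Whether real investments are uniform is unknown; the choice
  affects payoffs and account balances only, never the model.
* **Homogeneity.** Participants within a group share one parameter
  vector. This matches the aggregate model's implicit assumption; it also
  means recovery results certify the estimator *under the model*, not
  robustness to individual differences, trial-order effects, learning
  across trials, or partner-face effects — none of which the generator
  produces.
* **Punish-back.** The online variant's partner punishment of unilateral
  defection can be simulated (`partner_punishes_defection = TRUE`) for
  payoff realism; it never enters the frequency tables.
* **Reproducibility.** Every participant's stream derives from the master
  seed by a fixed (group, participant) offset, so enlarging a group
  appends participants without reshuffling existing rows.

## Validation scale

The built-in checks run at sizes chosen to make Monte-Carlo error small
relative to the assertions: probability normalization on 1000 random
parameter vectors at 1e-12; a 10⁵-draw branch-process simulation within 3
binomial standard errors of the analytic probabilities; grid-search oracle
equivalence of the optimizer on small tables over the full 5-dimensional
parameter grid at step 0.05 (~4.1M points); parameter recovery at 200
participants × 500 replicates (|bias| < 0.02, 95%-interval coverage
within [0.91, 0.99]); and a repeated-experiment check that a true
moral-punishment difference of 0.15 at 100 participants/group yields the
largest `ΔG²` among all five comparisons in ≥ 95 of 100 replicates.

## Known limitations

* Aggregate (complete-pooling) estimation only; no hierarchical/latent-trait
  MPT variants, no Bayesian estimation, no bootstrap intervals.
* Only the fixed two-tree model; this is not a general MPT compiler.
* Wald intervals on the probability scale can misbehave near boundaries;
  the package flags boundary estimates instead of transforming intervals.
* The equality-constraint mechanism covers the hypothesis tests this
  design needs; general linear or order constraints are out of scope.
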
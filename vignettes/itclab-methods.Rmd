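---
title: "Methods: staircase intertemporal choice, discounting estimation, and group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staircase intertemporal choice, discounting estimation, and group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itclab)
```

## The task and its titration rule

The intertemporal-choice task pits a fixed immediate reward of 10,000 KRW
against a delayed reward defined by one of 12 staircase arms: six delays
(1, 10, 21, 50, 90, 180 days) crossed with two initial delayed rewards
(15,000 and 20,000 KRW). Each arm presents five offers per block; a block
interleaves the 12 arms uniformly at random (the previous arm remains a
legal candidate), giving 60 trials per block and 180 per three-block
session.

After the choice at an arm's step *t*, the delayed reward is adjusted by
`10,000 × (1/2)^e` KRW — upward after an immediate choice, downward after a
delayed choice — except on the 15,000 arm, where a delayed choice shrinks
the *gap* to the immediate reward so the delayed offer can never reach
10,000. Two exponent schedules are implemented as `staircase_config()`
options:

* **`halving` (default)**: `e = t`, so the first adjustment is ±5,000 and
  each subsequent one halves; the 15,000-arm exception halves the gap
  (`next = 10,000 + (current − 10,000)/2`). With offers rounded down to the
  nearest 100 KRW (`floor100 = TRUE`), exhaustive enumeration of all 2^4
  choice paths on all 12 arms gives a reachable offer range of exactly
  10,300–29,300 KRW — the range the task is described with.
* **`literal`**: `e = t − 1`, a first adjustment of ±10,000; a delayed
  choice on the 15,000 arm at step 1 then lands exactly on 10,000 KRW, and
  the reachable range becomes 10,000–38,700. The two schedules cannot both
  be true of the same dataset; since only `halving` reproduces the printed
  offer range, it is the default, and the choice is a configuration, not a
  claim.

`min_margin` optionally enforces strict dominance (`delayed ≥ 10,000 +
margin`) for users who want to rule out offers equal to the immediate
reward; the default of 0 leaves the rules exactly as stated above.

### What the staircase guarantees

For a deterministic threshold agent with indifference reward
`R* = 10,000·(1 + kD)`, enumeration over a dense sweep of `k` shows that the
offered rewards always bracket `R*` whenever it is reachable, on both arm
types. The 20,000 arm is a true bisection: its final offer lies within one
terminal step (625 KRW, plus 100 for rounding) of `R*`. The 15,000 arm is
not: its down-steps are relative (gap-halving) while its up-steps are
absolute, so the sequence can oscillate when `R*` lies near 14,000 KRW, and
the final-offer error is only bounded by the largest post-initial
adjustment (2,500 KRW). This asymmetry is a property of the published task
design itself; the tests assert exactly these guarantees rather than a
uniform bisection claim.

## The choice model and its estimator

Choices are modelled by hyperbolic discounting, `SV = V/(1 + kD)` with
`k ∈ (0, 1)` per day, and a softmax rule
`P(immediate) = [1 + exp(−μ(SV_imm − SV_del))]^{-1}` with inverse
temperature `μ ≥ 0` in units of 1/KRW (subjective values are in KRW, so
typical fitted values are around 10^-4–10^-3). No alternative discounting
forms (exponential, quasi-hyperbolic, area under the curve) are provided.
All reported discount rates use **log10**; `Δlog k` is base-invariant up to
a constant, but the base matters for magnitudes, so it is fixed and
documented everywhere.

`fit_mle()` minimises the negative log-likelihood with Nelder–Mead
(`reltol 1e-10`, 500 iterations) in an unconstrained space: `k = plogis(a)`
and `μ = exp(b)`. This respects both positivity constraints and the `k < 1`
bound without penalty terms. Ten starting points stratify a Latin square
over `log10 k ∈ [−4, −0.5] × log10 μ ∈ [−5, −2]` with small seeded jitter;
the best optimum wins, ties broken toward smaller `k`. The per-trial log
probability uses `plogis(·, log.p = TRUE)`, which is stable under extreme
value differences.

### Uniqueness diagnostics

A fit is flagged **non-unique** when (i) the participant chose one option
throughout (the likelihood then pushes `k` into a boundary and carries no
information about its value), (ii) the best estimate sits at the edge of
the admissible range (`log10 k < −4.5` or `k > 0.995`), or (iii) two
converged starts tie in likelihood within `nll_tol = 0.01` while their
`log10 k` differ by more than `param_tol = 0.1` — a flat ridge. The
tolerances are engineering choices: wide enough to ignore normal numerical
scatter between starts, tight enough to catch ridges. Non-unique fits are
excluded from all group statistics, and the recovery studies report their
summary statistics over unique fits for the same reason: a single
boundary-degenerate session (e.g. `log10 k̂ ≈ −10` from an agent whose
indifference point the staircase barely samples) would otherwise dominate
a correlation computed over hundreds of well-identified ones.

## The synthetic cohort generator

`simulate_cohort()` draws, per participant, `log10 k ~ N(−2, 0.5)` and
`log10 μ ~ N(−3.5, 0.3)` by default — a population centred on `k = 0.01`
per day with realistic spread for healthy young adults, and choice noise
that leaves clear information in 180 staircase trials. The post-session
rate is `log10 k_post = log10 k_pre − (δ_group + ε)`, with
`ε ~ N(0, 0.1)` test–retest noise, so the expected pre-minus-post shift in
log10 k equals the group's effect δ. Serial-7s accuracy follows the
logistic learning curve `p(t) = p0 + (p1 − p0)(1 − e^{−rate·t})`
(defaults `p0 = 0.5`, `p1 = 0.9`, `rate = 0.02` per trial over 240 trials,
two blocks of 120) sampled as Bernoulli trials through the task validator,
so every trace obeys the reset rules. A Gaussian copula with correlation
`slope_effect_corr` couples each participant's learning-rate draw to their
individual effect shift; the `experiment1` preset sets it to 0.5 (a
positive slope–effect association scenario), the `experiment2` preset to 0
(the null scenario). Presets carry a common 0.1-decade repetition effect in
every group, with an additional working-memory effect in the
five-group preset.

What the generator does **not** emulate: reaction times and timing
structure, memory content of the associative task (retrieval accuracy is a
binary input, not a cognitive simulation), within-session drift of `k` or
`μ`, and any dependence of choice noise on delay or magnitude. Passing
recovery tests therefore establish that the estimator and pipeline are
correct and calibrated *under the model*, not that the model captures every
feature of human data.

## Group-level inference

* **Effect measures**: `Δlog k = log10 k_pre − log10 k_post` (positive =
  reduced impulsivity) and the model-agnostic
  `ΔP(immediate) = P_pre − P_post`.
* **Exclusion**: non-unique fits first; then a 3-MAD filter on the log10 k
  estimates of each phase, with the raw (unscaled)
  `MAD = median(|x − median|)`. When MAD is 0 (all values equal) nothing is
  excluded. The report accounts for every input participant
  (`n_input = n_nonunique + n_mad + n_included`).
* **Bootstrap tests** (default `B = 10,000`): the observed statistic is a t
  (paired/one-sample, or pooled two-sample) or the t transform of
  Pearson's r. The null is imposed by construction — samples are shifted to
  mean zero and resampled with replacement for mean tests; pairs are broken
  by independent resampling for correlations — and the two-sided p-value is
  `(#{|t*| ≥ |t_obs|} + 1)/(B + 1)`, which is reproducible bit for bit
  given a seed and bounded below by `1/(B+1)`. Measured type-I error at
  `α = 0.05` over 1,000 null replicates (`B = 2,000`) is 0.05 to within
  Monte-Carlo error. Cohen's d uses the difference-score sd (paired) or the
  pooled sd (two-sample). No multiple-testing correction is applied
  anywhere; interpret families of tests accordingly.
* **Mixed ANOVA**: the time × type decomposition is computed through
  `stats::aov` with an `Error(participant)` stratum; the test suite checks
  it against independently hand-worked sums of squares and verifies that
  the decomposition balances to machine precision. Unbalanced phase data
  raise an error rather than silently dropping cases.
* **Learning curves**: 10-trial windows with 5-trial steps
  (`floor((n−10)/5)+1` windows), OLS slope on 0-based window index. The
  five-bin association uses bins of `floor(L/3)` trials stepped by
  `floor(L/6)`, the fifth bin right-anchored to the trace end so exactly
  five bins always cover the full trace regardless of divisibility.

## Seeds and determinism

Every stochastic stage derives its stream from a global seed through
`child_seed(seed, stage, id)` — a stable polynomial string hash modulo
2^31 − 1 — so any single participant, fit, or bootstrap can be replayed in
isolation. Running `run_pipeline()` twice with the same configuration
yields byte-identical reports.

## Validation scale

The shipped validation studies use 200 agents for parameter recovery
(r ≥ 0.9, |bias| ≤ 0.1 decades over unique fits), 25 small fixtures for the
grid-search cross-check (dense 200 × 200 grid over
`log10 k ∈ [−4, 0] × log10 μ ∈ [−5, −1]`), 1,000 null replicates at
`B = 2,000` for bootstrap calibration, and 20 replicate three-group cohorts
(n = 30/group, δ = 0.3 in one group) for effect recovery — sizes chosen so
each study's Monte-Carlo error is comfortably below the property being
asserted while the whole suite stays quick to run.

## Known limitations

* The two titration schedules cannot be distinguished from the package's
  own outputs alone; analyses of external datasets should set
  `exponent_mode` to whichever schedule generated them.
* `μ` and `k` trade off in short sessions; with fewer than ~50 informative
  trials the uniqueness diagnostics flag many sessions, by design.
* The bootstrap's `+1/(B+1)` floor means p-values below `1/(B+1)` are not
  attainable; use larger `B` when very small p-values matter.
* The MAD filter is applied per phase on log10 k; with fewer than 3
  eligible values it is skipped.
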
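---
title: "Learning individualized screening schedules with linear Q-functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning individualized screening schedules with linear Q-functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issq)
```

## The decision problem

A participant in a low-dose CT lung-screening program presents with a
non-calcified pulmonary nodule. At each of up to three decision points the
clinician chooses among an immediate diagnostic work-up (`DIAG`), a repeat
scan in 3 months (`F3`), a repeat scan in 12 months (`F12`), or
discontinuing screening (`END`). `DIAG` and `END` end the schedule; `F3`
and `F12` continue it, advancing the clock 91 and 365 days respectively.
Ruling out continuations after a terminal action leaves exactly 22 legal
schedules over a three-stage horizon.

Each schedule, confronted with a patient's ground truth (cancer or not,
and if so the time of diagnosis), is scored with

$$R = 100 - 70\,\mathrm{misdiagnosis} - 60\,\mathrm{missed}
        - 5\,\mathrm{delayed} - 10\,n_\text{tests},$$

with misdiagnosis = `DIAG` for a cancer-free patient, missed = `END` for a
cancer patient, delayed = resolution strictly after the ground-truth
diagnosis time, and $n_\text{tests}$ the number of F3/F12 scans. Only
follow-up scans count as tests — under that counting the attainable range
over all legal schedules is exactly $[10, 100]$ (the lower bound is a
cancer-free patient sent to work-up after two annual scans), which the
test suite verifies by brute-force enumeration. A cancer patient whose
schedule ends on a follow-up scan at stage 3 is neither misdiagnosed nor
missed; only the delayed flag can fire. We allow missed and delayed to
co-occur (both penalties apply); disallowing it would only raise the
cancer-patient floor by the delayed weight.

## Q-learning on the episode bank

Crossing the 22 scenarios with every training patient yields the episode
bank; with the design's 462 training patients that is 10,164 episodes. On
this bank we fit stage-wise Q-functions by backward induction,

$$Q_t(s_t, a_t) = E\left[R_t + \gamma \max_a Q^*_{t+1}(s_{t+1}, a)\right],
\qquad \gamma = 1,$$

with the final stage fitted first on its stage reward and each earlier
stage on the pseudo-outcome combining its stage reward with the maximized
prediction of the later model **at the episode's realized next state** —
a model-free temporal-difference scheme that never estimates a transition
model. Each $Q_t$ is an ordinary-least-squares linear model containing the
state main effects, action dummies, and the full state × action
interaction block; the interactions are what let the optimal action depend
on the state at all. We include action main effects (an intercept per
action) so that actions can shift the Q-surface even at the reference
state; without them the saturated-design identity below could not hold.
Inference is the conventional OLS t-test at $\alpha = 0.05$, reported per
stage and variable by `effect_significance()`.

The total reward is decomposed across stages as: each F3/F12 stage carries
its own $-10$ test cost, and the final stage carries the base reward minus
the outcome penalties. The per-stage rewards sum to $R$ exactly, and with
$\gamma = 1$ the fitted total value is invariant to how the terminal
penalties are distributed — a different admissible decomposition changes
the stage models but not the policy's total-value ordering.

Greedy recommendation evaluates the stage model at the interpolated state
and takes the argmax; exact ties break by the fixed least-harm order
`END` > `F12` > `F3` > `DIAG`. Recommended sequences are by construction
always members of the 22-scenario set.

### State variables and the eight variants

Diameter at an arbitrary decision time is linearly interpolated between
screens and linearly extrapolated through the **last two** observations
beyond them (a global fit would smooth over the very growth signal the
delta variants use); a single observation is carried forward, and
extrapolated diameters are clamped at 0 mm. Attenuation
(solid/part-solid/non-solid) and margin (spiculated or not) use last
observation carried forward. The growth rate between two decision times is
$\Delta_i = (d_i - d_{i-1})/(t_i - t_{i-1})$ in mm/day.

The eight variants `D`, `DN`, `DP`, `DNP`, `Dd`, `DdN`, `DdP`, `DdNP`
combine three choices: diameter history coded directly (the decision-time
diameters observed so far) or as the delta; the appearance block; the
patient-information block. Stage 1 has a single measurement, so all
variants use the current diameter only there and the delta is undefined at
stage 1 by construction. Reference levels for the dummy coding: solid
attenuation, non-spiculated, male, former smoker, no family history;
the reference action is `F12`, the default behaviour of annual screening.
Continuous features are left in natural units (mm, years, pack-years) so
coefficients remain clinically interpretable.

## What the synthetic generator emulates

Real nested case-control screening records are access-restricted, so the
generator reproduces the statistical structure the analysis needs:

* **Design**: 308 cancer cases, controls matched 1:1 on the year of
  diagnosis (`floor(diagnosis_time/365)`, as the calendar origin of the
  source design is not part of the data), and a stratified 462/154
  train/validation split via largest-remainder apportionment.
* **Covariates**, drawn per arm and calibrated so the pooled sample
  reproduces the published marginals (mean age 63.0 y, 58.8% men, median
  53 pack-years, 25.5% family history; case/control follow-up medians 1018
  vs 2449.5 days). Age is a truncated normal on the 55–74 eligibility
  window whose latent mean is solved numerically so the *truncated* mean
  hits the target; pack-years and follow-up are lognormals fitted to the
  published median/IQR. We follow the per-arm table for the current-smoker
  proportions (48.1% cases / 54.5% controls), whose pooled value (~51%)
  the source's prose summary disagrees with slightly.
* **Nodule dynamics**: a malignant nodule's true diameter grows linearly
  at a patient-specific lognormal rate (median 3.65 mm/year, log-sd 0.6 —
  within the range of reported solid-nodule growth); a benign nodule is
  constant with Gaussian measurement jitter (sd 0.5 mm). Observed
  diameters are rounded to integer millimetres, as radiology reports do.
* **Ground truth**: a case's diagnosis time is the first scheduled screen
  at which the true diameter reaches the 15 mm trigger, else an
  interval-detection time drawn uniformly from days 731–1460. Case
  baselines are truncated below the trigger so diagnosis always follows
  baseline and every case has at least two screens. Controls' series are
  not truncated at the matched case's index year by default (a config
  switch enables it), since the source design leaves this open.
* Cancer stage at diagnosis is sampled from the published distribution for
  reporting only; the prose list and the table in the source disagree, and
  we follow the table's counts.

The generator is deterministic given its seed (the matching and split use
derived sub-seeds), to the output byte.

What it does **not** emulate: measurement error correlated across screens,
multiple nodules per patient, nodules that regress or accelerate,
informative missingness of screens, or any dependence of covariates on
nodule biology beyond the arm difference. Tests passing on these cohorts
therefore certify the estimator's correctness and the pipeline's
arithmetic, not clinical performance on real screening data — the
published real-data rates are not reproducible from synthetic cohorts, and
the package makes no attempt to tune toward them.

## Evaluation and benchmarking

`evaluate_policy_rates()` reports misdiagnosis (denominator: cancer-free
patients) and missed/delayed diagnosis (denominator: cancer patients, the
only patients for which a ground-truth diagnosis time exists) as
percentages. `rank_models()` orders variants by worst-rate-then-mean: the
"lowest rates" criterion is operationalized as minimizing the maximum of
the three rates, which is the reading under which a model controlling all
rates to a similar level beats one with a single excellent rate.

The guideline benchmarks are **editable JSON rule tables** with
size/attenuation/growth thresholds loosely styled after US and Chinese
screening protocols (shipped under `inst/extdata/` with `_synthetic` in
the filename); they are deliberately non-authoritative stand-ins, since
reproducing guideline logic verbatim is neither licensed nor needed for a
benchmark harness. A nodule is "growing" when its delta exceeds the
table's threshold (default 1.5–2 mm/year); the flag is false at stage 1.

The head-to-head comparison resolves the "earliest work-up *or* shortest
follow-up" criterion as an explicit lexicographic order — cancer patients:
earliest `DIAG` time, then shortest follow-up, then fewer tests;
cancer-free: shortest follow-up, then fewer tests, then no `DIAG` — and
marks every policy tying at the best rank optimal, so selection
probabilities can sum above 100%. Subgroup reports preserve empty
subgroups with `n = 0` and, because multiplicity is counted identically,
subgroup probabilities weighted by size reproduce the overall probability
exactly.

## Numerical choices and degenerate inputs

* Month arithmetic is fixed at 3 months = 91 days, 12 months = 365 days,
  keeping all schedule times integers.
* The delayed flag uses strict inequality (resolution at exactly the
  ground-truth time is on time).
* Argmax ties use the absolute tolerance $10^{-9}$ on Q-values.
* A rank-deficient stage design (e.g., a constant feature) is an error
  naming the collinear columns, not a silent drop.
* Zero-residual fits (possible on noiseless constructed banks) are
  legitimate; their p-values are degenerate and excluded from significance
  grouping where undefined.
* `gamma = 0` reduces every stage fit to a myopic regression on its own
  stage reward, which the tests use as a limit check.

## Problem sizes used by the test suite

The suite runs the full default-scale design where the claim is about the
design itself (616 patients, 10,164 training episodes), and smaller
cohorts (8–25 cases) where the claim is structural. The marginal-
convergence property uses 50 seeded replicates at n = 616; coefficient-
recovery properties use 100 replicates of n = 2000 single-stage fits. The
saturated-design and greedy-optimality identities run on a two-patient
noiseless instance (one flat benign 4 mm nodule, one malignant nodule
growing 8 mm/year from 12 mm with a far-future diagnosis time), chosen so
that every stage's true Q-function is exactly affine in the delta-variant
features and the identities hold to machine precision.

## Known limitations

The Q-functions are linear by design — interpretability is the point — so
the policy class cannot represent non-monotone size effects within a
stage. The episode bank treats the 22 scenarios as exhaustive and the
three-stage horizon as fixed. No confidence intervals are provided for
policy values, and no statistical test compares two policies' rates. The
default rule tables are approximations for benchmarking, not clinical
guidance.
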
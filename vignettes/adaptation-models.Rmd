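---
title: "State-space models of stride-by-stride motor adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-space models of stride-by-stride motor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strideadapt)
```

## The problem

Robot-assisted gait training applies torque pulses to the hip and knee
while a person walks on a treadmill, and the person's propulsion
mechanics — hip extension angle (HE) at peak anterior ground reaction
force, and the normalized propulsive impulse (NPI) — adapt stride by
stride, both while the assistance is on and after it is removed. Planning
such training (and eventually optimizing it in the loop) needs a
quantitative model of that adaptation: how fast the response builds up
during the intervention, and whether anything persists once the torque
pulses stop (the *after-effect*, the quantity rehabilitation actually
cares about).

`strideadapt` implements five discrete-time state-space models of that
process, a conditioning pipeline for stride series, a constrained
multi-start least-squares fitter scored by R² and AIC, the group-level
statistical comparison of those scores, and a synthetic-cohort generator
emulating the experimental protocol (100 baseline strides, 200
intervention strides with the exoskeleton input on, 100 washout strides;
16 participants).

## The model families

All five families share the observation structure: at stride $n$ the
measured outcome is $y(n)$, the exoskeleton input is $u(n)$ (1 during the
intervention block, 0 elsewhere), and one or two internal states carry
the nervous system's plan across strides. Every family is reduced to the
canonical linear form

$$X(n+1) = A\,X(n) + B\,u(n), \qquad y(n+1) = C\,X(n+1) + D\,u(n+1),$$

simulated from $X(0) = x_{init}$ (zero by default — after baseline
referencing, the pre-intervention response is ≈ 0), with $u(0)$ taken as
the schedule's first entry. The families, with their free parameter
counts:

* **single-state** (4: $a', b', c, d$) — error-based learning
  $x(n+1) = a\,x(n) + b\,e(n)$ with $e(n) = y(n) - x(n)$, collapsed to
  the canonical $a' = a - b + bc$, $b' = bd$. A scalar pole: exponential
  build-up and exponential washout.
* **UDL** (3: $a_u, b_u, d_u$) — use-dependent learning, where the next
  plan is pulled toward the previously *produced* output:
  $x(n+1) = a_u x(n) + b_u y(n) + (1 - a_u - b_u)x_0$ with the reference
  movement $x_0$ fixed at 0 (baseline referencing makes the unperturbed
  movement zero). Canonically $A = a_u + b_u$, $B = b_u d_u$, $C = 1$,
  $D = d_u$.
* **two-state fast/slow** (5: $a_f, b_f, a_s, b_s, d$) — two error-driven
  states with $a_s > a_f > 0$ and $b_f > b_s$ (the fast state learns more
  and forgets faster); $A = \mathrm{diag}(a_f, a_s)$,
  $B = d\,(b_f, b_s)^T$, $C = (1, 1)$, $D = d$. Produces temporary
  after-effects that decay at the slow state's rate.
* **modified UDL** (4: $a_{mu}, b_{mu}, c_{mu}, d_{mu}$) — the UDL model
  with the reference state made dynamic:
  $x_0(n+1) = c_{mu} x_0(n) + (1 - c_{mu})\,y(n)$. With state
  $(x_0, x)^T$,
  $$A' = \begin{pmatrix} c_{mu} & 1 - c_{mu} \\ 1 - a_{mu} - b_{mu} &
  a_{mu} + b_{mu} \end{pmatrix}, \quad B = d_{mu}\begin{pmatrix}
  1 - c_{mu} \\ b_{mu}\end{pmatrix}, \quad C = (0, 1), \quad D = d_{mu}.$$
  The rows of $A'$ sum to 1, so $A'$ always has an eigenvalue exactly 1
  along the consensus direction $(1,1)$; the free eigenvalue is
  $a_{mu} + b_{mu} + c_{mu} - 1$. That structural unit eigenvalue is the
  model's point: under constant input the output grows linearly
  (gradual, non-exponential change), and under washout the two states
  equalize at a *persistent* after-effect rather than decaying to zero.
* **two-state** (9) — the general $2 \times 2$ $(A, B, C, D)$ with no
  structure beyond stability; the supermodel of both two-state families.

### After-effect asymptotics

Under washout ($u \equiv 0$) a strictly stable model's output decays to
zero — this is why the single-state and UDL families cannot represent
lasting training effects. For the modified UDL model the quantity
$(1 - a_{mu} - b_{mu})\,x_0(n) + (1 - c_{mu})\,x(n)$ (the left
eigenvector of the unit eigenvalue) is conserved stride to stride, and
the output converges to

$$y_\infty = \frac{(1 - a_{mu} - b_{mu})\,x_{0,w} + (1 - c_{mu})\,x_w}
{2 - a_{mu} - b_{mu} - c_{mu}},$$

where $(x_{0,w}, x_w)$ is the state entering washout.
`after_effect_asymptote()` implements this closed form (degenerate when
$a_{mu} + b_{mu} + c_{mu} = 2$, a second marginal mode).

```{r}
m <- model_spec("modified_udl", c(amu = 0.6, bmu = 0.2, cmu = 0.9, dmu = 1))
eigen_analysis(canonical_form(m))$eigenvalues
after_effect_asymptote(m, c(0.21, 0.38))
```

### Stability convention

Fits are constrained to a stable response, with eigenvalue magnitudes up
to $1 + 10^{-9}$ admitted. Marginal stability must be allowed because the
modified UDL transition matrix *structurally* carries a unit eigenvalue;
a strict-contraction constraint would make the family infeasible.
`check_constraints()` reports violations (stability, the fast/slow
ordering, $c_{mu} \in [0, 1]$) as data, never as errors.

### Timing alignment

The recursion is implemented exactly as written above: the state update
uses the same-stride input $u(n)$ and the output equation uses
$u(n+1)$. The input schedule holds $u(1 \dots N)$ aligned stride-by-stride
with $y(1 \dots N)$, and $u(0)$ is taken as the schedule's first entry
(zero for protocol schedules, which begin in baseline).

## Preprocessing

`preprocess()` composes three steps, in order:

1. `fill_missing()` — linear interpolation of interior gaps against the
   stride index; leading/trailing gaps take the nearest observed value
   (interpolation is undefined there — an explicit choice, not a
   reconstruction of the original procedure, which did not state its edge
   behavior).
2. `smooth_within_session()` — each stride averaged with its 2 preceding
   and 2 subsequent strides *within the same session* (baseline,
   intervention, washout), windows shrinking at session edges so nothing
   bleeds across the transitions where the dynamics of interest live.
3. `reference_and_scale()` — the mean over baseline strides 81–100 (once
   participants have settled) is subtracted everywhere, then everything
   is divided by the sample standard deviation (the $n-1$ denominator) of
   the referenced values from stride 81 to the end. The SD is computed
   after the subtraction; the order is immaterial to the subtraction but
   fixes the scale definition. Post-conditions, verified on every
   generated cohort: reference-window mean ≈ 0, normalization-window
   SD = 1. Constant series are rejected (zero SD).

## Estimation

`fit_model()` minimizes the free-run simulation error
$\sum_{n=81}^{N} (y_{obs}(n) - y_{sim}(n))^2$, simulating open-loop from
a zero state at the window origin. The free-run objective (rather than
one-step-ahead prediction error) is the design choice here: the models
carry no process-noise term and the scientific claims are about
trajectory shapes during and after training, so the simplest consistent
reading of a least-squares fit is the trajectory error. A
prediction-error/Kalman formulation with an explicit noise model is a
deliberate non-goal.

Numerics that matter:

* **Multi-start.** 100 random restarts by default, drawn uniformly from
  per-parameter boxes declared in `fit_options()` (retention-type
  parameters on $[0,1]$, learning-type on $[-1,1]$, gains on $[-5,5]$ in
  normalized response units). Draws are row-nested, so the first $m$
  starts of an $n > m$ restart run coincide — the best RSS is
  non-increasing in the restart count for a fixed seed. Ties within
  $10^{-12}$ break by restart index.
* **Local solver.** L-BFGS-B with box bounds (a scalar pole bound
  $|a'| \le 1$ is exact box stability), a finite-difference step of
  $10^{-7}$ and a tight `factr` of $10^4$. Loose gradient steps and
  tolerances demonstrably stall in the shallow curved valleys of this
  objective; the defaults were chosen for reliable basin convergence.
  Nelder-Mead is the fallback if a restart errors.
* **Constraints.** Non-box constraints (the fast/slow ordering, the UDL
  and modified-UDL pole bounds, the two-state spectral radius) enter as a
  smooth quadratic penalty with a $10^{-6}$ interior margin; strict
  inequalities are enforced as ≥ with that margin. Near-boundary iterates
  are projected back into the feasible set, and every returned optimum
  must pass `check_constraints()`.
* **Chained initialization.** `fit_all_families()` fits UDL, fast/slow
  and modified UDL by random multi-start, then seeds the single-state fit
  from the best UDL result ($a' = a_u + b_u$, $b' = b_u d_u$, $c = 1$,
  $d = d_u$) and the two-state fit from the best modified-UDL *and*
  fast/slow realizations, embedded verbatim. The seeded specs are also
  scored directly (zero-iteration candidates), so each supermodel's R² is
  never below its submodels' — the nesting inequalities hold by
  construction, not by optimizer luck.
* **Scores.** $R^2 = 1 - RSS/TSS$ about the fit-window mean (negative
  values are meaningful: worse than the mean); AIC in the least-squares
  form $n \ln(RSS/n) + 2k$. Additive AIC constants are dropped — they
  cancel in every within-dataset comparison, and model *rankings* are the
  quantity of interest. A perfect fit ($RSS = 0$) yields $-\infty$ with a
  warning; a constant observed window makes R² undefined (`NA`, with the
  RSS still reported).

### Identifiability of the modified UDL family

Two facts about this family shape how its fits must be read:

1. **Label switching.** The input-output map is *exactly* invariant under
   exchanging $a_{mu}$ and $c_{mu}$ (with $b_{mu}, d_{mu}$ fixed): the
   identifiable quantities are $d_{mu}$, $b_{mu}$, $a_{mu} + c_{mu}$ and
   $a_{mu} c_{mu}$, so data determine the pair $\{a_{mu}, c_{mu}\}$ only
   as an unordered set. Fits are canonicalized to the slow-reference
   branch $c_{mu} \ge a_{mu}$ — the regime that motivates the model, and
   the same resolution the fast/slow family hard-codes via $a_s > a_f$.
2. **A flat ridge.** Even on the canonical branch, the sensitivity of the
   trajectory to $a_{mu}$ is weak: with the default synthetic truth and
   observation noise of SD 0.05 over the 320-stride fit window, the
   Cramér–Rao bound for $a_{mu}$ is roughly 0.08, while $b_{mu}$,
   $c_{mu}$ and $d_{mu}$ are determined to ~0.03 or better. Across a
   16-participant cohort the worst-case $a_{mu}$ error of *any* unbiased
   estimator is therefore expected in the 0.2–0.35 range — which is what
   the recovery suite measures (fits whose RSS beats the truth's RSS, so
   optimization is not the limit). Blanket per-parameter recovery claims
   tighter than that bound are not achievable under these conditions and
   the corresponding check is intentionally left failing rather than
   loosened; median recovery error is ~0.01–0.02 and median R² ≈ 1.

## Group-level comparison

`compare_models()` reproduces the comparison workflow on a units ×
families table of R² or AIC values: Shapiro–Wilk on every column, with
the parametric branch (one-way repeated-measures ANOVA, then paired t)
taken only if *all* columns look normal, otherwise Friedman plus Wilcoxon
signed-rank; all 10 pairs of the 5 families are tested at the
Bonferroni-corrected level $0.05/10 = 0.005$. Choices the original
procedure left unstated, made explicit here: no sphericity correction is
applied to the RM-ANOVA (and the report says so); Wilcoxon zeros get the
Pratt treatment (zeros ranked, then dropped from the signed statistic,
with zero- and tie-corrected normal variance), since discarding zeros
silently would overstate evidence on near-tied fitness columns; a
fully-tied table yields a Friedman statistic of 0 with p = 1; an all-zero
difference pair is reported non-significant with a `degenerate` flag,
while a constant *nonzero* difference is maximal evidence (p = 0), not a
degeneracy. The post-hoc table is computed regardless of the omnibus
outcome, with the omnibus result recorded alongside, so the gating
decision stays visible rather than implicit.

On null tables (five i.i.d. normal columns, 16 rows) the family-wise
false-positive rate of the pairwise procedure at the corrected level
stays below 5% — with 10 tests at 0.005 the union bound gives 5%, and
the positive correlation between tests sharing columns pulls the realized
rate below it (~3.5–4% measured over 1000 tables).

## The synthetic-data generator

`generate_cohort()` emulates the study conditions: 16 participants, the
100/200/100 protocol, per-participant parameters jittered around a truth
spec, observation noise added to the simulated trajectory, optional
missing strides. Default choices, made once:

* **Truth**: modified UDL with $a_{mu} = 0.6$, $b_{mu} = 0.2$,
  $c_{mu} = 0.9$, $d_{mu} = 1$ — moderate movement retention, slow
  reference drift, a clear training ramp and a persistent after-effect;
  the regime the model was built to express.
* **Input level** $u = 1$, with the gain $d$ absorbing pulse magnitude
  and direction: responses are SD-normalized anyway, and no mapping from
  physical torque to model input units exists. Distinct pulse conditions
  are represented as distinct condition labels with distinct truth
  parameters, not distinct $u$.
* **Noise** is i.i.d. Gaussian on $y$ (SD 0.05 by default), the simplest
  observation model; **jitter** is Gaussian per parameter (SD 0.02) with
  rejection resampling at constraint boundaries.
* **Reproducibility**: everything is deterministic given the seed, and a
  fixed seed reuses the same underlying noise draws across noise levels
  (common random numbers), so noise-sweep comparisons — e.g. recovery
  error shrinking monotonically as $\sigma \to 0$ — are not confounded by
  resampling.

What the generator deliberately does *not* emulate: the short-range
autocorrelation of real stride series (the 5-stride smoothing in
preprocessing induces some of it downstream), biomechanics (no gait
kinematics, ground-reaction forces, or torque-pulse physics), any
coupling between the HE and NPI outcomes, and real inter-participant
structure beyond parameter jitter. Passing tests on this generator
demonstrate that the pipeline recovers what it simulates under the
stated noise model — not that the five families describe real gait data;
that question needs the experimental data the package does not ship.

## Problem sizes used by the test and acceptance suites

Unit tests run on shortened protocols (e.g. 100/120/60 strides) with
10–30 restarts; the end-to-end suites use the full 400-stride protocol,
16-series cohorts and 100 restarts for the recovery study, 40–50
restarts for nesting and washout checks, and 1000 replicate tables for
the false-positive study — sizes at which every stochastic margin in the
assertions is comfortable while the whole suite stays in the minutes
range on one CPU.

## Known limitations

* The fitter assumes an additive, uncorrelated observation-noise model
  implicitly through its least-squares objective; correlated residuals
  (which smoothing creates) bias no parameter but invalidate naive
  standard errors, which is why the package reports none.
* $a_{mu}$ is weakly identified at realistic noise (see above); treat
  individual-participant $a_{mu}$ estimates with corresponding caution
  and prefer the identifiable combinations.
* The CLI's `fit` subcommand reconstructs the input schedule from session
  labels with $u = 1$; interventions with stride-varying input need the
  programmatic API.
* AIC values use the least-squares form without small-sample correction;
  rankings, not absolute values, are the supported use.
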
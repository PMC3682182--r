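---
title: "Detecting consolidation of rapid learning in resting-state effective connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting consolidation of rapid learning in resting-state effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restdcm)
```

# The scientific question

Rapid perceptual learning — the steep early phase of improvement on a
sensory task, within a single session — is accompanied by changes in evoked
brain responses. `restdcm` implements, on fully synthetic data, the
inference chain used to ask a further question: does that learning also
change the *spontaneous* coupling between brain regions at rest, and does
the change persist a day later, as a consolidation account predicts?

The design that frames everything is a 2 (day) × 2 (time) arrangement of
four resting-state runs: before and directly after a learning session on
day 1, and at the same times on day 2 (without learning). A hippocampal
seed region is identified from the learning-modulated task response; a
striatal region is identified from a coupling-change screen; their directed
coupling across the four rest runs is then compared across ten hypotheses
of *when* and *on which connections* coupling changed.

# The models

## Behavior

Performance is summarized per block as inverse efficiency (IE), mean
reaction time divided by accuracy (seconds; lower is better). Trials whose
RT deviates from their block mean by more than three sample standard
deviations are excluded first, in a single pass. The 25 motion-block IE
values are fitted with

$$y = a\,e^{-bx},$$

where $x$ is the block index (starting at 1 — a convention, configurable
through the `x` argument of `fit_learning_curve()`), $a$ is the amplitude
(s) and $b$ the learning rate (per block). The *fitted* values are what
enters the task GLM as a parametric modulator: they are the subject's
smoothed learning trajectory.

Fitting uses Levenberg–Marquardt least squares with multiple starting
values of $b$ (0.01, 0.05, 0.2), keeping the lowest residual sum of
squares; this avoids local minima on noisy curves. A negative $b$ is
permitted but flagged. Degenerate inputs (fewer than three blocks,
non-positive IE, a zero-accuracy block) raise classed errors rather than
propagating `NaN`s.

## Task GLM

`fit_first_level()` is an ordinary least-squares convolution GLM on a
region-mean series: condition boxcars and an IE-modulated motion regressor
convolved with the canonical double-gamma HRF (peak ≈ 5 s, undershoot,
unit-sum normalized), per-run discrete-cosine high-pass columns (128-s
cut-off for task data) and per-run intercepts. The parametric modulator is
mean-centered per run before convolution, so that the modulated regressor
is orthogonal to the condition mean by construction. Degrees of freedom are
$n - \mathrm{rank}(X)$, so the filtering columns are accounted for.
Contrast estimates are carried to a one-sample t-test across subjects.
Serial correlations are not modeled (OLS); the type-I error of the
modulator t-statistic under white noise is verified by simulation in the
test suite.

## PPI screen

For each rest run, the coupling between seed and target is the OLS
regression slope of the target on the seed after partialling out a
constant and the 256-s DCT basis from both. The four slopes
$\beta_1,\dots,\beta_4$ enter fixed factorial contrasts:

* main effect of day: $(\beta_1+\beta_2)-(\beta_3+\beta_4)$,
* main effect of time: $(\beta_1+\beta_3)-(\beta_2+\beta_4)$,
* day × time interaction: $(\beta_2-\beta_1)-(\beta_4-\beta_3)$.

The interaction is the screen: it is zero for a pure within-day adaptation
pattern `[0 1 0 1]` and equals 2 for the consolidation pattern `[0 2 1 1]`
(per unit of coupling change). Contrast signs are a convention; group tests
are two-sided. Because the literature labels these effects inconsistently
("run" vs "time"), both main effects are always emitted alongside the
interaction.

## Dynamic causal model

The neuronal model is bilinear: with $z \in \mathbb{R}^2$ the latent
activity of the two regions,

$$\dot z = \Big(A + \sum_j m_j(r)\,B_j\Big) z + w(t),$$

where $A$ has fixed self-connections of $-0.5$ Hz on the diagonal and free
between-region couplings (Hz), and each modulator $j$ is a run-weight
4-vector $m_j$ scaling a bilinear matrix $B_j$ that is nonzero only on the
modulated connections. Resting-state data need no driving input; the
endogenous fluctuation $w(t)$ does the driving. The three change types are

| type | weights | meaning |
|---|---|---|
| adaptation | `[0 1 0 1]` | non-specific post-session change, both days |
| learning | `[0 1 0 1]` + `[0 1 0 0]` | adaptation plus a day-1-only change |
| consolidation | `[0 1 0 1]` + `[0 2 1 1]` | adaptation plus a learning change persisting at half level on day 2 |

Learning and consolidation models carry two bilinear parameters per
modulated connection (one per weight row). Crossing the three types with
forward / backward / bidirectional modulation and adding the null model of
no change gives twelve candidates of which the three null variants are
identical — ten unique models (`build_model_space()`).

Hemodynamics are the balloon model: vasodilatory signal $s$, inflow $f$,
venous volume $v$, deoxyhemoglobin $q$, with BOLD read-out
$y = V_0\,(k_1(1-q)+k_2(1-q/v)+k_3(1-v))$ and standard constants
($\kappa = 0.64\,s^{-1}$, $\gamma = 0.32\,s^{-1}$, $\tau = 2$ s,
$\alpha = 0.32$, $E_0 = 0.32$, $V_0 = 0.04$). The *generator* integrates
the full nonlinear cascade; the *inversion* uses its first-order
linearization around the resting fixed point, which the test suite shows
matches the nonlinear response to within 5% RMS for small inputs.

## Inversion: state space, Kalman likelihood, Laplace evidence

Each run is a time-invariant linear-Gaussian state space with twelve
latent states — two neuronal, two Ornstein–Uhlenbeck innovation states
modeling the temporally smooth endogenous fluctuations (correlation
half-life 2 s, no free parameters beyond the fluctuation scale
$\sigma_z$; set `innovation_half_life = 0` for a white-noise drive), and
four linearized hemodynamic states per region — discretized
*exactly* at the TR: $\Phi_r = e^{F_r \cdot TR}$, with the innovation
covariance obtained from the stationary covariance $P_\infty$ (solving the
continuous Lyapunov equation $F P + P F^\top = -L$) as
$Q_r = P_\infty - \Phi_r P_\infty \Phi_r^\top$. Euler discretization would
bias the dynamics at a TR of 2.176 s; the matrix-exponential route has no
step-size error. Runs are separate acquisitions: the state is initialized
at its stationary distribution per run and never carried across runs,
while a single parameter vector is shared — the "concatenation" happens at
the parameter level.

The marginal likelihood of each run is computed exactly by the
Kalman-filter prediction-error decomposition; the suite's cornerstone test
verifies it against a brute-force joint-Gaussian density on random small
instances to $10^{-8}$. Before fitting, the first five volumes of every run
are dropped and a constant plus the 256-s DCT basis is partialled out per
run.

Parameters $\theta$ = (two couplings, the bilinear parameters of the
model, three log noise SDs) get zero-mean Gaussian shrinkage priors
(SD 0.25 Hz on couplings and bilinear terms, SD 1 on log noise SDs; prior
mean $\log 0.1$ for the noise scales). The fit is maximum-a-posteriori by
BFGS, and the log model evidence is the Laplace approximation

$$\log p(y \mid m) \approx \log p(y \mid \theta^*) + \log p(\theta^*)
  + \tfrac{d}{2}\log 2\pi - \tfrac12 \log |H|,$$

with $H$ the negative Hessian of the log joint at $\theta^*$ (central
finite differences). If $H$ is not positive definite, the nearest-PD
eigenvalue clamp is used and the fit is flagged (`hessian_pd = FALSE`).
Unstable parameter excursions (any run-effective matrix with a
non-negative real eigenvalue, with a small margin) and excursions beyond
eight prior SDs are rejected by smooth barrier values so the optimizer
backtracks rather than evaluating degenerate models.

Model comparison is fixed-effects: log evidences are summed over subjects,
reported relative to the weakest model, and the winner must beat the
runner-up by 3 nats — a Bayes factor of about 20:1 — for the criterion to
be met. Ties are reported as ties, never silently broken. Under the winning
model, the run-wise coupling change of connection $c$ is
$\sum_j m_j(r)\, \hat b_{jc}$, reported relative to run 1 (exactly zero
under all shipped weight patterns).

# The synthetic cohort

`gen_behavior()`, `gen_rest_bold()`, `gen_task_bold()` and `gen_cohort()`
generate data with the statistical structure the analysis assumes:

* **Behavior.** Per-trial correctness is Bernoulli with a block-wise
  probability rising from `acc_start` (0.65) to `acc_asymptote` (0.92) as
  a saturating exponential in the block index; RT is truncated normal with
  a mean chosen so that the expected block IE is *exactly*
  `ie_asymptote + ie_amplitude * exp(-learning_rate * x)` (defaults 0.6 s,
  0.7 s, 0.15/block). A saturating-exponential accuracy rise was chosen
  over a free logistic because it shares its parameterization with the IE
  curve and degenerates cleanly to perfect accuracy. Control blocks sit at
  99% accuracy with no trend; 1% of trials are omitted (no response,
  counted as errors, contributing no RT). Blocks strictly alternate, the
  starting condition is counterbalanced across subjects.
* **Rest BOLD.** The bilinear neuronal model is integrated by
  Euler–Maruyama at dt = 0.05 s (self-convergence at this step is verified
  to <1% RMS), with AR(1) endogenous fluctuations (correlation half-life
  2 s, low-frequency spectral density $\sigma_z^2$), passed through the
  full nonlinear balloon cascade, burned in for 32 s per run, sampled at
  TR = 2.176 s, 276 volumes × 4 runs. Slow drift (the three
  lowest-frequency DCT components with random amplitudes, SD 0.4%) and
  white observation noise are added. Runs are re-initialized
  independently.
* **Task BOLD.** Five runs of 246 volumes; the learning region's motion
  response is linearly modulated by the subject's fitted IE (gain 0.8% per
  centered IE unit); a second region responds to both conditions without
  modulation. The generator and the GLM share the regressor construction,
  so noiseless recovery is exact — a deliberate closed-loop check of the
  design code, not a statement about real data.

## Default effect sizes

The true change model defaults to bidirectional consolidation with average
couplings of 0.10 Hz, adaptation changes of 0.04 Hz and consolidation
changes of 0.15 Hz per connection, $\sigma_z = 0.05$ and observation noise
0.05% — about 1% resting BOLD fluctuations, with the run-2 effective
coupling (0.44 Hz) still comfortably inside the stable region (slowest
eigenvalue $-0.06$ Hz). These values were chosen so that single-subject
model recovery is *achievable but not trivial*: subject-level evidence
margins for the true model over its closest competitor (the learning
model) range from under 1 to about 18 nats at the full run length. All of
them are exposed in `ground_truth()` rather than hard-coded.

## What the generator does *not* emulate

Head motion, physiological (cardiac/respiratory) structure, scanner
spikes, spatial structure of any kind (everything is a region-mean
series), non-Gaussian RT tails, inter-subject variability in effect sizes
(the shipped cohorts share one ground truth), and hemodynamic variability
across regions. Passing tests therefore demonstrate that the *inference
chain* is correct and calibrated under its own assumptions — not that it
is robust to the full mess of real fMRI.

# Numerical and design choices

* Discretization at the TR via the matrix exponential and a Sylvester
  solve (no integration error); the generator integrates the nonlinear
  system at dt = 0.05 s.
* The optimizer starts at the prior mean, warm-started from the null-model
  fit across the model space; jittered restarts are attempted only when a
  start fails. A fixed set of always-on extra starts was not adopted: on
  this model class the posterior is well behaved near the prior mean and
  the extra starts tripled runtime without changing any result.
* Per-subject model fits are deterministic given the data (BFGS with fixed
  tolerances and finite-difference steps), so reports are bit-identical
  on re-runs with the same seed.
* Subject screening mirrors a learning-cohort workflow: subjects at
  ceiling (mean accuracy ≥ 0.97) or floor (≤ 0.60, or non-positive fitted
  learning rate) are flagged; the pipeline excludes them between the
  behavior and GLM stages (configurable).
* Problem sizes in the test suite are scaled to the question being asked:
  oracle-equivalence tests run at $T \le 10$; calibration of the PPI
  screen uses 500 replicate 11-subject cohorts at 150 volumes per run; the
  null-model false-positive rate of the selection criterion uses 50
  two-subject cohorts at 60 volumes; the headline recovery runs the full
  11-subject, 276-volume design.

Modeling the temporal smoothness of the endogenous fluctuations in the
inversion matters for calibration: with a white-noise drive, the
run-specific bilinear parameters absorb the spectral mismatch on null
data and the false-positive rate of the evidence criterion inflates
measurably. The test suite checks the calibrated behavior directly.

# Known limitations

* The inversion linearizes the hemodynamics; with endogenous fluctuations
  much stronger than the defaults the generator's nonlinearity becomes
  visible to the fit and evidence comparisons degrade gracefully but
  measurably.
* The Laplace evidence is a local approximation; for weakly identified
  bilinear parameters (short runs, small effects) its Occam penalty is
  approximate, which is why the calibration tests check the false-positive
  rate of the decision rule directly.
* Fixed-effects model selection assumes one model generated every
  subject's data; random-effects BMS is out of scope.
* Two regions only, no driving inputs, no nonlinear (second-order)
  coupling terms.

# A worked example

```{r example, eval = FALSE}
library(restdcm)

cfg <- pipeline_config(
  n_subjects = 5,
  scan = scan_config(rest_volumes = 100)  # desk-scale illustration
)
rep <- run_pipeline(cfg, seed = 42)

glance(rep$bms)
autoplot(rep$bms)
plot_coupling_timecourse(rep$coupling)
```

The full-scale replay (11 subjects, 276 volumes per rest run, all ten
models) is what `scripts/acceptance.R` executes; see the README for how to
run it.
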
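---
title: "Modeling the sleep onset process as a wake probability curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the sleep onset process as a wake probability curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(wakeprob)
```

## The problem

Falling asleep is not an event but a process. Behavioral responsiveness, motor
tone, and EEG rhythms all change gradually — and on different timescales — as
a person drifts from wake to sleep, yet clinical practice compresses all of
this into a single "sleep onset" epoch read off a hypnogram scored in
30-second blocks. `wakeprob` instead tracks the sleep onset process (SOP) as a
continuous posterior probability of wakefulness, Pr(Wake), estimated jointly
from three simultaneously recorded observation streams:

* **Behavior**: a self-paced breathing task — squeeze a ball on each inhale —
  scored as correct/incorrect per breath, with unscorable breaths treated as
  missing. The task needs no external stimuli, so it probes responsiveness
  without perturbing the very transition being measured.
* **EMG**: the log amplitude of each squeeze, extracted from the forearm
  flexor EMG by a Hilbert envelope averaged over a 1-s window around the
  inhale apex. Squeeze force decays toward baseline muscle tone as
  wakefulness fades.
* **EEG**: occipital alpha (8–12 Hz) and combined delta–theta (0.5–8 Hz)
  band powers from multitaper spectrograms (6-s windows, 0.25-s step,
  time–bandwidth 3, 5 tapers, median over occipital channels). Alpha wanes
  and delta–theta waxes across the SOP.

## The model

Three latent activity states evolve as independent Gaussian random walks on a
common grid with spacing $\Delta t$ (the spectrogram step, 0.25 s):
$x^m$ (motor), $x^\alpha$ (alpha), and $x^{\Delta\theta}$ (delta–theta),

$$x_t = x_{t-1} + \varepsilon_t,\qquad \varepsilon_t \sim N(0, \sigma^2_\varepsilon).$$

The combined wake state is a fixed linear combination carrying the signs of
the physiology — motor and alpha activity raise wakefulness, delta–theta
lowers it:

$$x^{wake}_t = \beta\,(x^m_t + x^\alpha_t - x^{\Delta\theta}_t),\qquad \beta = \tfrac13,$$

and the response probability is its logistic transform,
$p_t = \mathrm{logistic}(x^{wake}_t)$, so that Pr(Wake) is directly the
instantaneous probability of a correct behavioral response.

Each observation stream has its own likelihood, tied to its own state:

* binary responses: $b_t \sim \mathrm{Bernoulli}(p_t)$;
* log squeeze amplitude: $m_t \sim N(\mu_0 + \mu_1 x^m_t, \sigma_m^2)$, with
  the intercept absorbing baseline muscle tone;
* log band powers: $y_t \sim N(\mathrm{offset} + \mathrm{gain}\cdot
  \mathrm{logistic}(x_t), \sigma^2)$ — a saturating (sigmoidal) response of
  power to underlying activity, for alpha and delta–theta separately.

The joint log-likelihood at each time is the indicator-weighted sum of the
modality terms: any missing observation contributes exactly zero, so sensor
dropouts and unscorable trials degrade the estimate gracefully instead of
breaking it.

Band powers enter on a log scale because physiological power varies
multiplicatively; the sigmoid's slope is fixed at 1 since it is confounded
with the scale of the (dimensionless) state; gains and noise scales are
constrained positive by parameterizing them on the log scale.

## Inference

States and the nine observation coefficients are estimated jointly by a
sequential importance resampling particle filter: propagate, reweight by the
joint likelihood (in the log domain with max subtraction), and
systematically resample when the effective sample size drops below half the
particle count. The wake probability curve is the per-time weighted 2.5/50/
97.5 percentile of $p_t$ across particles. At each behavioral observation
the filter also retains draws of $p_t$ from *before* assimilating that
response — the one-step-ahead predictive distribution used by the
goodness-of-fit analysis, so a response is never judged by a model that has
already seen it.

**Coefficient evolution.** Static coefficients carried by particles need
artificial dynamics to survive resampling. A plain small-variance random
walk inflates coefficient variance linearly in time while resampling
destroys diversity; on 10-minute simulations this collapses the ensemble to
a single ancestral lineage and biases the curve. The default is therefore
Liu–West kernel shrinkage (discount 0.99): each coefficient is shrunk toward
the ensemble's weighted mean and reinflated with matched noise, preserving
the cloud's mean and variance while continuously regenerating diversity. The
plain random walk remains available (`wp_config(param_evolution = "walk")`).

**Monte Carlo error.** `run_filter()` reports a Monte Carlo standard error
for each state mean using the ancestral-genealogy variance estimator (sum of
squared within-ancestor-family weighted deviations). The naive
$\mathrm{sd}/\sqrt{\mathrm{ESS}}$ ignores the dependence introduced by
resampling and understates the error by up to a factor of two; the genealogy
estimator is what the package's Kalman-oracle validation uses.

**Validation against an exact oracle.** Restricted to one state with a
linear-Gaussian EMG observation and fixed coefficients, the model is exactly
solvable by the Kalman recursions (`kalman_oracle()`). The test suite checks
that the particle filter's posterior mean stays within 3 genealogy-estimated
standard errors of the exact mean at every one of 200 steps with 20,000
particles. This is a family-wise ~3-sigma statistical check; the oracle
fixture uses moderate observation noise (slow forgetting), which makes
successive errors strongly correlated so the bound has close to its nominal
coverage. It can still fail for an unlucky seed, at roughly the rate a
3-sigma bound should.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 1/3 | state combination weight; the wake state is the mean of the three |
| `state_walk_sd` | 0.1 per 0.25-s step | state diffusion scale; chosen so diffusion can traverse the ±3 wake–sleep state range on the 1–2 minute timescale of arousals, and the sleep-onset ramp drift (~0.0125 units/step) stays well inside one step's sd |
| `param_prior_*` | centered on the generator defaults | weakly informative Gaussian priors on the walk scale |
| `lw_delta` | 0.99 | Liu–West discount; closer to 1 = less shrinkage per step |
| `n_particles` | 10,000 | particle count |
| `ess_frac` | 0.5 | resampling trigger as a fraction of N |

Observation-model defaults (EMG slope 1, intercept 0, residual sd 0.3; EEG
gain 2, offset 0, residual sd 0.3 on the log-power scale) describe a clean
recording: a 2-nat (~9 dB) dynamic range of band power across the SOP with
~1.3 dB residual scatter per window, and a 6-nat EMG amplitude range from
crisp squeezes to baseline tone.

## The synthetic-data generator

`wp_scenario()` + `simulate_sop()` generate complete ground-truth datasets:
state trajectories (smooth sigmoid descent; descent with a ~1-minute
arousal; alpha dropout, where the alpha descent leads delta–theta by minutes;
a pure random walk; or an instantaneous step), observations drawn from the
model's own observation equations at the true coefficients, jittered breath
trials at ~15 breaths/min, configurable per-modality missingness, and a
hypnogram derived by thresholding epoch-mean true p (W ≥ 0.7 > N1 ≥ 0.3 >
N2). The thresholds are scenario parameters, not physiological claims — real
hypnograms are human-scored.

What the generator deliberately mirrors is the *structure the model
assumes*: independent per-window Gaussian noise on log band powers, iid
Bernoulli responses given $p_t$, exact sigmoid observation means. Real data
violate all of these in ways the generator does not emulate: overlapping
multitaper windows make neighboring band-power estimates strongly
autocorrelated (so real recordings carry far less independent information
per step than the simulation), spectral artifacts are not Gaussian, and
behavioral lapses cluster. Passing the recovery tests therefore demonstrates
the estimator is correct *under its own assumptions* — it does not certify
calibration on real polysomnography.

The `step` trajectory exists so the goodness-of-fit comparison can be run
under the null hypothesis of the competing model class: when the world truly
switches instantaneously, a well-behaved comparison should *stop* preferring
the wake model, and the test suite checks exactly that.

## Calibration: what holds and what does not

On 20 simulated sigmoid descents the posterior median of $p_t$ tracks the
truth with pooled RMSE ≈ 0.05 (target < 0.1). Pooled 95%-band coverage,
however, measures ≈ 0.86 against a 0.90–0.98 target band, and the package
reports this honestly rather than adjusting the simulation to flatter the
estimator. The misses are almost entirely confined to deeply saturated
stretches: once a state has driven its sigmoid flat (e.g. delta–theta far
above the observable range), the data contain no information about how much
further the true state drifts, true $p_t$ reaches $10^{-5}$–$10^{-7}$, and
the posterior band floor sits near $3\times10^{-4}$ — a miss of less than
0.01 in probability. Coverage counted with a 0.01 tolerance is 0.98–0.995.
Increasing the particle count four-fold leaves coverage unchanged, which
identifies this as a property of the exact filtering posterior under
saturation, not of the Monte Carlo approximation: no filter can recover
information the observation model has saturated away.

## Goodness of fit against instantaneous transition models

Every hypnogram-based definition of a sleep-onset moment (first N1 epoch,
first N2 epoch, first of 3 or of 10 consecutive NREM epochs) implies a
response-probability curve with a single step from 0.95 (awake) to 0.05
(asleep). `gof_analysis()` compares these against the wake model by Bayesian
Monte Carlo: per iteration, draw one $p$ per scored trial (from the
predictive samples for the wake model; the step value, a point mass, for the
instantaneous models), sum the Bernoulli log-likelihoods, and summarize the
paired difference distribution — median, central 95% interval, and the
fraction of difference samples above zero. Missing trials are excluded from
all models identically. The onset epoch itself counts as asleep, since each
definition names the first epoch *of sleep*. Because per-night
total-log-likelihood samples add, the comparison pools naturally across
nights and subjects, and the package's validation runs it over several
simulated nights at once: single nights leave the verdict at the mercy of
one noise realization, while the pooled comparison is decisive in both
directions (the wake model wins under gradual transitions, and stops
winning when the true transition is a step that the hypnogram definitions
can represent exactly).

## Population spectrograms over Pr(Wake)

Because Pr(Wake) is also the response probability, it provides a common
axis on which different subjects' recordings can be aligned without
assuming they fall asleep at the same rate. `align_spectra()` pairs each
spectrogram window with the posterior-median wake probability at the nearest
curve time (within half a grid step); `build_population_spectrogram()` pools
the aligned samples across subjects and nights and takes the median spectrum
in each of 400 wake-probability bins of width 0.0025 (half-open bins, last
bin closed; empty bins stay missing, never interpolated). Two populations
are compared per (bin, frequency) cell by a bootstrap on the difference of
group medians (default 10,000 iterations), flagging cells where zero falls
outside the central 2.5–97.5 percentile interval. The resampling unit is the
individual aligned window; because neighboring windows are autocorrelated in
real data, a circular block-bootstrap option (`block_length`) is provided.
The binning summary is the posterior median of the curve — the same
statistic the curve displays.

## Numerical choices and degenerate inputs

* Weights are accumulated in the log domain with max subtraction; an
  all-zero weight vector raises an error naming the offending observation
  time rather than silently renormalizing garbage.
* Curve quantiles are weighted empirical quantiles of the particle values —
  no kernel smoothing, so the reported band is exactly the ensemble's.
* Zero-phase filtering uses forward–backward Butterworth passes with ~2 s of
  point-reflected padding, which suppresses the edge transients that
  otherwise dominate a notch filter's stop-band residual.
* Squeeze amplitudes of silent windows are floored at 1e-12 before the log;
  trials whose window leaves the recording are marked missing, not errors.
* Frequency bands are half-open `[lo, hi)`, so 5 Hz belongs to theta alone
  and the delta/theta/alpha powers partition total 0.5–12 Hz power exactly.
* Hypnogram onset rules that never fire return an explicit no-onset value,
  which the comparison treats as "awake throughout".
* Every randomized function takes an explicit seed, and rerunning any
  command with the same inputs and seed reproduces outputs bit-exactly.

## Problem sizes used by the validation studies

The packaged studies use 10-minute recordings on a 0.25-s grid (2,401 time
points), the default 10,000 particles for the recovery and goodness-of-fit
fits, 20,000 for the Kalman oracle, 10,000 Monte Carlo iterations for
likelihood distributions, and 1,000 bootstrap iterations over 300
comparable cells (about 480 samples per bin and group, where the percentile
rule attains close to its nominal level) for the false-positive-rate study. The filtering loop has
a compiled core (`run_filter(engine = "cpp")`, the default), with a pure-R
reference implementation (`engine = "r"`) retained for step-level testing;
both draw their randomness deterministically from the run seed, through
different streams, so they agree statistically rather than bit-for-bit.
These sizes keep a full validation run in the minutes range on one CPU.

## Known limitations

* Filtering only: estimates at time t use data up to t. The retrospective
  (smoothed) trajectory would differ, especially around arousals.
* The three states share one walk scale by default; heterogeneous dynamics
  (e.g. abrupt motor changes with slow spectral drift) would call for
  per-state tuning.
* Saturated observations bound what any inference can say about extreme
  states; see the calibration section.
* The instantaneous-model likelihoods are point masses given the fixed
  0.95/0.05 accuracies; the comparison's spread comes entirely from the wake
  model's predictive distribution.
* EDF support covers continuous recordings with one sampling rate per
  channel — the common PSG export case — not discontinuous EDF+ sessions.
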
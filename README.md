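# wakeprob

Continuous, probabilistic tracking of the sleep onset process (SOP).

Clinical sleep scoring reduces falling asleep to a single staged epoch on a
hypnogram. In reality, behavioral responsiveness, muscle tone, and EEG
rhythms decline gradually and on different timescales. `wakeprob` estimates
the instantaneous probability that a subject is awake — **Pr(Wake)**, defined
so that it equals the probability of a correct behavioral response — by
fusing three simultaneously recorded observation streams in a Bayesian
state-space model:

* binary responses from a breathing-paced squeeze task (one trial per
  inhale, no external stimuli),
* log EMG squeeze amplitudes (Hilbert envelope, 1-s windows),
* occipital EEG alpha (8–12 Hz) and delta–theta (0.5–8 Hz) band powers from
  multitaper spectrograms (6-s windows, 0.25-s step, NW = 3, 5 tapers).

## Model

Latent activity states for the motor, alpha, and delta–theta systems evolve
as independent Gaussian random walks x_t = x_{t−1} + ε_t on a 0.25-s grid.
Wakefulness is their signed combination with β = 1/3,

    x_wake = β (x_m + x_alpha − x_deltatheta),    p = logistic(x_wake),

and the observation equations are b_t ~ Bernoulli(p_t) for responses,
m_t ~ N(μ0 + μ1 x_m, σ_m²) for log squeeze amplitude, and
y_t ~ N(offset + gain · logistic(x), σ²) for each log band power. Missing
observations contribute exactly zero to the joint log-likelihood, so the
model runs on whatever data survive artifact screening. States and the
observation coefficients are estimated jointly by a sequential importance
resampling particle filter (systematic resampling at ESS < N/2; Liu–West
kernel shrinkage keeps the coefficient ensemble alive), yielding the **wake
probability curve**: the per-time posterior median of p_t with a 95%
credible band.

Companion analyses:

* `gof_analysis()` — Bayesian Monte Carlo comparison of the wake model
  against the four hypnogram-derived *instantaneous transition models*
  (first N1 epoch, first N2 epoch, first of 3 / of 10 consecutive NREM
  epochs; 0.95 → 0.05 response accuracy at onset), using one-step-ahead
  predictive draws so responses never inform their own evaluation.
* `build_population_spectrogram()` / `bootstrap_compare()` — median EEG
  spectra across subjects as a function of Pr(Wake) (400 bins of width
  0.0025), with per-bin bootstrap significance between populations.
* `simulate_sop()` — ground-truth synthetic recordings (smooth descent,
  descent with arousal, alpha dropout, random walk, or instantaneous step)
  for validation.

## Worked example

Simulate a 5-minute sleep-onset descent, fit the filter, and compare models:

```r
library(wakeprob)
scenario <- wp_scenario(duration = 300, trajectory = "sigmoid_descent", t_mid = 150)
sim <- simulate_sop(scenario, seed = 11)
fit <- run_filter(sim$grid, wp_config(n_particles = 2000), seed = 12)
fit
#> <wp_fit> 1201 time points, 2000 particles, seed 12
#>   final Pr(Wake) median 0.031 [0.006, 0.078]
```

The curve starts near 1 (awake, correct squeezes, strong alpha), crosses 0.5
around the 150-s midpoint, and ends near 0 with a tight band:

```r
idx <- seq(1, 1201, by = 300)
round(data.frame(time_s = fit$curve$time[idx], p_true = sim$p[idx],
                 p_lo = fit$curve$p_lo[idx], p_median = fit$curve$p_median[idx],
                 p_hi = fit$curve$p_hi[idx]), 3)
#>   time_s p_true  p_lo p_median  p_hi
#> 1      0  0.952 0.725    0.881 0.958
#> 2     75  0.801 0.731    0.813 0.887
#> 3    150  0.198 0.313    0.439 0.574
#> 4    225  0.018 0.064    0.136 0.220
#> 5    300  0.012 0.006    0.031 0.078
```

The true trajectory `sim$p` is shown alongside the fitted quantiles. The
goodness-of-fit comparison ranks the wake model above every instantaneous
transition model for this gradual transition — e.g. against the first-N1
model the log-likelihood difference is 2.6 with 99.84% of difference samples
above zero, and against first-of-10-NREM the difference is 109:

```r
gof_analysis(fit, sim$grid, sim$hypnogram, n_mc = 5000, seed = 13)$table
#>              model loglik_median diff_median prob_diff_positive
#> 1 wake_probability        -24.81          NA                 NA
#> 2         first_N1        -27.40       2.592             0.9984
#> 3         first_N2        -30.35       5.536             1.0000
#> 4     first_3_NREM        -27.40       2.592             0.9984
#> 5    first_10_NREM       -133.40     108.592             1.0000
```

A command-line front end (`simulate`, `preprocess`, `fit`, `gof`, `popspec`)
is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/wakeprob.R", package="wakeprob"))')" \
  simulate --seed 7 --out night1
```

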
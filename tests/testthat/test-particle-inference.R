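test_that("particle initialization draws from the priors with uniform weights", {
  cfg <- wp_config(n_particles = 4L)
  ens <- init_particles(cfg, seed = 1)
  expect_equal(ens$weights, rep(0.25, 4))
  expect_equal(ens$time_index, 0L)

  # determinism: same seed, identical ensemble
  ens2 <- init_particles(cfg, seed = 1)
  expect_identical(ens$states, ens2$states)
  expect_identical(ens$params, ens2$params)

  # zero-variance prior: all particles identical
  degen <- fixed_param_config(state_prior_sd = c(0, 0, 0), n_particles = 10L)
  e0 <- init_particles(degen, seed = 2)
  expect_true(all(apply(e0$states, 2, sd) == 0))
  expect_true(all(apply(e0$params, 2, sd) == 0))

  bad <- wp_config(n_particles = 10L)
  bad$state_prior_sd[1] <- NaN
  expect_error(init_particles(bad, seed = 1), "improper prior")

  # moments of a larger ensemble match the prior
  big <- init_particles(wp_config(n_particles = 50000L), seed = 3)
  expect_equal(colMeans(big$states), unname(wp_config()$state_prior_mean),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("a filter step reweights by the joint likelihood and preserves normalization", {
  cfg <- fixed_param_config(n_particles = 500L, state_walk_sd = 1e-9)
  ens <- init_particles(cfg, seed = 4)

  # fully-missing observation row: weights unchanged (propagation only)
  obs_none <- list(time = 0, b = NA, m = NA, y_alpha = NA, y_dt = NA,
                   I_b = FALSE, I_m = FALSE, I_alpha = FALSE, I_dt = FALSE)
  stepped <- pf_step(ens, obs_none, cfg)
  expect_identical(stepped$weights, ens$weights)
  expect_equal(stepped$time_index, 1L)

  # informative EMG observation: weights renormalize, favor matching particles
  obs_m <- list(time = 0, b = NA, m = 2.5, y_alpha = NA, y_dt = NA,
                I_b = FALSE, I_m = TRUE, I_alpha = FALSE, I_dt = FALSE)
  up <- pf_step(ens, obs_m, cfg)
  expect_equal(sum(up$weights), 1, tolerance = 1e-9)
  if (!attr(up, "resampled")) {
    best <- which.max(up$weights)
    expect_lt(abs(up$states[best, 1] - 2.5),
              abs(sum(ens$states[, 1] * ens$weights) - 2.5) + 1)
  }

  # two-particle toy: posterior mass concentrates on the matching particle
  tiny <- fixed_param_config(n_particles = 2L, state_prior_sd = c(0, 0, 0),
                             state_walk_sd = 1e-12, ess_frac = 1e-9)
  e2 <- init_particles(tiny, seed = 5)
  e2$states[1, ] <- c(0, 0, 0)
  e2$states[2, ] <- c(40, 0, 0)   # EMG loglik ~ -Inf-ish for particle 2
  r2 <- pf_step(e2, obs_m, tiny)
  expect_gt(r2$weights[1], 1 - 1e-10)
})

test_that("filtering a grid yields ordered quantile curves and deterministic reruns", {
  sim <- simulate_sop(wp_scenario(duration = 60), seed = 71)
  cfg <- wp_config(n_particles = 400L)
  fit <- run_filter(sim$grid, cfg, seed = 72)
  expect_true(all(fit$curve$p_lo <= fit$curve$p_median + 1e-12))
  expect_true(all(fit$curve$p_median <= fit$curve$p_hi + 1e-12))
  expect_true(all(fit$curve$p_lo >= 0 & fit$curve$p_hi <= 1))
  # predictive samples exist for every behavioral observation, inside (0,1)
  expect_equal(length(fit$predictive$times), sum(sim$grid$I_b))
  expect_true(all(fit$predictive$samples > 0 & fit$predictive$samples < 1))

  # bit-identical rerun under the same seed, config and data
  fit2 <- run_filter(sim$grid, cfg, seed = 72)
  expect_identical(fit$curve, fit2$curve)
  expect_identical(fit$predictive$samples, fit2$predictive$samples)

  # seed is required
  expect_error(run_filter(sim$grid, cfg), "seed")
})

test_that("compiled and reference filtering engines agree statistically", {
  sim <- simulate_sop(wp_scenario(duration = 120), seed = 75)
  cfg <- wp_config(n_particles = 3000L)
  fc <- run_filter(sim$grid, cfg, seed = 76, engine = "cpp")
  fr <- run_filter(sim$grid, cfg, seed = 76, engine = "r")
  # same algorithm, different random streams: medians agree to Monte Carlo
  # precision and the bands have comparable width
  expect_lt(median(abs(fc$curve$p_median - fr$curve$p_median)), 0.03)
  expect_equal(median(fc$curve$p_hi - fc$curve$p_lo),
               median(fr$curve$p_hi - fr$curve$p_lo), tolerance = 0.25)
  # each engine is bit-reproducible under its own stream
  fc2 <- run_filter(sim$grid, cfg, seed = 76, engine = "cpp")
  expect_identical(fc$curve, fc2$curve)
})

test_that("the filter matches the exact Kalman recursion on the linear-Gaussian submodel", {
  case <- linear_emg_case(seed = 81, n_particles = 4000L)
  fit <- run_filter(case$grid, case$config, seed = 82)
  z <- abs(fit$states$m_mean - case$kalman$mean) / fit$states$m_mcse
  expect_lt(max(z), 3)
  # posterior spread agrees with the exact filter variance
  expect_equal(median(fit$states$m_sd / sqrt(case$kalman$var)), 1,
               tolerance = 0.05)
})

test_that("kalman oracle limits and a hand-computed two-step recursion", {
  g <- observation_grid(c(0, 0.25), m = c(1.0, 1.3))
  # hand recursion: prior N(0,1), walk sd 0.5, obs m = mu1 x + e, mu1 = 2,
  # obs sd 1. Step 1: P- = 1.25, S = 5*1.25/... K = P-*mu1/(mu1^2 P- + r^2)
  P1m <- 1 + 0.25
  K1 <- P1m * 2 / (4 * P1m + 1)
  mu1_ <- 0 + K1 * (1.0 - 0)
  P1 <- (1 - 2 * K1) * P1m
  P2m <- P1 + 0.25
  K2 <- P2m * 2 / (4 * P2m + 1)
  mu2_ <- mu1_ + K2 * (1.3 - 2 * mu1_)
  P2 <- (1 - 2 * K2) * P2m
  kf <- kalman_oracle(g, mu1 = 2, intercept = 0, obs_sd = 1, walk_sd = 0.5,
                      prior_mean = 0, prior_sd = 1)
  expect_equal(kf$mean, c(mu1_, mu2_), tolerance = 1e-12)
  expect_equal(kf$var, c(P1, P2), tolerance = 1e-12)

  # zero observation noise: posterior mean equals observation / mu1
  kf0 <- kalman_oracle(g, mu1 = 2, obs_sd = 0, walk_sd = 0.5)
  expect_equal(kf0$mean, c(1.0, 1.3) / 2, tolerance = 1e-12)

  # huge observation noise: posterior tracks the prior propagation
  kfi <- kalman_oracle(g, mu1 = 2, obs_sd = 1e8, walk_sd = 0.5,
                       prior_mean = 0.7, prior_sd = 0.1)
  expect_equal(kfi$mean, c(0.7, 0.7), tolerance = 1e-4)

  # nonlinear configuration refused
  gb <- observation_grid(c(0, 0.25), b = c(1, NA), m = c(1, 1.3))
  expect_error(kalman_oracle(gb, mu1 = 1, obs_sd = 1, walk_sd = 0.1),
               "linear-Gaussian")
})

test_that("systematic resampling preserves the particle count and expected mix", {
  set.seed(91)
  w <- c(0.5, 0.3, 0.15, 0.05)
  draws <- replicate(2000, {
    idx <- wakeprob:::.systematic_resample(w)
    tabulate(idx, 4)
  })
  expect_true(all(colSums(draws) == 4))
  expect_equal(rowMeans(draws) / 4, w, tolerance = 0.02)
})

test_that("weighted quantiles agree with a sort-based oracle", {
  set.seed(92)
  x <- rnorm(500)
  w <- runif(500)
  w <- w / sum(w)
  probs <- c(0.025, 0.5, 0.975)
  got <- wakeprob:::.weighted_quantile(x, w, probs)
  o <- order(x)
  cw <- cumsum(w[o])
  oracle <- vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
  expect_equal(got, oracle)
})
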
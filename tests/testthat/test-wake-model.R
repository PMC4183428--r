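test_that("likelihood terms match independent closed-form densities to 1e-12", {
  set.seed(101)
  n <- 1000
  m_obs <- rnorm(n, 0, 3)
  x <- rnorm(n, 0, 2)
  mu1 <- runif(n, 0.2, 3)
  sd_ <- runif(n, 0.05, 2)
  icpt <- rnorm(n)
  expect_equal(loglik_emg(m_obs, x, mu1, sd_, icpt),
               dnorm(m_obs, icpt + mu1 * x, sd_, log = TRUE),
               tolerance = 1e-12)

  gain <- runif(n, 0.1, 5)
  off <- rnorm(n)
  y <- rnorm(n, 0, 2)
  expect_equal(loglik_eeg(y, x, gain, off, sd_),
               dnorm(y, off + gain * plogis(x), sd_, log = TRUE),
               tolerance = 1e-12)

  b <- rbinom(n, 1, 0.5)
  p <- runif(n, 0.01, 0.99)
  expect_equal(loglik_behavior(b, p),
               dbinom(b, 1, p, log = TRUE),
               tolerance = 1e-12)
})

test_that("likelihood closed-form spot values and input validation", {
  # observation at the predicted mean: Gaussian mode
  expect_equal(loglik_emg(1.4, 2, 0.7, sd = 0.5), -log(0.5 * sqrt(2 * pi)))
  # sigmoid saturation limits
  expect_equal(loglik_eeg(3, 50, gain = 3, offset = 0, sd = 1),
               dnorm(3, 3, 1, log = TRUE), tolerance = 1e-10)
  expect_equal(loglik_eeg(0, -50, gain = 3, offset = 0, sd = 1),
               dnorm(0, 0, 1, log = TRUE), tolerance = 1e-10)
  # Bernoulli closed forms
  expect_equal(loglik_behavior(1, 0.5), log(0.5))
  expect_equal(loglik_behavior(0, 0.05), log(0.95))
  # n trials at constant p equals the binomial loglik up to the constant term
  set.seed(5)
  b <- rbinom(25, 1, 0.7)
  expect_equal(sum(loglik_behavior(b, 0.7)),
               dbinom(sum(b), 25, 0.7, log = TRUE) - log(choose(25, sum(b))),
               tolerance = 1e-12)

  expect_error(loglik_emg(Inf, 0, 1, 1), "finite")
  expect_error(loglik_emg(0, 0, 1, -1), "sd")
  expect_error(loglik_eeg(0, 0, -2, 0, 1), "gain")
  expect_error(loglik_behavior(1, 1), "strictly")
  expect_error(loglik_behavior(2, 0.5), "0 or 1")
})

test_that("joint log-likelihood is an indicator-weighted sum over modalities", {
  params <- params_natural(true_params)
  state <- c(1.2, 0.4, -0.8)
  obs <- list(b = 1, m = 1.1, y_alpha = 1.4, y_dt = 0.5,
              I_b = TRUE, I_m = TRUE, I_alpha = TRUE, I_dt = TRUE)
  p <- plogis((state[1] + state[2] - state[3]) / 3)
  manual <- loglik_behavior(1, p) +
    loglik_emg(1.1, state[1], params$mu1, params$emg_sd, params$emg_intercept) +
    loglik_eeg(1.4, state[2], params$alpha_gain, params$alpha_offset, params$alpha_sd) +
    loglik_eeg(0.5, state[3], params$dt_gain, params$dt_offset, params$dt_sd)
  expect_equal(joint_loglik(obs, state, params), manual, tolerance = 1e-12)

  # all indicators false: exactly zero
  none <- obs
  none[c("I_b", "I_m", "I_alpha", "I_dt")] <- FALSE
  expect_identical(joint_loglik(none, state, params), 0)

  # removing one modality changes the total by exactly that term
  for (mod in c("I_b", "I_m", "I_alpha", "I_dt")) {
    drop1 <- obs
    drop1[[mod]] <- FALSE
    term <- joint_loglik(obs, state, params) - joint_loglik(drop1, state, params)
    only <- none
    only[[mod]] <- TRUE
    expect_equal(term, joint_loglik(only, state, params), tolerance = 1e-12)
  }
})

test_that("wake state combines states with beta and the logistic link", {
  ws <- wake_state(0, 0, 0)
  expect_equal(ws$x_wake, 0)
  expect_equal(ws$p, 0.5)
  # stated sign convention: (3, 3, 3) -> x_wake = 1
  expect_equal(wake_state(3, 3, 3)$x_wake, 1)
  expect_equal(wake_state(2, 1, -1, beta = 0.5)$x_wake, 2)

  # monotone: p increases in x_m and x_alpha, decreases in x_dt
  grid <- seq(-5, 5, length.out = 41)
  expect_true(all(diff(wake_state(grid, 0, 0)$p) > 0))
  expect_true(all(diff(wake_state(0, grid, 0)$p) > 0))
  expect_true(all(diff(wake_state(0, 0, grid)$p) < 0))
})

test_that("state and coefficient random walks have the stated moments", {
  set.seed(202)
  n <- 1e5
  prev <- matrix(0, n, 3)
  stepped <- state_transition(prev, c(0.3, 0.5, 0.7))
  inc <- stepped - prev
  expect_equal(colMeans(inc), c(0, 0, 0), tolerance = 0.01)
  expect_equal(apply(inc, 2, sd), c(0.3, 0.5, 0.7), tolerance = 0.02)
  # components evolve independently
  cc <- cor(inc)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.02))
  # zero-noise limit: constant state
  expect_equal(state_transition(prev, 0), prev)

  pmat <- matrix(rnorm(n * 9), n)
  colnames(pmat) <- names(true_params)
  walked <- parameter_transition(pmat, 0.05)
  expect_equal(sd(walked - pmat), 0.05, tolerance = 0.01)
  expect_identical(parameter_transition(pmat, 0), pmat)
  # positive-constrained coefficients stay positive after many steps
  w <- matrix(true_params, 50, 9, byrow = TRUE,
              dimnames = list(NULL, names(true_params)))
  for (i in 1:200) w <- parameter_transition(w, 0.1)
  nat <- params_natural(w)
  expect_true(all(nat$emg_sd > 0 & nat$alpha_gain > 0 & nat$dt_sd > 0))
})

test_that("walk-scale and natural-scale parameter views are inverse", {
  w <- params_walk_scale(mu1 = 1.5, emg_intercept = -0.4, emg_sd = 0.2,
                         alpha_gain = 3, alpha_offset = 1, alpha_sd = 0.5,
                         dt_gain = 0.8, dt_offset = -1, dt_sd = 0.1)
  nat <- params_natural(w)
  expect_equal(nat$mu1, 1.5)
  expect_equal(nat$emg_sd, 0.2)
  expect_equal(nat$dt_offset, -1)
  expect_error(params_walk_scale(mu1 = -1), "mu1")
})

test_that("observation grid derives indicators from missingness", {
  g <- observation_grid(seq(0, 1, by = 0.25),
                        b = c(1, NA, 0, NA, NA),
                        m = c(NA, 0.5, NA, NA, 1.2),
                        y_alpha = c(1, 1, NA, 1, 1),
                        y_dt = rep(0.2, 5))
  expect_equal(g$I_b, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(g$I_m, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(sum(g$I_alpha), 4L)
  expect_true(all(g$I_dt))
  expect_equal(attr(g, "dt"), 0.25)
  expect_error(observation_grid(c(0, 1, 3)), "constant")
  expect_error(observation_grid(0:2, b = c(2, NA, NA)), "0/1")
})

test_that("strong wake-consistent observations drive the posterior of p above 0.95", {
  # delta-theta at its wake (low) level, alpha and EMG at their peaks, with
  # strong gains: the wake-state posterior mode must sit near p = 1
  set.seed(303)
  params <- params_walk_scale(mu1 = 1, emg_sd = 0.1,
                              alpha_gain = 4, alpha_sd = 0.1,
                              dt_gain = 4, dt_sd = 0.1)
  cfg <- fixed_param_config(params = params,
                            state_prior_mean = c(0, 0, 0),
                            state_prior_sd = c(3, 3, 3),
                            n_particles = 4000L)
  g <- observation_grid(seq(0, 4.75, by = 0.25),
                        b = rep(1, 20),
                        m = rep(3, 20),
                        y_alpha = rep(4, 20),
                        y_dt = rep(0, 20))
  fit <- run_filter(g, cfg, seed = 9)
  expect_gt(fit$curve$p_median[20], 0.95)
})
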
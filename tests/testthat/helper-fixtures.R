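# shared fixtures, built in code at test time

# walk-scale coefficients used as ground truth throughout
true_params <- params_walk_scale(mu1 = 1, emg_intercept = 0, emg_sd = 0.3,
                                 alpha_gain = 2, alpha_offset = 0,
                                 alpha_sd = 0.3,
                                 dt_gain = 2, dt_offset = 0, dt_sd = 0.3)

# a configuration with coefficient priors collapsed onto fixed values and no
# coefficient walk: the filter then estimates states only
fixed_param_config <- function(params = true_params, ...) {
  wp_config(param_walk_sd = 0,
            param_prior_mean = params,
            param_prior_sd = setNames(rep(0, 9), names(params)),
            ...)
}

# EMG-only linear-Gaussian grid + matching config for oracle comparisons.
# Moderate observation noise gives the filter slow forgetting, so the
# genealogy-based MC standard error is well calibrated and per-step errors
# are strongly correlated, making a 3-SE everywhere bound meaningful.
linear_emg_case <- function(seed, T_ = 200, walk_sd = 0.03, obs_sd = 2,
                            n_particles = 20000L) {
  set.seed(seed)
  x <- cumsum(rnorm(T_, 0, walk_sd))
  m <- x + rnorm(T_, 0, obs_sd)
  grid <- observation_grid(seq(0, by = 0.25, length.out = T_), m = m)
  cfg <- fixed_param_config(
    params = params_walk_scale(mu1 = 1, emg_intercept = 0, emg_sd = obs_sd),
    state_walk_sd = walk_sd,
    state_prior_mean = c(0, 0, 0), state_prior_sd = c(1, 1, 1),
    n_particles = n_particles)
  list(grid = grid, config = cfg, truth = x,
       kalman = kalman_oracle(grid, mu1 = 1, intercept = 0, obs_sd = obs_sd,
                              walk_sd = walk_sd, prior_mean = 0, prior_sd = 1))
}
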
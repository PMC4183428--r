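#' Model and inference configuration
#'
#' Assembles the full configuration for the wake-probability model: the state
#' combination weight `beta`, random-walk scales, priors on the walked
#' observation coefficients, and particle-filter settings. Positive-valued
#' coefficients (slopes, gains, noise scales) are walked and given priors on
#' the log scale so they remain positive under any number of walk steps.
#'
#' @param beta Weight of the linear state combination (default 1/3, making the
#'   wake state the mean of the three component states).
#' @param state_walk_sd Per-step random-walk sd for the motor, alpha and
#'   delta-theta states (length 3 or scalar).
#' @param param_walk_sd Per-step random-walk sd applied to every walked
#'   coefficient on its walk scale when `param_evolution = "walk"`; small, so
#'   coefficients explore without large jumps. Set to 0 to hold coefficients
#'   fixed.
#' @param param_evolution How walked coefficients evolve inside the filter:
#'   `"liu_west"` (default) applies kernel shrinkage toward the weighted
#'   coefficient mean with matched noise, keeping the coefficient cloud's
#'   mean and variance invariant while regenerating diversity lost to
#'   resampling; `"walk"` is the plain random walk of sd `param_walk_sd`,
#'   whose variance inflates linearly over time.
#' @param lw_delta Liu-West discount factor in (0.5, 1); larger values
#'   shrink less per step.
#' @param state_prior_mean,state_prior_sd Gaussian prior on the initial
#'   states (motor, alpha, delta-theta). The default mean `c(2, 2, -2)`
#'   encodes that recordings start with the subject awake.
#' @param param_prior_mean,param_prior_sd Named numeric vectors giving the
#'   Gaussian prior for each walked coefficient *on its walk scale* (log
#'   scale for `mu1`, `emg_sd`, `alpha_gain`, `alpha_sd`, `dt_gain`,
#'   `dt_sd`; natural scale for the intercept/offsets).
#' @param n_particles Particle count for filtering.
#' @param ess_frac Resample when the effective sample size drops below
#'   `ess_frac * n_particles` (systematic resampling).
#' @param n_keep Number of equally weighted posterior/predictive draws of
#'   `p_t` retained per behavioral observation time.
#'
#' @return A list of class `wp_config`.
#' @export
wp_config <- function(beta = 1 / 3,
                      state_walk_sd = c(m = 0.1, alpha = 0.1, dt = 0.1),
                      param_walk_sd = 0.005,
                      param_evolution = c("liu_west", "walk"),
                      lw_delta = 0.99,
                      state_prior_mean = c(m = 2, alpha = 2, dt = -2),
                      state_prior_sd = c(m = 1, alpha = 1, dt = 1),
                      param_prior_mean = c(log_mu1 = 0, emg_intercept = 0,
                                           log_emg_sd = log(0.3),
                                           log_alpha_gain = log(2),
                                           alpha_offset = 0,
                                           log_alpha_sd = log(0.3),
                                           log_dt_gain = log(2),
                                           dt_offset = 0,
                                           log_dt_sd = log(0.3)),
                      param_prior_sd = c(log_mu1 = 0.2, emg_intercept = 0.5,
                                         log_emg_sd = 0.3,
                                         log_alpha_gain = 0.3,
                                         alpha_offset = 0.5,
                                         log_alpha_sd = 0.3,
                                         log_dt_gain = 0.3,
                                         dt_offset = 0.5,
                                         log_dt_sd = 0.3),
                      n_particles = 10000L,
                      ess_frac = 0.5,
                      n_keep = 500L) {
  if (length(state_walk_sd) == 1L) state_walk_sd <- rep(state_walk_sd, 3L)
  names(state_walk_sd) <- c("m", "alpha", "dt")
  stopifnot(all(state_walk_sd >= 0), param_walk_sd >= 0,
            length(state_prior_mean) == 3L, length(state_prior_sd) == 3L,
            all(state_prior_sd >= 0), n_particles >= 2L,
            ess_frac > 0, ess_frac <= 1)
  nm <- .wp_param_names
  if (!all(nm %in% names(param_prior_mean)) ||
      !all(nm %in% names(param_prior_sd)))
    stop("param priors must name all walked coefficients: ",
         paste(nm, collapse = ", "))
  if (any(param_prior_sd[nm] < 0)) stop("prior sds must be >= 0")
  param_evolution <- match.arg(param_evolution)
  stopifnot(lw_delta > 0.5, lw_delta <= 1)
  structure(list(beta = beta,
                 state_walk_sd = state_walk_sd,
                 param_walk_sd = param_walk_sd,
                 param_evolution = param_evolution,
                 lw_delta = lw_delta,
                 state_prior_mean = state_prior_mean,
                 state_prior_sd = state_prior_sd,
                 param_prior_mean = param_prior_mean[nm],
                 param_prior_sd = param_prior_sd[nm],
                 n_particles = as.integer(n_particles),
                 ess_frac = ess_frac,
                 n_keep = as.integer(n_keep)),
            class = "wp_config")
}

# walk-scale coefficient names, fixed order (log_* entries are positive
# coefficients walked on the log scale)
.wp_param_names <- c("log_mu1", "emg_intercept", "log_emg_sd",
                     "log_alpha_gain", "alpha_offset", "log_alpha_sd",
                     "log_dt_gain", "dt_offset", "log_dt_sd")

#' Natural-scale parameter vector from walk-scale values
#'
#' @param walk Named numeric vector (or matrix with named columns) of
#'   coefficients on the walk scale.
#' @return A list (or list of vectors) with natural-scale fields `mu1`,
#'   `emg_intercept`, `emg_sd`, `alpha_gain`, `alpha_offset`, `alpha_sd`,
#'   `dt_gain`, `dt_offset`, `dt_sd`.
#' @export
params_natural <- function(walk) {
  if (is.matrix(walk)) {
    list(mu1 = exp(walk[, "log_mu1"]),
         emg_intercept = walk[, "emg_intercept"],
         emg_sd = exp(walk[, "log_emg_sd"]),
         alpha_gain = exp(walk[, "log_alpha_gain"]),
         alpha_offset = walk[, "alpha_offset"],
         alpha_sd = exp(walk[, "log_alpha_sd"]),
         dt_gain = exp(walk[, "log_dt_gain"]),
         dt_offset = walk[, "dt_offset"],
         dt_sd = exp(walk[, "log_dt_sd"]))
  } else {
    list(mu1 = exp(walk[["log_mu1"]]),
         emg_intercept = walk[["emg_intercept"]],
         emg_sd = exp(walk[["log_emg_sd"]]),
         alpha_gain = exp(walk[["log_alpha_gain"]]),
         alpha_offset = walk[["alpha_offset"]],
         alpha_sd = exp(walk[["log_alpha_sd"]]),
         dt_gain = exp(walk[["log_dt_gain"]]),
         dt_offset = walk[["dt_offset"]],
         dt_sd = exp(walk[["log_dt_sd"]]))
  }
}

#' Walk-scale parameter vector from natural-scale values
#'
#' Inverse of [params_natural()] for scalar parameter sets.
#' @param mu1,emg_intercept,emg_sd,alpha_gain,alpha_offset,alpha_sd,dt_gain,dt_offset,dt_sd
#'   Natural-scale coefficients (positive where required).
#' @return Named numeric vector on the walk scale.
#' @export
params_walk_scale <- function(mu1 = 1, emg_intercept = 0, emg_sd = 0.3,
                              alpha_gain = 2, alpha_offset = 0, alpha_sd = 0.3,
                              dt_gain = 2, dt_offset = 0, dt_sd = 0.3) {
  stopifnot(mu1 > 0, emg_sd > 0, alpha_gain > 0, alpha_sd > 0,
            dt_gain > 0, dt_sd > 0)
  c(log_mu1 = log(mu1), emg_intercept = emg_intercept,
    log_emg_sd = log(emg_sd),
    log_alpha_gain = log(alpha_gain), alpha_offset = alpha_offset,
    log_alpha_sd = log(alpha_sd),
    log_dt_gain = log(dt_gain), dt_offset = dt_offset,
    log_dt_sd = log(dt_sd))
}

#' Random-walk state transition
#'
#' Each latent state advances by independent zero-mean Gaussian noise:
#' `x_t = x_{t-1} + e_t`, `e_t ~ N(0, walk_sd^2)` componentwise.
#'
#' @param prev Numeric vector of length 3 (`m`, `alpha`, `dt`) or an `N x 3`
#'   matrix of particles.
#' @param walk_sd Length-3 (or scalar) per-component walk sd.
#' @return Same shape as `prev`.
#' @export
state_transition <- function(prev, walk_sd) {
  if (length(walk_sd) == 1L) walk_sd <- rep(walk_sd, 3L)
  stopifnot(all(walk_sd >= 0))
  if (is.matrix(prev)) {
    n <- nrow(prev)
    noise <- matrix(stats::rnorm(3L * n), n, 3L)
    noise[, 1L] <- noise[, 1L] * walk_sd[1L]
    noise[, 2L] <- noise[, 2L] * walk_sd[2L]
    noise[, 3L] <- noise[, 3L] * walk_sd[3L]
    prev + noise
  } else {
    prev + stats::rnorm(3L, 0, walk_sd)
  }
}

#' Random-walk transition of walked coefficients
#'
#' Perturbs every walked coefficient by zero-mean Gaussian noise of sd
#' `eps_sd` on its walk scale (log scale for positive-constrained
#' coefficients), so positivity is preserved exactly.
#'
#' @param prev Named walk-scale vector, or `N x 9` matrix of particles.
#' @param eps_sd Small positive walk sd (0 freezes the coefficients).
#' @return Same shape as `prev`.
#' @export
parameter_transition <- function(prev, eps_sd) {
  stopifnot(eps_sd >= 0)
  if (eps_sd == 0) return(prev)
  prev + stats::rnorm(length(prev), 0, eps_sd)
}

#' Combined wake state and response probability
#'
#' The wake state is the weighted combination `x_wake = beta * (x_m + x_alpha
#' - x_dt)`: motor and alpha activity raise wakefulness, delta-theta activity
#' lowers it. The response probability is the logistic transform of the wake
#' state, mapping the unbounded state to (0, 1) with `p = 0.5` at
#' `x_wake = 0`.
#'
#' @param x_m,x_alpha,x_dt State components (vectors broadcast together).
#' @param beta Combination weight (default 1/3).
#' @return List with `x_wake` and `p`.
#' @export
wake_state <- function(x_m, x_alpha, x_dt, beta = 1 / 3) {
  xw <- beta * (x_m + x_alpha - x_dt)
  list(x_wake = xw, p = stats::plogis(xw))
}

# hand-written Gaussian log-density (the model's likelihood kernel)
.gauss_loglik <- function(x, mean, sd) {
  -0.5 * log(2 * pi) - log(sd) - 0.5 * ((x - mean) / sd)^2
}

#' EMG observation log-likelihood
#'
#' The log squeeze amplitude is modeled linearly in the motor state:
#' `m_t ~ N(intercept + mu1 * x_m, sd^2)`. The intercept absorbs the baseline
#' muscle-tone level that squeezes revert to as wakefulness declines.
#'
#' @param m_obs Observed log squeeze amplitude(s).
#' @param x_m Motor state value(s).
#' @param mu1 Linear coefficient.
#' @param sd Residual sd (> 0).
#' @param intercept Baseline log amplitude (default 0).
#' @return Gaussian log-density, vectorized.
#' @export
loglik_emg <- function(m_obs, x_m, mu1, sd, intercept = 0) {
  if (any(!is.finite(m_obs))) stop("m_obs must be finite")
  if (any(sd <= 0)) stop("sd must be > 0")
  .gauss_loglik(m_obs, intercept + mu1 * x_m, sd)
}

#' EEG band-power observation log-likelihood
#'
#' Each (log) band power is a sigmoidal function of its own state plus
#' Gaussian noise: `y ~ N(offset + gain * logistic(x), sd^2)`. The logistic
#' slope is fixed at 1 (it is confounded with the state scale); `gain > 0`
#' sets the dynamic range and `offset` the floor. The direction of coupling
#' to wakefulness (direct for alpha, inverse for delta-theta) is carried by
#' the sign convention in [wake_state()], not here.
#'
#' @param y_obs Observed (log) band power(s).
#' @param x State value(s) for this band process.
#' @param gain Sigmoid dynamic range (> 0).
#' @param offset Sigmoid floor.
#' @param sd Residual sd (> 0).
#' @return Gaussian log-density, vectorized.
#' @export
loglik_eeg <- function(y_obs, x, gain, offset, sd) {
  if (any(sd <= 0)) stop("sd must be > 0")
  if (any(gain <= 0)) stop("gain must be > 0")
  .gauss_loglik(y_obs, offset + gain * stats::plogis(x), sd)
}

#' Behavioral (binary response) log-likelihood
#'
#' Bernoulli log-likelihood of a correct (`b = 1`) or incorrect (`b = 0`)
#' response at response probability `p`: `b * log(p) + (1 - b) * log(1 - p)`.
#'
#' @param b_obs Binary response(s) in `{0, 1}`.
#' @param p Response probability, strictly in (0, 1), vectorized.
#' @return Log-likelihood, vectorized.
#' @export
loglik_behavior <- function(b_obs, p) {
  if (any(!b_obs %in% c(0, 1))) stop("b_obs must be 0 or 1")
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  b_obs * log(p) + (1 - b_obs) * log(1 - p)
}

# natural-scale view of only the coefficients a given observation row needs
.params_for <- function(walk, need_emg, need_alpha, need_dt) {
  out <- list()
  if (need_emg) {
    out$mu1 <- exp(walk[, "log_mu1"])
    out$emg_intercept <- walk[, "emg_intercept"]
    out$emg_sd <- exp(walk[, "log_emg_sd"])
  }
  if (need_alpha) {
    out$alpha_gain <- exp(walk[, "log_alpha_gain"])
    out$alpha_offset <- walk[, "alpha_offset"]
    out$alpha_sd <- exp(walk[, "log_alpha_sd"])
  }
  if (need_dt) {
    out$dt_gain <- exp(walk[, "log_dt_gain"])
    out$dt_offset <- walk[, "dt_offset"]
    out$dt_sd <- exp(walk[, "log_dt_sd"])
  }
  out
}

#' Joint log-likelihood of one observation time
#'
#' Sums the modality log-likelihoods, weighted by the presence indicators:
#' an absent modality contributes exactly 0, so the likelihood degrades
#' gracefully under missing data (sensor dropouts, unscorable trials).
#'
#' @param obs A list/row with fields `b`, `m`, `y_alpha`, `y_dt` and logical
#'   indicators `I_b`, `I_m`, `I_alpha`, `I_dt`.
#' @param state Numeric length-3 vector (`m`, `alpha`, `dt`) or `N x 3`
#'   particle matrix.
#' @param params Natural-scale parameter list (see [params_natural()]).
#' @param beta Combination weight for the wake state.
#' @return Scalar (or length-N) joint log-likelihood.
#' @export
joint_loglik <- function(obs, state, params, beta = 1 / 3) {
  if (is.matrix(state)) {
    x_m <- state[, 1L]; x_a <- state[, 2L]; x_d <- state[, 3L]
  } else {
    x_m <- state[[1L]]; x_a <- state[[2L]]; x_d <- state[[3L]]
  }
  ll <- 0
  if (isTRUE(obs$I_b)) {
    p <- stats::plogis(beta * (x_m + x_a - x_d))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- ll + loglik_behavior(obs$b, p)
  }
  if (isTRUE(obs$I_m))
    ll <- ll + loglik_emg(obs$m, x_m, params$mu1, params$emg_sd,
                          params$emg_intercept)
  if (isTRUE(obs$I_alpha))
    ll <- ll + loglik_eeg(obs$y_alpha, x_a, params$alpha_gain,
                          params$alpha_offset, params$alpha_sd)
  if (isTRUE(obs$I_dt))
    ll <- ll + loglik_eeg(obs$y_dt, x_d, params$dt_gain,
                          params$dt_offset, params$dt_sd)
  ll
}

#' Construct a time-aligned observation grid
#'
#' Bundles the three observation streams onto one regular time grid.
#' Indicators are derived from missingness: `NA` means absent.
#'
#' @param times Regularly spaced grid times (s).
#' @param b Binary responses (`NA` off trial times or unscored).
#' @param m Log EMG squeeze amplitudes (`NA` where absent).
#' @param y_alpha,y_dt (Log) band-power observations (`NA` where absent).
#' @return A data frame of class `wp_obs_grid` with attribute `dt` (grid
#'   spacing, s).
#' @export
observation_grid <- function(times, b = NULL, m = NULL, y_alpha = NULL,
                             y_dt = NULL) {
  times <- as.numeric(times)
  n <- length(times)
  stopifnot(n >= 1L)
  if (n > 1L) {
    dts <- diff(times)
    if (max(abs(dts - dts[1L])) > 1e-6 * max(abs(dts[1L]), 1))
      stop("grid spacing must be constant")
    dt <- dts[1L]
  } else dt <- NA_real_
  fill <- function(x) if (is.null(x)) rep(NA_real_, n) else {
    if (length(x) != n) stop("all observation vectors must match the grid length")
    as.numeric(x)
  }
  g <- data.frame(time = times, b = fill(b), m = fill(m),
                  y_alpha = fill(y_alpha), y_dt = fill(y_dt))
  g$I_b <- !is.na(g$b)
  g$I_m <- !is.na(g$m)
  g$I_alpha <- !is.na(g$y_alpha)
  g$I_dt <- !is.na(g$y_dt)
  if (any(g$b[g$I_b] != 0 & g$b[g$I_b] != 1))
    stop("behavioral responses must be 0/1/NA")
  attr(g, "dt") <- dt
  class(g) <- c("wp_obs_grid", "data.frame")
  g
}

#' @export
print.wp_obs_grid <- function(x, ...) {
  cat(sprintf(
    "<wp_obs_grid> %d times (dt = %g s): %d behavioral, %d EMG, %d alpha, %d delta-theta observations\n",
    nrow(x), attr(x, "dt"), sum(x$I_b), sum(x$I_m), sum(x$I_alpha), sum(x$I_dt)))
  invisible(x)
}
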
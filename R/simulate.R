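#' Define a simulation scenario
#'
#' Describes a fully specified synthetic sleep-onset recording: the latent
#' state trajectory shape, the true observation coefficients, trial rate and
#' missingness. Defaults emulate a 10-minute sleep-onset descent sampled on a
#' 0.25-s grid, with breaths at a resting respiratory rate of ~15/min.
#'
#' @param duration Recording length, seconds.
#' @param dt Grid spacing, seconds (the spectrogram step).
#' @param trajectory One of `"random_walk"`, `"sigmoid_descent"`,
#'   `"descent_with_arousal"`, `"alpha_dropout"`, `"step"`. `sigmoid_descent`
#'   moves motor/alpha states from `state_hi` down to `state_lo` (delta-theta
#'   mirrored upward) along a logistic ramp; `descent_with_arousal` adds a
#'   roughly one-minute reversal toward wake; `alpha_dropout` advances the
#'   alpha descent by `alpha_lag` seconds before the delta-theta rise; `step`
#'   switches instantaneously at `t_mid` (the generative form implied by
#'   hypnogram-based instantaneous transition models).
#' @param params True walk-scale coefficient vector (see
#'   [params_walk_scale()]).
#' @param state_hi,state_lo Wake and sleep plateau values of the state paths.
#' @param t_mid Transition midpoint, seconds (default `duration / 2`).
#' @param tau Logistic ramp time constant, seconds (~4 `tau` spans the
#'   transition).
#' @param alpha_lag Advance of the alpha descent for `alpha_dropout`, s.
#' @param arousal_time,arousal_sd,arousal_amp Center, width (Gaussian sd) and
#'   state amplitude of the arousal reversal.
#' @param walk_sd Per-step generative state walk sd (length 3 or scalar).
#' @param trial_rate Breaths (trials) per minute.
#' @param trial_jitter Fractional jitter of the inter-breath interval.
#' @param missing Named rates in `[0, 1]` for clearing observations:
#'   `b`, `m`, `eeg`.
#' @return A list of class `wp_scenario`.
#' @export
wp_scenario <- function(duration = 600, dt = 0.25,
                        trajectory = c("sigmoid_descent", "random_walk",
                                       "descent_with_arousal",
                                       "alpha_dropout", "step"),
                        params = params_walk_scale(),
                        state_hi = 3, state_lo = -3,
                        t_mid = duration / 2, tau = 30,
                        alpha_lag = 300,
                        arousal_time = t_mid + 120, arousal_sd = 15,
                        arousal_amp = state_hi - state_lo,
                        walk_sd = 0.1,
                        trial_rate = 15, trial_jitter = 0.2,
                        missing = c(b = 0, m = 0, eeg = 0)) {
  trajectory <- match.arg(trajectory)
  stopifnot(duration > 0, dt > 0, trial_rate >= 0,
            all(missing >= 0), all(missing <= 1),
            all(c("b", "m", "eeg") %in% names(missing)))
  if (length(walk_sd) == 1L) walk_sd <- rep(walk_sd, 3L)
  structure(list(duration = duration, dt = dt, trajectory = trajectory,
                 params = params, state_hi = state_hi, state_lo = state_lo,
                 t_mid = t_mid, tau = tau, alpha_lag = alpha_lag,
                 arousal_time = arousal_time, arousal_sd = arousal_sd,
                 arousal_amp = arousal_amp, walk_sd = walk_sd,
                 trial_rate = trial_rate, trial_jitter = trial_jitter,
                 missing = missing),
            class = "wp_scenario")
}

#' Simulate latent state and wake-probability trajectories
#'
#' Generates the three state paths (motor, alpha, delta-theta) for a
#' scenario: a deterministic shape per the trajectory type plus random-walk
#' noise (`random_walk` is pure walk), and the implied true response
#' probability `p = logistic(beta * (x_m + x_alpha - x_dt))`.
#'
#' @param scenario A [wp_scenario()].
#' @param seed Integer seed.
#' @param beta Combination weight.
#' @return List with `times`, `states` (T x 3 matrix), `p` (true wake
#'   probability per grid time).
#' @export
simulate_states <- function(scenario, seed, beta = 1 / 3) {
  stopifnot(inherits(scenario, "wp_scenario"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  times <- seq(0, scenario$duration, by = scenario$dt)
  T_ <- length(times)
  hi <- scenario$state_hi; lo <- scenario$state_lo
  ramp_down <- function(t, mid) hi - (hi - lo) * stats::plogis((t - mid) / scenario$tau)
  mean_path <- switch(scenario$trajectory,
    random_walk = NULL,
    sigmoid_descent = cbind(m = ramp_down(times, scenario$t_mid),
                            alpha = ramp_down(times, scenario$t_mid),
                            dt = (hi + lo) - ramp_down(times, scenario$t_mid)),
    alpha_dropout = cbind(m = ramp_down(times, scenario$t_mid),
                          alpha = ramp_down(times, scenario$t_mid - scenario$alpha_lag),
                          dt = (hi + lo) - ramp_down(times, scenario$t_mid)),
    descent_with_arousal = {
      bump <- scenario$arousal_amp *
        exp(-(times - scenario$arousal_time)^2 / (2 * scenario$arousal_sd^2))
      base <- ramp_down(times, scenario$t_mid)
      cbind(m = pmin(base + bump, hi),
            alpha = pmin(base + bump, hi),
            dt = pmax((hi + lo) - base - bump, lo))
    },
    step = cbind(m = ifelse(times < scenario$t_mid, hi, lo),
                 alpha = ifelse(times < scenario$t_mid, hi, lo),
                 dt = ifelse(times < scenario$t_mid, lo, hi)))
  walk <- cbind(cumsum(stats::rnorm(T_, 0, scenario$walk_sd[1L])),
                cumsum(stats::rnorm(T_, 0, scenario$walk_sd[2L])),
                cumsum(stats::rnorm(T_, 0, scenario$walk_sd[3L])))
  if (is.null(mean_path)) {
    states <- cbind(m = hi + walk[, 1L], alpha = hi + walk[, 2L],
                    dt = lo + walk[, 3L])
  } else {
    states <- mean_path + walk
  }
  colnames(states) <- c("m", "alpha", "dt")
  p <- stats::plogis(beta * (states[, 1L] + states[, 2L] - states[, 3L]))
  list(times = times, states = states, p = as.numeric(p))
}

#' Simulate observations from latent states
#'
#' Draws the observation streams from the model's own observation equations
#' under the true coefficients: EEG (log) band powers at every grid time,
#' log EMG amplitudes and Bernoulli responses at jittered breath-trial times
#' assigned to the nearest grid point, with configured missingness applied by
#' clearing observations.
#'
#' @param sim Output of [simulate_states()].
#' @param scenario The same [wp_scenario()].
#' @param seed Integer seed.
#' @param beta Combination weight.
#' @return A [observation_grid()].
#' @export
simulate_observations <- function(sim, scenario, seed, beta = 1 / 3) {
  stopifnot(inherits(scenario, "wp_scenario"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  times <- sim$times
  T_ <- length(times)
  pars <- params_natural(scenario$params)
  y_alpha <- pars$alpha_offset + pars$alpha_gain * stats::plogis(sim$states[, 2L]) +
    stats::rnorm(T_, 0, pars$alpha_sd)
  y_dt <- pars$dt_offset + pars$dt_gain * stats::plogis(sim$states[, 3L]) +
    stats::rnorm(T_, 0, pars$dt_sd)
  b <- rep(NA_real_, T_)
  m <- rep(NA_real_, T_)
  if (scenario$trial_rate > 0) {
    ibi <- 60 / scenario$trial_rate
    tt <- ibi / 2
    trial_times <- numeric(0)
    while (tt < scenario$duration) {
      trial_times <- c(trial_times, tt)
      tt <- tt + ibi * (1 + stats::runif(1, -scenario$trial_jitter,
                                         scenario$trial_jitter))
    }
    idx <- unique(pmin(pmax(round(trial_times / scenario$dt) + 1L, 1L), T_))
    p_tr <- pmin(pmax(sim$p[idx], 1e-12), 1 - 1e-12)
    b[idx] <- stats::rbinom(length(idx), 1L, p_tr)
    m[idx] <- pars$emg_intercept + pars$mu1 * sim$states[idx, 1L] +
      stats::rnorm(length(idx), 0, pars$emg_sd)
  }
  # missingness: clear observations at the configured rates
  drop <- function(x, rate) {
    if (rate > 0) {
      pres <- which(!is.na(x))
      x[pres[stats::runif(length(pres)) < rate]] <- NA_real_
    }
    x
  }
  b <- drop(b, scenario$missing[["b"]])
  m <- drop(m, scenario$missing[["m"]])
  if (scenario$missing[["eeg"]] > 0) {
    gone <- stats::runif(T_) < scenario$missing[["eeg"]]
    y_alpha[gone] <- NA_real_
    y_dt[gone] <- NA_real_
  }
  observation_grid(times, b = b, m = m, y_alpha = y_alpha, y_dt = y_dt)
}

#' Derive a hypnogram from the true wake probability
#'
#' Maps the mean true `p` in each epoch to a stage via descending
#' thresholds: `W` for mean p >= `w_thresh`, `N1` for >= `n1_thresh`, else
#' `N2`. The thresholds are scenario parameters, not physiological claims:
#' real hypnograms are human-scored, and these simply provide staged inputs
#' with the right structure for testing onset definitions.
#'
#' @param p True wake probability per grid time.
#' @param times Grid times (s).
#' @param epoch_length Epoch length, s (default 30).
#' @param w_thresh,n1_thresh Stage thresholds on mean epoch p.
#' @return A data frame of class `wp_hypnogram` with columns `epoch`
#'   (0-based index), `stage`; attribute `epoch_length`.
#' @export
simulate_hypnogram <- function(p, times, epoch_length = 30,
                               w_thresh = 0.7, n1_thresh = 0.3) {
  stopifnot(length(p) == length(times), epoch_length > 0,
            w_thresh > n1_thresh)
  ep <- floor(times / epoch_length)
  means <- tapply(p, ep, mean)
  stage <- ifelse(means >= w_thresh, "W",
                  ifelse(means >= n1_thresh, "N1", "N2"))
  hypnogram(stage, epoch_length)
}

#' Construct a hypnogram
#' @param stages Character vector of stage codes in `{W, N1, N2, N3, R}`.
#' @param epoch_length Epoch length in seconds (default 30).
#' @return A `wp_hypnogram` data frame with `epoch` (0-based) and `stage`.
#' @export
hypnogram <- function(stages, epoch_length = 30) {
  stages <- as.character(stages)
  stopifnot(length(stages) >= 1L, epoch_length > 0)
  bad <- !stages %in% c("W", "N1", "N2", "N3", "R")
  if (any(bad))
    stop("invalid stage code(s) at epoch(s) ",
         paste(which(bad) - 1L, collapse = ", "),
         ": must be one of W, N1, N2, N3, R")
  structure(data.frame(epoch = seq_along(stages) - 1L, stage = stages),
            epoch_length = epoch_length,
            class = c("wp_hypnogram", "data.frame"))
}

#' Simulate a complete synthetic sleep-onset dataset
#'
#' Ground-truth states and wake probability, the observation grid, and a
#' derived hypnogram, reproducible from `(scenario, seed)`.
#'
#' @param scenario A [wp_scenario()].
#' @param seed Integer seed.
#' @param beta Combination weight.
#' @param epoch_length Hypnogram epoch length, s.
#' @return A list of class `wp_simulation`: `scenario`, `seed`, `times`,
#'   `states`, `p`, `grid`, `hypnogram`.
#' @export
simulate_sop <- function(scenario = wp_scenario(), seed, beta = 1 / 3,
                         epoch_length = 30) {
  if (missing(seed)) stop("seed is required")
  sim <- simulate_states(scenario, seed = seed, beta = beta)
  grid <- simulate_observations(sim, scenario, seed = seed + 1L, beta = beta)
  hyp <- simulate_hypnogram(sim$p, sim$times, epoch_length = epoch_length)
  structure(list(scenario = scenario, seed = seed, times = sim$times,
                 states = sim$states, p = sim$p, grid = grid,
                 hypnogram = hyp),
            class = "wp_simulation")
}

#' @export
print.wp_simulation <- function(x, ...) {
  cat(sprintf("<wp_simulation> %s, %.0f s @ dt = %g s, %d trials, seed %d\n",
              x$scenario$trajectory, x$scenario$duration, x$scenario$dt,
              sum(x$grid$I_b), x$seed))
  invisible(x)
}
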
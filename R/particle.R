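#' Initialize a particle ensemble from the priors
#'
#' Draws `n_particles` i.i.d. samples of the latent states and walk-scale
#' coefficients from the Gaussian priors in the configuration, with uniform
#' weights `1/N`.
#'
#' @param config A [wp_config()].
#' @param n_particles Particle count (defaults to `config$n_particles`).
#' @param seed Optional integer seed (set for reproducibility).
#' @return A list of class `wp_ensemble` with `states` (N x 3), `params`
#'   (N x 9, walk scale), `weights`, `time_index`.
#' @export
init_particles <- function(config, n_particles = config$n_particles,
                           seed = NULL) {
  stopifnot(inherits(config, "wp_config"), n_particles >= 2L)
  if (!is.null(seed)) set.seed(seed)
  if (any(!is.finite(config$state_prior_sd)) ||
      any(!is.finite(config$param_prior_sd)))
    stop("improper prior configuration: non-finite prior sd")
  n <- as.integer(n_particles)
  states <- cbind(
    stats::rnorm(n, config$state_prior_mean[1L], config$state_prior_sd[1L]),
    stats::rnorm(n, config$state_prior_mean[2L], config$state_prior_sd[2L]),
    stats::rnorm(n, config$state_prior_mean[3L], config$state_prior_sd[3L]))
  colnames(states) <- c("m", "alpha", "dt")
  params <- vapply(.wp_param_names, function(nm)
    stats::rnorm(n, config$param_prior_mean[[nm]], config$param_prior_sd[[nm]]),
    numeric(n))
  structure(list(states = states, params = params,
                 weights = rep(1 / n, n), eve = seq_len(n),
                 time_index = 0L),
            class = "wp_ensemble")
}

#' @export
print.wp_ensemble <- function(x, ...) {
  cat(sprintf("<wp_ensemble> %d particles at time index %d (ESS = %.1f)\n",
              nrow(x$states), x$time_index, 1 / sum(x$weights^2)))
  invisible(x)
}

# systematic resampling: N evenly spaced points on the weight CDF
.systematic_resample <- function(weights) {
  n <- length(weights)
  u <- (stats::runif(1L) + 0:(n - 1L)) / n
  findInterval(u, cumsum(weights), rightmost.closed = TRUE) + 1L
}

# weighted empirical quantile (left-continuous inverse CDF)
.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o])
  cw <- cw / cw[length(cw)]
  x[o][pmax(1L, findInterval(probs, cw, left.open = TRUE) + 1L)]
}

#' One propagate-weight-resample step of the particle filter
#'
#' Propagates every particle through the state and coefficient random walks,
#' reweights by the exponentiated joint log-likelihood of the observation row
#' (log-domain with max-subtraction, so underflow cannot zero the ensemble
#' spuriously), renormalizes, and applies systematic resampling when the
#' effective sample size falls below `ess_frac * N`. A fully-missing
#' observation row leaves the weights untouched (pure propagation).
#'
#' @param ens A `wp_ensemble`.
#' @param obs One observation row (list with `b`, `m`, `y_alpha`, `y_dt`,
#'   `I_b`, `I_m`, `I_alpha`, `I_dt`).
#' @param config A [wp_config()].
#' @return The updated `wp_ensemble` (attribute `resampled` records whether
#'   resampling fired).
#' @export
pf_step <- function(ens, obs, config) {
  stopifnot(inherits(ens, "wp_ensemble"))
  n <- nrow(ens$states)
  ens <- .propagate(ens, config)
  w <- ens$weights
  any_obs <- isTRUE(obs$I_b) || isTRUE(obs$I_m) ||
    isTRUE(obs$I_alpha) || isTRUE(obs$I_dt)
  resampled <- FALSE
  if (any_obs) {
    ll <- joint_loglik(obs, ens$states,
                       .params_for(ens$params, isTRUE(obs$I_m),
                                   isTRUE(obs$I_alpha), isTRUE(obs$I_dt)),
                       beta = config$beta)
    ll[!is.finite(ll)] <- -Inf
    lw <- log(w) + ll
    mx <- max(lw)
    if (!is.finite(mx))
      stop("all particle weights vanished at t = ", obs$time,
           " (time index ", ens$time_index + 1L, "); observation inconsistent with the ensemble")
    w <- exp(lw - mx)
    w <- w / sum(w)
    ess <- 1 / sum(w^2)
    if (ess < config$ess_frac * n) {
      idx <- .systematic_resample(w)
      ens$states <- ens$states[idx, , drop = FALSE]
      ens$params <- ens$params[idx, , drop = FALSE]
      ens$eve <- ens$eve[idx]
      w <- rep(1 / n, n)
      resampled <- TRUE
    }
  }
  ens$weights <- w
  ens$time_index <- ens$time_index + 1L
  attr(ens, "resampled") <- resampled
  ens
}

#' Run the particle filter over an observation grid
#'
#' Applies [pf_step()] across all grid times, recording after each update the
#' weighted 2.5/50/97.5 percentiles of the response probability `p_t` (the
#' wake probability curve), weighted state means/sds and the effective sample
#' size, posterior quantiles of the predicted observation mean for each
#' modality, and -- at behavioral observation times -- equally weighted draws
#' of `p_t` from the distribution *before* assimilating that observation (the
#' one-step-ahead predictive used by the goodness-of-fit analysis).
#'
#' @param grid A [observation_grid()].
#' @param config A [wp_config()].
#' @param seed Integer seed; required, echoed in the result.
#' @param n_particles Override of `config$n_particles`.
#' @param record_obs_pred Record per-modality observation-mean quantiles
#'   (the overlay curves plotted on top of raw data). Skipping them
#'   (`FALSE`) speeds up long runs.
#' @param engine `"cpp"` (default) runs the compiled filtering core;
#'   `"r"` runs the pure-R reference loop built from [pf_step()]. Both
#'   implement the identical algorithm and draw from R's RNG, but their
#'   random-number streams differ, so results agree statistically rather
#'   than bit-for-bit across engines. Reruns with the same engine, seed,
#'   config and data are bit-identical.
#' @return A list of class `wp_fit`: `curve` (a `wp_curve` data frame),
#'   `predictive` (times + `n_keep` x n-trials matrix of pre-update p
#'   samples), `states` (per-time summaries), `obs_pred` (modality mean
#'   quantiles), `config`, `seed`, `n_particles`.
#' @export
run_filter <- function(grid, config = wp_config(), seed,
                       n_particles = config$n_particles,
                       record_obs_pred = TRUE,
                       engine = c("cpp", "r")) {
  stopifnot(inherits(grid, "wp_obs_grid"))
  engine <- match.arg(engine)
  if (missing(seed)) stop("seed is required for every inference run")
  T_ <- nrow(grid)
  if (T_ == 0L) stop("observation grid is empty")
  if (engine == "cpp") {
    set.seed(seed)
    out <- .pf_filter_cpp(
      grid$time, grid$b, grid$m, grid$y_alpha, grid$y_dt,
      as.integer(n_particles),
      unname(config$state_prior_mean), unname(config$state_prior_sd),
      unname(config$param_prior_mean), unname(config$param_prior_sd),
      unname(config$state_walk_sd),
      identical(config$param_evolution, "liu_west"), config$lw_delta,
      config$param_walk_sd, config$beta, config$ess_frac,
      as.integer(config$n_keep), isTRUE(record_obs_pred))
    curve <- data.frame(time = grid$time, p_lo = out$curve[, 1L],
                        p_median = out$curve[, 2L], p_hi = out$curve[, 3L])
    class(curve) <- c("wp_curve", "data.frame")
    return(structure(list(
      curve = curve,
      predictive = list(times = grid$time[grid$I_b], samples = out$pred),
      states = data.frame(time = grid$time,
                          m_mean = out$st_mean[, 1L], m_sd = out$st_sd[, 1L],
                          m_mcse = out$st_mcse[, 1L],
                          alpha_mean = out$st_mean[, 2L],
                          alpha_sd = out$st_sd[, 2L],
                          alpha_mcse = out$st_mcse[, 2L],
                          dt_mean = out$st_mean[, 3L],
                          dt_sd = out$st_sd[, 3L],
                          dt_mcse = out$st_mcse[, 3L],
                          ess = out$ess, resampled = out$resampled),
      obs_pred = if (record_obs_pred)
        list(emg = out$emgq, alpha = out$alphaq, dt = out$dtq,
             probs = c(0.025, 0.5, 0.975), time = grid$time),
      config = config, seed = seed, n_particles = as.integer(n_particles)),
      class = "wp_fit"))
  }
  ens <- init_particles(config, n_particles, seed = seed)
  n <- nrow(ens$states)
  probs <- c(0.025, 0.5, 0.975)
  curve_q <- matrix(NA_real_, T_, 3L)
  st_mean <- matrix(NA_real_, T_, 3L)
  st_sd <- matrix(NA_real_, T_, 3L)
  st_mcse <- matrix(NA_real_, T_, 3L)
  ess <- numeric(T_)
  resampled <- logical(T_)
  emg_q <- matrix(NA_real_, T_, 3L)
  alpha_q <- matrix(NA_real_, T_, 3L)
  dt_q <- matrix(NA_real_, T_, 3L)
  bt_idx <- which(grid$I_b)
  pred_samples <- matrix(NA_real_, config$n_keep, length(bt_idx))
  bt_pos <- 1L
  for (t in seq_len(T_)) {
    obs <- list(time = grid$time[t], b = grid$b[t], m = grid$m[t],
                y_alpha = grid$y_alpha[t], y_dt = grid$y_dt[t],
                I_b = grid$I_b[t], I_m = grid$I_m[t],
                I_alpha = grid$I_alpha[t], I_dt = grid$I_dt[t])
    # one-step-ahead predictive of p at behavioral times: propagate first,
    # sample p before weighting by this observation
    if (obs$I_b) {
      ens <- .propagate(ens, config)
      p_pre <- stats::plogis(config$beta *
        (ens$states[, 1L] + ens$states[, 2L] - ens$states[, 3L]))
      ki <- sample.int(n, config$n_keep, replace = TRUE, prob = ens$weights)
      pred_samples[, bt_pos] <- p_pre[ki]
      bt_pos <- bt_pos + 1L
      # weight/resample without re-propagating
      ens <- .pf_weight_only(ens, obs, config)
    } else {
      ens <- pf_step(ens, obs, config)
    }
    resampled[t] <- isTRUE(attr(ens, "resampled"))
    w <- ens$weights
    p_post <- stats::plogis(config$beta *
      (ens$states[, 1L] + ens$states[, 2L] - ens$states[, 3L]))
    curve_q[t, ] <- .weighted_quantile(p_post, w, probs)
    mu <- colSums(ens$states * w)
    st_mean[t, ] <- mu
    st_sd[t, ] <- sqrt(pmax(colSums(ens$states^2 * w) - mu^2, 0))
    ess[t] <- 1 / sum(w^2)
    # Monte Carlo standard error of each state mean via the ancestral
    # genealogy estimator (sum over surviving initial ancestors of the
    # squared within-family weighted deviations); unlike sd/sqrt(ESS) it
    # accounts for the dependence that resampling introduces
    dev <- ens$states - rep(mu, each = n)
    fam <- rowsum(dev * w, ens$eve)
    st_mcse[t, ] <- sqrt(colSums(fam^2))
    if (record_obs_pred) {
      np <- params_natural(ens$params)
      emg_q[t, ] <- .weighted_quantile(
        np$emg_intercept + np$mu1 * ens$states[, 1L], w, probs)
      alpha_q[t, ] <- .weighted_quantile(
        np$alpha_offset + np$alpha_gain * stats::plogis(ens$states[, 2L]), w, probs)
      dt_q[t, ] <- .weighted_quantile(
        np$dt_offset + np$dt_gain * stats::plogis(ens$states[, 3L]), w, probs)
    }
  }
  curve <- data.frame(time = grid$time, p_lo = curve_q[, 1L],
                      p_median = curve_q[, 2L], p_hi = curve_q[, 3L])
  class(curve) <- c("wp_curve", "data.frame")
  structure(list(
    curve = curve,
    predictive = list(times = grid$time[bt_idx], samples = pred_samples),
    states = data.frame(time = grid$time,
                        m_mean = st_mean[, 1L], m_sd = st_sd[, 1L],
                        m_mcse = st_mcse[, 1L],
                        alpha_mean = st_mean[, 2L], alpha_sd = st_sd[, 2L],
                        alpha_mcse = st_mcse[, 2L],
                        dt_mean = st_mean[, 3L], dt_sd = st_sd[, 3L],
                        dt_mcse = st_mcse[, 3L],
                        ess = ess, resampled = resampled),
    obs_pred = list(emg = emg_q, alpha = alpha_q, dt = dt_q,
                    probs = probs, time = grid$time),
    config = config, seed = seed, n_particles = n),
    class = "wp_fit")
}

# propagate states and coefficients one step. Coefficients evolve either by
# the plain random walk or by Liu-West kernel shrinkage: shrink each particle
# toward the weighted coefficient mean and add noise matched so the cloud's
# weighted mean and variance are preserved, regenerating the diversity that
# resampling removes without inflating coefficient variance over time.
.propagate <- function(ens, config) {
  ens$states <- state_transition(ens$states, config$state_walk_sd)
  if (identical(config$param_evolution, "walk")) {
    ens$params <- parameter_transition(ens$params, config$param_walk_sd)
  } else {
    n <- nrow(ens$params)
    w <- ens$weights
    a <- (3 * config$lw_delta - 1) / (2 * config$lw_delta)
    pm <- colSums(ens$params * w)
    pv <- pmax(colSums(ens$params^2 * w) - pm^2, 0)
    noise_sd <- sqrt((1 - a^2) * pv)
    ens$params <- a * ens$params +
      rep((1 - a) * pm, each = n) +
      matrix(stats::rnorm(n * length(pm)), n) * rep(noise_sd, each = n)
  }
  ens
}

# weighting/resampling part of pf_step, for times where propagation has
# already been applied (predictive sampling path)
.pf_weight_only <- function(ens, obs, config) {
  n <- nrow(ens$states)
  w <- ens$weights
  ll <- joint_loglik(obs, ens$states,
                     .params_for(ens$params, isTRUE(obs$I_m),
                                 isTRUE(obs$I_alpha), isTRUE(obs$I_dt)),
                     beta = config$beta)
  ll[!is.finite(ll)] <- -Inf
  lw <- log(w) + ll
  mx <- max(lw)
  if (!is.finite(mx))
    stop("all particle weights vanished at t = ", obs$time)
  w <- exp(lw - mx)
  w <- w / sum(w)
  resampled <- FALSE
  if (1 / sum(w^2) < config$ess_frac * n) {
    idx <- .systematic_resample(w)
    ens$states <- ens$states[idx, , drop = FALSE]
    ens$params <- ens$params[idx, , drop = FALSE]
    ens$eve <- ens$eve[idx]
    w <- rep(1 / n, n)
    resampled <- TRUE
  }
  ens$weights <- w
  ens$time_index <- ens$time_index + 1L
  attr(ens, "resampled") <- resampled
  ens
}

#' @export
print.wp_fit <- function(x, ...) {
  cat(sprintf("<wp_fit> %d time points, %d particles, seed %s\n",
              nrow(x$curve), x$n_particles, format(x$seed)))
  cat(sprintf("  final Pr(Wake) median %.3f [%.3f, %.3f]\n",
              x$curve$p_median[nrow(x$curve)], x$curve$p_lo[nrow(x$curve)],
              x$curve$p_hi[nrow(x$curve)]))
  invisible(x)
}

#' Plot a wake probability curve
#' @param x A `wp_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.wp_curve <- function(x, ...) {
  graphics::plot(x$time / 60, x$p_median, type = "n", ylim = c(0, 1),
                 xlab = "Time (min)", ylab = "Pr(Wake)", ...)
  graphics::polygon(c(x$time, rev(x$time)) / 60, c(x$p_lo, rev(x$p_hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$time / 60, x$p_median, col = "steelblue4", lwd = 2)
  invisible(x)
}

#' Exact Kalman filter for the linear-Gaussian EMG-only submodel
#'
#' When the model is restricted to the single motor state with a
#' linear-Gaussian EMG observation and fixed coefficients, the filtering
#' distributions are Gaussian and available in closed form. This recursion
#' serves as an exact oracle against which the particle filter is validated.
#'
#' @param grid A [observation_grid()] carrying only EMG observations (any
#'   behavioral or EEG indicator raises an error: the submodel is linear).
#' @param mu1 Observation slope.
#' @param intercept Observation intercept.
#' @param obs_sd Observation noise sd.
#' @param walk_sd State random-walk sd per step.
#' @param prior_mean,prior_sd Gaussian prior on the initial state.
#' @return Data frame with per-time predictive (`pred_mean`, `pred_var`) and
#'   filtered (`mean`, `var`) moments of the motor state.
#' @export
kalman_oracle <- function(grid, mu1, intercept = 0, obs_sd, walk_sd,
                          prior_mean = 0, prior_sd = 1) {
  stopifnot(inherits(grid, "wp_obs_grid"))
  if (any(grid$I_b) || any(grid$I_alpha) || any(grid$I_dt))
    stop("kalman_oracle handles the EMG-only linear-Gaussian submodel; remove nonlinear observations")
  stopifnot(obs_sd >= 0, walk_sd >= 0, prior_sd >= 0)
  T_ <- nrow(grid)
  out <- data.frame(time = grid$time, pred_mean = NA_real_,
                    pred_var = NA_real_, mean = NA_real_, var = NA_real_)
  mu <- prior_mean
  P <- prior_sd^2
  for (t in seq_len(T_)) {
    mu_p <- mu
    P_p <- P + walk_sd^2
    out$pred_mean[t] <- mu_p
    out$pred_var[t] <- P_p
    if (grid$I_m[t]) {
      S <- mu1^2 * P_p + obs_sd^2
      K <- P_p * mu1 / S
      mu <- mu_p + K * (grid$m[t] - intercept - mu1 * mu_p)
      P <- (1 - K * mu1) * P_p
    } else {
      mu <- mu_p
      P <- P_p
    }
    out$mean[t] <- mu
    out$var[t] <- P
  }
  out
}
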
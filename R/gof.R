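#' Hypnogram-defined sleep onset time
#'
#' Evaluates one of the four clinical instantaneous sleep-onset definitions
#' on a staged hypnogram: first epoch of N1, first epoch of N2, first of any
#' 3 consecutive NREM (N1 or deeper) epochs, or first of any 10 consecutive
#' NREM epochs. For the run rules the returned time is the start of the
#' *first* epoch of the qualifying run.
#'
#' @param h A [hypnogram()].
#' @param rule One of `"first_N1"`, `"first_N2"`, `"first_3_NREM"`,
#'   `"first_10_NREM"`.
#' @return Onset time in seconds from the start of the hypnogram, or
#'   `NA_real_` when the rule is never satisfied (subject treated as awake
#'   throughout by downstream comparisons).
#' @export
onset_time <- function(h, rule = c("first_N1", "first_N2", "first_3_NREM",
                                   "first_10_NREM")) {
  stopifnot(inherits(h, "wp_hypnogram"), nrow(h) >= 1L)
  rule <- match.arg(rule)
  el <- attr(h, "epoch_length")
  st <- h$stage
  idx <- switch(rule,
    first_N1 = which(st == "N1")[1L],
    first_N2 = which(st == "N2")[1L],
    first_3_NREM = .first_run(st %in% c("N1", "N2", "N3"), 3L),
    first_10_NREM = .first_run(st %in% c("N1", "N2", "N3"), 10L))
  if (is.na(idx)) return(NA_real_)
  (idx - 1L) * el
}

# index of the first element of the first run of >= k TRUEs
.first_run <- function(x, k) {
  run <- 0L
  for (i in seq_along(x)) {
    run <- if (x[i]) run + 1L else 0L
    if (run == k) return(i - k + 1L)
  }
  NA_integer_
}

#' Instantaneous-transition response probability curve
#'
#' The stepwise response-probability curve implied by a hypnogram-based
#' sleep-onset definition: the subject responds correctly with probability
#' `p_awake` (default 0.95) before onset and `p_asleep` (default 0.05) from
#' the onset epoch onward. No onset means awake throughout.
#'
#' @param h A [hypnogram()].
#' @param rule Onset definition (see [onset_time()]).
#' @param p_awake,p_asleep Response probabilities while awake / asleep,
#'   `0 < p_asleep < p_awake < 1`.
#' @param times Times (s) at which to evaluate the curve.
#' @return Data frame with `time` and `p` (taking at most two values with a
#'   single downward step).
#' @export
transition_probability_curve <- function(h, rule, p_awake = 0.95,
                                         p_asleep = 0.05, times) {
  stopifnot(0 < p_asleep, p_asleep < p_awake, p_awake < 1)
  onset <- onset_time(h, rule)
  p <- if (is.na(onset)) rep(p_awake, length(times))
       else ifelse(times < onset, p_awake, p_asleep)
  data.frame(time = as.numeric(times), p = p)
}

#' Monte Carlo total log-likelihood distribution of behavioral responses
#'
#' For each Monte Carlo iteration, one response probability is drawn per
#' scored trial from that trial's sample collection and the Bernoulli
#' log-likelihoods are summed over trials, yielding a sample from the
#' distribution of the total log-likelihood. For the wake-probability model
#' the per-trial collections are one-step-ahead predictive draws of `p_t`
#' (the posterior from the time step before the behavioral observation, so
#' the observed response never informs its own prediction); for an
#' instantaneous transition model each collection is degenerate at the step
#' curve value and every iteration returns the same closed-form sum.
#'
#' @param p_samples A list with one numeric vector per scored trial (each a
#'   sample collection of that trial's response probability; length-1 vectors
#'   are degenerate point masses), or a matrix with one column per trial.
#' @param responses Binary responses, one per scored trial (no `NA`s: missing
#'   trials are excluded from all models identically before calling).
#' @param n_mc Number of Monte Carlo iterations (default 10000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_mc` total log-likelihood samples.
#' @export
loglik_distribution <- function(p_samples, responses, n_mc = 10000L, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.matrix(p_samples))
    p_samples <- lapply(seq_len(ncol(p_samples)), function(j) p_samples[, j])
  n_tr <- length(responses)
  if (length(p_samples) != n_tr)
    stop("need one p-sample collection per scored trial (got ",
         length(p_samples), " collections for ", n_tr, " trials)")
  if (any(is.na(responses)))
    stop("responses must be scored (0/1); drop missing trials first")
  stopifnot(n_mc >= 1L)
  set.seed(seed)
  total <- numeric(n_mc)
  for (j in seq_len(n_tr)) {
    s <- p_samples[[j]]
    if (length(s) == 0L || any(is.na(s)))
      stop("empty or NA p-sample collection for trial ", j)
    s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
    draws <- if (length(s) == 1L) rep(s, n_mc)
             else s[sample.int(length(s), n_mc, replace = TRUE)]
    total <- total + loglik_behavior(rep(responses[j], n_mc), draws)
  }
  total
}

#' Compare two model log-likelihood distributions
#'
#' Pairs the sample sets by iteration, forms the difference distribution
#' (first minus second), and summarizes it: medians, central 95% credible
#' intervals, the posterior probability that the difference is positive, and
#' the largest central credible level at which the difference distribution
#' excludes zero.
#'
#' @param model_samples,competitor_samples Equal-length log-likelihood sample
#'   vectors (pair by iteration).
#' @return A list of class `wp_model_comparison` with `model_median`,
#'   `model_ci`, `competitor_median`, `competitor_ci`, `diff_median`,
#'   `diff_ci`, `prob_diff_positive`, `credibility_excluding_zero`.
#' @export
compare_models <- function(model_samples, competitor_samples) {
  if (length(model_samples) == 0L || length(competitor_samples) == 0L)
    stop("empty log-likelihood samples")
  if (length(model_samples) != length(competitor_samples))
    stop("sample counts must be equal across models (pair by iteration)")
  d <- model_samples - competitor_samples
  ci <- function(x) unname(stats::quantile(x, c(0.025, 0.975)))
  q_pos <- mean(d > 0)
  # largest central level excluding zero: 1 - 2 * min tail mass at zero
  cred <- 1 - 2 * min(mean(d <= 0), mean(d >= 0))
  structure(list(model_median = stats::median(model_samples),
                 model_ci = ci(model_samples),
                 competitor_median = stats::median(competitor_samples),
                 competitor_ci = ci(competitor_samples),
                 diff_median = stats::median(d),
                 diff_ci = ci(d),
                 prob_diff_positive = q_pos,
                 credibility_excluding_zero = max(cred, 0)),
            class = "wp_model_comparison")
}

#' @export
print.wp_model_comparison <- function(x, ...) {
  cat(sprintf("<wp_model_comparison> model %.1f [%.1f, %.1f] vs competitor %.1f [%.1f, %.1f]\n",
              x$model_median, x$model_ci[1], x$model_ci[2],
              x$competitor_median, x$competitor_ci[1], x$competitor_ci[2]))
  cat(sprintf("  difference median %.1f [%.1f, %.1f]; Pr(diff > 0) = %.4f\n",
              x$diff_median, x$diff_ci[1], x$diff_ci[2], x$prob_diff_positive))
  invisible(x)
}

#' Goodness-of-fit table: wake model vs instantaneous transition models
#'
#' Runs the full Bayesian Monte Carlo likelihood comparison for one night:
#' the wake-probability model (via its one-step-ahead predictive samples of
#' `p_t` at scored trial times) against the four hypnogram-derived
#' instantaneous transition models.
#'
#' @param fit A [run_filter()] result.
#' @param grid The [observation_grid()] that was filtered.
#' @param h The night's [hypnogram()].
#' @param p_awake,p_asleep Instantaneous-model accuracies.
#' @param n_mc Monte Carlo iterations.
#' @param seed Integer seed.
#' @return A list of class `wp_gof`: `table` (one row per model: median
#'   loglik, 95% CI, difference median/CI vs the wake model, and
#'   `prob_diff_positive`), plus the raw sample vectors in `samples`.
#' @export
gof_analysis <- function(fit, grid, h, p_awake = 0.95, p_asleep = 0.05,
                         n_mc = 10000L, seed) {
  stopifnot(inherits(fit, "wp_fit"), inherits(grid, "wp_obs_grid"))
  if (missing(seed)) stop("seed is required")
  bt <- which(grid$I_b)
  responses <- grid$b[bt]
  bt_times <- grid$time[bt]
  # wake model: predictive p samples per trial
  stopifnot(length(fit$predictive$times) == length(bt))
  wake_cols <- lapply(seq_along(bt), function(j) fit$predictive$samples[, j])
  wake_ll <- loglik_distribution(wake_cols, responses, n_mc, seed = seed)
  rules <- c("first_N1", "first_N2", "first_3_NREM", "first_10_NREM")
  samples <- list(wake = wake_ll)
  rows <- list(data.frame(model = "wake_probability",
                          loglik_median = stats::median(wake_ll),
                          loglik_lo = stats::quantile(wake_ll, 0.025),
                          loglik_hi = stats::quantile(wake_ll, 0.975),
                          diff_median = NA_real_, diff_lo = NA_real_,
                          diff_hi = NA_real_, prob_diff_positive = NA_real_))
  for (r in rules) {
    curve <- transition_probability_curve(h, r, p_awake, p_asleep, bt_times)
    inst_cols <- as.list(curve$p)
    inst_ll <- loglik_distribution(inst_cols, responses, n_mc,
                                   seed = seed + match(r, rules))
    cmp <- compare_models(wake_ll, inst_ll)
    samples[[r]] <- inst_ll
    rows[[length(rows) + 1L]] <- data.frame(
      model = r,
      loglik_median = cmp$competitor_median,
      loglik_lo = cmp$competitor_ci[1], loglik_hi = cmp$competitor_ci[2],
      diff_median = cmp$diff_median,
      diff_lo = cmp$diff_ci[1], diff_hi = cmp$diff_ci[2],
      prob_diff_positive = cmp$prob_diff_positive)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, samples = samples,
                 p_awake = p_awake, p_asleep = p_asleep,
                 n_mc = n_mc, seed = seed),
            class = "wp_gof")
}

#' @export
print.wp_gof <- function(x, ...) {
  cat("<wp_gof> Bayesian goodness-of-fit comparison\n")
  print(x$table, digits = 4)
  invisible(x)
}
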
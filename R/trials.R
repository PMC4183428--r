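#' Construct a breath-trial series
#'
#' Each respiratory inhale apex is one trial of the breathing task. The
#' response is `1` (correct squeeze), `0` (incorrect / no squeeze) or `NA`
#' (unscorable, e.g. inside an artifact interval).
#'
#' @param time Strictly increasing inhale-apex times (s).
#' @param response Integer/numeric vector in `{1, 0, NA}`.
#' @return A data frame of class `wp_trials` with columns `time`, `response`.
#' @export
breath_trials <- function(time, response) {
  time <- as.numeric(time)
  if (length(time) != length(response))
    stop("time and response must have equal length")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("trial times must be strictly increasing")
  response <- as.integer(response)
  if (any(!response %in% c(0L, 1L) & !is.na(response)))
    stop("responses must be 1 (correct), 0 (incorrect) or NA (missing)")
  structure(data.frame(time = time, response = response),
            class = c("wp_trials", "data.frame"))
}

#' Score breath trials from squeeze and artifact intervals
#'
#' One trial is emitted per inhale apex. A trial is *correct* when some
#' squeeze interval overlaps the apex's alignment window, *incorrect* when no
#' squeeze does, and *missing* (`NA`) when the apex falls inside an artifact
#' interval. The alignment window is `[apex - half_breath, apex +
#' half_breath]`; by default `half_breath` is half the local inter-inhale
#' interval, since a squeeze belonging to a breath must land within that
#' breath.
#'
#' @param inhale_times Sorted inhale-apex times (s).
#' @param squeeze_intervals List of `c(start, end)` squeeze intervals, or a
#'   two-column matrix/data frame.
#' @param artifact_intervals Same shape; trials inside these are unscored.
#' @param half_breath Alignment half-window (s); `NULL` (default) uses half
#'   the local inter-inhale gap.
#' @return A `wp_trials` data frame.
#' @export
score_trials <- function(inhale_times, squeeze_intervals = list(),
                         artifact_intervals = list(), half_breath = NULL) {
  inhale_times <- as.numeric(inhale_times)
  if (length(inhale_times) == 0L) return(breath_trials(numeric(0), integer(0)))
  if (any(diff(inhale_times) <= 0)) stop("inhale_times must be sorted, strictly increasing")
  sq <- .as_intervals(squeeze_intervals, "squeeze_intervals")
  ar <- .as_intervals(artifact_intervals, "artifact_intervals")
  n <- length(inhale_times)
  if (is.null(half_breath)) {
    gaps <- diff(inhale_times)
    hb <- numeric(n)
    if (n == 1L) {
      hb[] <- 2  # lone breath: generous 2-s window
    } else {
      hb[1L] <- gaps[1L] / 2
      hb[n] <- gaps[n - 1L] / 2
      if (n > 2L) hb[2:(n - 1L)] <- pmin(gaps[-(n - 1L)], gaps[-1L])[1:(n - 2L)] / 2
    }
  } else {
    stopifnot(half_breath > 0)
    hb <- rep(half_breath, n)
  }
  resp <- integer(n)
  for (i in seq_len(n)) {
    t <- inhale_times[i]
    if (nrow(ar) > 0L && any(t >= ar[, 1L] & t <= ar[, 2L])) {
      resp[i] <- NA_integer_
    } else if (nrow(sq) > 0L &&
               any(sq[, 1L] <= t + hb[i] & sq[, 2L] >= t - hb[i])) {
      resp[i] <- 1L
    } else {
      resp[i] <- 0L
    }
  }
  breath_trials(inhale_times, resp)
}

.as_intervals <- function(x, what) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(0), ncol = 2L))
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.list(x)) x <- do.call(rbind, x)
  x <- matrix(as.numeric(x), ncol = 2L)
  if (any(x[, 1L] >= x[, 2L]))
    stop(what, ": intervals must satisfy start < end")
  x
}

#' Trim trials to the task scoring window
#'
#' Task scoring begins at the first trial of the first run of at least
#' `min_run` consecutive correct responses after lights out, and stops
#' `stop_after` seconds (default 600 s = 10 min) after the last correct
#' response. Trials are never reordered or relabeled, only trimmed.
#'
#' @param trials A `wp_trials` series sorted by time.
#' @param lights_out Lights-out time (s); trials before it are ignored.
#' @param min_run Required run of consecutive correct responses (default 3).
#' @param stop_after Seconds past the last correct response at which scoring
#'   stops (default 600).
#' @return The trimmed `wp_trials` series (possibly empty, with a warning
#'   when no qualifying run exists).
#' @export
scoring_window <- function(trials, lights_out = 0, min_run = 3L,
                           stop_after = 600) {
  stopifnot(inherits(trials, "wp_trials"))
  keep <- trials$time >= lights_out
  tr <- trials[keep, , drop = FALSE]
  n <- nrow(tr)
  start_idx <- NA_integer_
  if (n >= min_run) {
    correct <- !is.na(tr$response) & tr$response == 1L
    run <- 0L
    for (i in seq_len(n)) {
      run <- if (correct[i]) run + 1L else 0L
      if (run == min_run) { start_idx <- i - min_run + 1L; break }
    }
  }
  if (is.na(start_idx)) {
    warning("no run of ", min_run, " consecutive correct responses after lights out; empty scoring window")
    return(breath_trials(numeric(0), integer(0)))
  }
  tr <- tr[start_idx:n, , drop = FALSE]
  correct_times <- tr$time[!is.na(tr$response) & tr$response == 1L]
  end_time <- max(correct_times) + stop_after
  out <- tr[tr$time <= end_time, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("wp_trials", "data.frame")
  out
}
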
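#' Construct a raw sampled signal
#'
#' A thin container for a uniformly sampled physiological channel (EEG, EMG,
#' airflow, ...). Times are measured in seconds from lights-out.
#'
#' @param samples Numeric vector of samples (signal units). `NA` marks missing
#'   samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel name.
#' @param start_time Time of the first sample, in seconds from lights-out.
#'
#' @return An object of class `wp_raw_signal` with fields `samples`, `fs`,
#'   `label`, `start_time`.
#' @export
#' @examples
#' sig <- raw_signal(sin(2 * pi * 10 * seq(0, 1, by = 1/250)), fs = 250, label = "EMG")
#' print(sig)
raw_signal <- function(samples, fs, label = "signal", start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (any(is.infinite(samples)))
    stop("samples must be finite or NA")
  structure(
    list(samples = samples, fs = fs, label = as.character(label)[1L],
         start_time = as.numeric(start_time)[1L]),
    class = "wp_raw_signal")
}

#' @export
print.wp_raw_signal <- function(x, ...) {
  cat(sprintf("<wp_raw_signal> %s: %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              x$label, length(x$samples), x$fs, x$start_time,
              x$start_time + (length(x$samples) - 1L) / x$fs))
  invisible(x)
}

#' Sample times of a raw signal
#' @param x A `wp_raw_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "wp_raw_signal"))
  x$start_time + seq.int(0L, length(x$samples) - 1L) / x$fs
}

#' Bandpass and notch filter an EMG channel
#'
#' Applies a Butterworth bandpass (default 10--70 Hz) followed by a narrow
#' band-stop notch at the mains frequency (default 60 Hz, +/- 1 Hz). Both
#' stages are applied forward-backward (zero phase), so squeeze timing is
#' preserved.
#'
#' @param raw A `wp_raw_signal`.
#' @param low,high Bandpass corner frequencies in Hz.
#' @param notch Mains frequency to reject, in Hz, or `NULL` to skip the notch.
#' @param order Butterworth order of the bandpass stage.
#'
#' @return A filtered `wp_raw_signal` on the same time base.
#' @export
filter_emg <- function(raw, low = 10, high = 70, notch = 60, order = 4L) {
  stopifnot(inherits(raw, "wp_raw_signal"))
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (raw$fs <= 2 * high)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz passband edge (need fs > %g)",
                 raw$fs, high, 2 * high))
  nyq <- raw$fs / 2
  x <- raw$samples
  npad <- round(2 * raw$fs)  # ~2 s reflection padding suppresses edge transients
  bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- .filtfilt_padded(bp, x, npad)
  if (!is.null(notch)) {
    if (notch + 1 >= nyq) stop("notch frequency too close to Nyquist")
    bs <- signal::butter(2L, c(notch - 1, notch + 1) / nyq, type = "stop")
    y <- .filtfilt_padded(bs, y, npad)
  }
  out <- raw
  out$samples <- as.numeric(y)
  out
}

# forward-backward filtering with odd (point-reflected) end padding
.filtfilt_padded <- function(filt, x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  if (npad < 1L) return(as.numeric(signal::filtfilt(filt, x)))
  xp <- c(2 * x[1L] - rev(x[2:(npad + 1L)]), x,
          2 * x[n] - rev(x[(n - npad):(n - 1L)]))
  y <- signal::filtfilt(filt, xp)
  as.numeric(y[(npad + 1L):(npad + n)])
}

#' Analytic-signal amplitude envelope
#'
#' FFT-based Hilbert envelope: the magnitude of the analytic signal
#' `x + i * H(x)`.
#'
#' @param x Numeric vector (a real signal).
#' @return Numeric vector of envelope amplitudes, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1L) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' EMG squeeze amplitude at a trial time
#'
#' Computes the log of the mean Hilbert-envelope amplitude of the (already
#' filtered) EMG in a window centered on the trial time. If the window is not
#' fully inside the recording the observation is returned as missing
#' (`present = FALSE`) rather than raising an error.
#'
#' @param filtered_emg A filtered EMG `wp_raw_signal`.
#' @param trial_time Trial (inhale-apex) time in seconds.
#' @param window Window length in seconds (default 1 s, centered).
#' @param envelope Optional precomputed envelope (same length as the signal);
#'   computed on the fly when `NULL`. Pass it when scoring many trials of the
#'   same recording.
#' @param floor_eps Positive floor applied to the mean amplitude before the
#'   log, guarding `log(0)`.
#'
#' @return A list of class `wp_emg_obs` with `time`, `log_amplitude`,
#'   `present`.
#' @export
squeeze_amplitude <- function(filtered_emg, trial_time, window = 1,
                              envelope = NULL, floor_eps = 1e-12) {
  stopifnot(inherits(filtered_emg, "wp_raw_signal"), window > 0)
  t0 <- filtered_emg$start_time
  n <- length(filtered_emg$samples)
  fs <- filtered_emg$fs
  i_lo <- floor((trial_time - window / 2 - t0) * fs) + 1
  i_hi <- ceiling((trial_time + window / 2 - t0) * fs) + 1
  if (i_lo < 1 || i_hi > n) {
    return(structure(list(time = trial_time, log_amplitude = NA_real_,
                          present = FALSE), class = "wp_emg_obs"))
  }
  if (is.null(envelope)) {
    envelope <- hilbert_envelope(filtered_emg$samples)
  } else if (length(envelope) != n) {
    stop("envelope length must match the signal")
  }
  amp <- mean(envelope[i_lo:i_hi])
  structure(list(time = trial_time,
                 log_amplitude = log(max(amp, floor_eps)),
                 present = TRUE),
            class = "wp_emg_obs")
}

#' Extract log squeeze amplitudes for a series of trials
#'
#' Vectorized convenience wrapper around [squeeze_amplitude()]: the envelope
#' is computed once and reused for all trials.
#'
#' @param filtered_emg A filtered EMG `wp_raw_signal`.
#' @param trial_times Numeric vector of trial times (s).
#' @inheritParams squeeze_amplitude
#' @return A data frame with columns `time`, `log_amplitude`, `present`.
#' @export
squeeze_amplitudes <- function(filtered_emg, trial_times, window = 1,
                               floor_eps = 1e-12) {
  env <- hilbert_envelope(filtered_emg$samples)
  obs <- lapply(trial_times, function(tt)
    squeeze_amplitude(filtered_emg, tt, window, envelope = env,
                      floor_eps = floor_eps))
  data.frame(time = vapply(obs, `[[`, numeric(1), "time"),
             log_amplitude = vapply(obs, `[[`, numeric(1), "log_amplitude"),
             present = vapply(obs, `[[`, logical(1), "present"))
}
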
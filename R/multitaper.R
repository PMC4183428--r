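#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the eigenvectors of the standard symmetric tridiagonal
#' matrix whose eigenvectors coincide with the Slepian sequences. Tapers are
#' normalized to unit energy and sign-fixed so each has nonnegative mean
#' (even orders) or positive initial slope (odd orders).
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (e.g. 3).
#' @param k Number of tapers (typically `2 * nw - 1`).
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  n <- as.integer(n); k <- as.integer(k)
  stopifnot(n >= 2L, k >= 1L, nw > 0, k <= n)
  w <- nw / n
  tt <- 0:(n - 1L)
  diag_main <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1L)) * (n - (1:(n - 1L))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1L), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1L))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    if (j %% 2 == 1L) {        # even-order taper: nonnegative mean
      if (sum(v) < 0) v <- -v
    } else {                   # odd-order: positive initial slope
      if (v[2] - v[1] < 0) v <- -v
    }
    tapers[, j] <- v
  }
  tapers
}

#' Multitaper spectrogram of a sampled signal
#'
#' Sliding-window multitaper power spectral density. Defaults follow common
#' sleep-EEG practice: 6-s windows advanced in 0.25-s steps, time-bandwidth
#' product 3, 5 tapers. Each window is demeaned, tapered with each DPSS
#' sequence, and the one-sided eigenspectra are averaged. Power is returned
#' as a density (signal-units^2/Hz) so that the integral over frequency
#' approximates the windowed signal variance.
#'
#' @param raw A `wp_raw_signal`.
#' @param win Window length, seconds.
#' @param step Window step (stride), seconds.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @param demean Subtract the window mean before tapering (default `TRUE`).
#'
#' @return An object of class `wp_spectrogram`: list with `times`
#'   (window-center times, s), `freqs` (Hz), and `power` (matrix, time x
#'   frequency, units^2/Hz).
#' @export
multitaper_spectrogram <- function(raw, win = 6, step = 0.25, nw = 3, k = 5,
                                   demean = TRUE) {
  stopifnot(inherits(raw, "wp_raw_signal"), step > 0, win > 0)
  fs <- raw$fs
  nwin <- round(win * fs)
  if (nwin < 2 * k)
    stop("window too short for the requested number of tapers (need win*fs >= 2*k)")
  x <- raw$samples
  n <- length(x)
  if (nwin > n) nwin <- n  # signal shorter than one window: single window
  nstep <- max(1L, round(step * fs))
  starts <- seq.int(1L, n - nwin + 1L, by = nstep)
  tapers <- dpss_tapers(nwin, nw, k)
  nfreq <- nwin %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / nwin
  onesided <- rep(2, nfreq)
  onesided[1L] <- 1
  if (nwin %% 2L == 0L) onesided[nfreq] <- 1
  power <- matrix(0, length(starts), nfreq)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nwin - 1L)]
    if (demean) seg <- seg - mean(seg)
    acc <- numeric(nfreq)
    for (j in seq_len(k)) {
      sp <- stats::fft(seg * tapers[, j])[seq_len(nfreq)]
      acc <- acc + (Re(sp)^2 + Im(sp)^2)
    }
    power[i, ] <- acc / k * onesided / fs
  }
  times <- raw$start_time + (starts - 1L + (nwin - 1L) / 2) / fs
  structure(list(times = times, freqs = freqs, power = power,
                 df = fs / nwin),
            class = "wp_spectrogram")
}

#' @export
print.wp_spectrogram <- function(x, ...) {
  cat(sprintf("<wp_spectrogram> %d windows x %d frequency bins (0-%.2f Hz, df = %.3f Hz)\n",
              length(x$times), length(x$freqs), max(x$freqs), x$df))
  invisible(x)
}

#' Elementwise median across channel spectrograms
#'
#' Combines several per-channel spectrograms (e.g. the 8 occipital EEG
#' channels) into one robust spectrogram by taking the median power in each
#' (time, frequency) cell.
#'
#' @param specs A list of `wp_spectrogram` objects on identical time and
#'   frequency grids.
#' @return A `wp_spectrogram` of the elementwise medians.
#' @export
median_channel_spectrogram <- function(specs) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  ref <- specs[[1L]]
  stopifnot(inherits(ref, "wp_spectrogram"))
  for (s in specs[-1L]) {
    if (!inherits(s, "wp_spectrogram") ||
        length(s$times) != length(ref$times) ||
        length(s$freqs) != length(ref$freqs) ||
        max(abs(s$times - ref$times)) > 1e-9 ||
        max(abs(s$freqs - ref$freqs)) > 1e-9)
      stop("all spectrograms must share identical time and frequency grids")
  }
  if (length(specs) == 1L) return(ref)
  arr <- vapply(specs, function(s) s$power,
                matrix(0, nrow(ref$power), ncol(ref$power)))
  med <- apply(arr, c(1L, 2L), stats::median)
  out <- ref
  out$power <- med
  out
}

#' Total band power per spectrogram window
#'
#' Sums spectral power over named frequency bands. Band intervals are
#' half-open `[lo, hi)`, so adjacent bands sharing an endpoint (0.5-5, 5-8,
#' 8-12 Hz) partition the spectrum without double counting. Power is
#' integrated (density times bin width), giving units^2 per window.
#'
#' @param spec A `wp_spectrogram`.
#' @param bands Named list of `c(lo, hi)` frequency intervals in Hz. Defaults
#'   to delta 0.5-5, theta 5-8, alpha 8-12.
#' @return An object of class `wp_band_powers`: data frame with `time`, one
#'   column per band, and `present` (all `TRUE`; downstream artifact marking
#'   can clear entries).
#' @export
band_powers <- function(spec,
                        bands = list(delta = c(0.5, 5), theta = c(5, 8),
                                     alpha = c(8, 12))) {
  stopifnot(inherits(spec, "wp_spectrogram"), length(bands) >= 1L,
            !is.null(names(bands)))
  out <- data.frame(time = spec$times)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || b[1] >= b[2]) stop("band '", nm, "' must be c(lo, hi) with lo < hi")
    if (b[1] < min(spec$freqs) - 1e-9 || b[2] > max(spec$freqs) + spec$df + 1e-9)
      stop("band '", nm, "' outside the spectrogram frequency range")
    sel <- spec$freqs >= b[1] - 1e-12 & spec$freqs < b[2] - 1e-12
    if (!any(sel)) stop("band '", nm, "' contains no frequency bins")
    out[[nm]] <- rowSums(spec$power[, sel, drop = FALSE]) * spec$df
  }
  out$present <- TRUE
  class(out) <- c("wp_band_powers", "data.frame")
  out
}
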
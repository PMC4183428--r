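#' Align spectrogram windows to a wake probability curve
#'
#' For each spectrogram window whose center time has a curve point within
#' half the curve's time step, emits one aligned sample: the posterior-median
#' wake probability at that time and the window's spectrum. Windows without a
#' close curve point are dropped.
#'
#' @param spec A `wp_spectrogram`.
#' @param curve A `wp_curve` (from [run_filter()]), or any data frame with
#'   `time` and `p_median`.
#' @param subject_id Subject/night label carried with the samples.
#' @return A list of class `wp_aligned`: `subject`, `p` (one value per kept
#'   window), `spectra` (kept-window x frequency matrix), `freqs`.
#' @export
align_spectra <- function(spec, curve, subject_id = "s1") {
  stopifnot(inherits(spec, "wp_spectrogram"),
            all(c("time", "p_median") %in% names(curve)))
  ct <- curve$time
  if (length(ct) < 2L) stop("curve must have at least two time points")
  tol <- stats::median(diff(ct)) / 2
  if (min(spec$times) > max(ct) + tol || max(spec$times) < min(ct) - tol) {
    warning("no temporal overlap between spectrogram and curve")
    return(structure(list(subject = subject_id, p = numeric(0),
                          spectra = matrix(numeric(0), 0L, length(spec$freqs)),
                          freqs = spec$freqs), class = "wp_aligned"))
  }
  nn <- vapply(spec$times, function(tt) {
    j <- which.min(abs(ct - tt))
    if (abs(ct[j] - tt) <= tol) j else NA_integer_
  }, integer(1))
  keep <- !is.na(nn)
  structure(list(subject = subject_id,
                 p = curve$p_median[nn[keep]],
                 spectra = spec$power[keep, , drop = FALSE],
                 freqs = spec$freqs),
            class = "wp_aligned")
}

#' Construct aligned spectral samples directly
#'
#' Low-level constructor used when the (p, spectrum) pairs come from
#' elsewhere (e.g. simulation).
#'
#' @param p Wake probabilities in `[0, 1]`, one per sample.
#' @param spectra Sample x frequency matrix of nonnegative power.
#' @param freqs Frequency-bin centers (Hz).
#' @param subject Subject label.
#' @return A `wp_aligned` object.
#' @export
aligned_samples <- function(p, spectra, freqs, subject = "s1") {
  spectra <- as.matrix(spectra)
  stopifnot(length(p) == nrow(spectra), length(freqs) == ncol(spectra),
            all(p >= 0 & p <= 1), all(spectra >= 0 | is.na(spectra)))
  structure(list(subject = subject, p = as.numeric(p), spectra = spectra,
                 freqs = as.numeric(freqs)),
            class = "wp_aligned")
}

# pool a list of wp_aligned (or a single one) into p vector + spectra matrix
.pool_aligned <- function(x) {
  if (inherits(x, "wp_aligned")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "wp_aligned")))
  freqs <- x[[1L]]$freqs
  for (a in x) {
    if (length(a$freqs) != length(freqs) || max(abs(a$freqs - freqs)) > 1e-9)
      stop("all aligned sample sets must share one frequency grid")
  }
  list(p = unlist(lapply(x, `[[`, "p")),
       spectra = do.call(rbind, lapply(x, `[[`, "spectra")),
       freqs = freqs)
}

# half-open p bins [lo, lo + w) partitioning [0, 1], last bin closed at 1
.p_bin_index <- function(p, bin_width) {
  nb <- ceiling(1 / bin_width - 1e-9)
  pmin(floor(p / bin_width) + 1L, nb)
}

#' Build a population spectrogram over wake-probability bins
#'
#' Pools aligned (p, spectrum) samples across all subjects and nights, bins
#' them into non-overlapping wake-probability bins of the given width
#' (half-open `[lo, lo + w)`, last bin closed at 1), and takes the median
#' power per (bin, frequency). Empty bins are `NA`, never interpolated.
#'
#' @param samples A `wp_aligned` object or list of them.
#' @param bin_width Wake-probability bin width (default 0.0025, i.e. 400
#'   bins).
#' @return A list of class `wp_popspec`: `p_centers`, `p_edges`, `freqs`,
#'   `phi` (bin x frequency median power), `counts` (samples per bin).
#' @export
build_population_spectrogram <- function(samples, bin_width = 0.0025) {
  stopifnot(bin_width > 0, bin_width <= 1)
  pooled <- .pool_aligned(samples)
  if (length(pooled$p) == 0L) stop("no aligned samples supplied")
  nb <- ceiling(1 / bin_width - 1e-9)
  bin <- .p_bin_index(pooled$p, bin_width)
  nf <- length(pooled$freqs)
  phi <- matrix(NA_real_, nb, nf)
  counts <- integer(nb)
  for (bb in unique(bin)) {
    rows <- which(bin == bb)
    counts[bb] <- length(rows)
    phi[bb, ] <- if (length(rows) == 1L) pooled$spectra[rows, ]
                 else apply(pooled$spectra[rows, , drop = FALSE], 2L, stats::median)
  }
  structure(list(p_centers = (seq_len(nb) - 0.5) * bin_width,
                 p_edges = seq(0, nb) * bin_width,
                 freqs = pooled$freqs, phi = phi, counts = counts,
                 bin_width = bin_width),
            class = "wp_popspec")
}

#' @export
print.wp_popspec <- function(x, ...) {
  cat(sprintf("<wp_popspec> %d Pr(Wake) bins (width %g) x %d frequencies; %d populated bins\n",
              length(x$p_centers), x$bin_width, length(x$freqs),
              sum(x$counts > 0)))
  invisible(x)
}

#' Plot a population spectrogram
#' @param x A `wp_popspec`.
#' @param db Display on a 10*log10 scale (default `TRUE`).
#' @param ... Passed to [graphics::image()].
#' @export
plot.wp_popspec <- function(x, db = TRUE, ...) {
  z <- if (db) 10 * log10(pmax(x$phi, 1e-12)) else x$phi
  graphics::image(x$p_centers, x$freqs, z, xlab = "Pr(Wake)",
                  ylab = "Frequency (Hz)", xlim = c(1, 0), ...)
  invisible(x)
}

#' Bootstrap comparison of two population spectrograms
#'
#' For every (wake-probability bin, frequency) cell populated in both groups,
#' resamples each group's aligned samples with replacement `n_iterations`
#' times, forms the difference of group medians per iteration, and flags the
#' cell significant when zero falls outside the central [2.5, 97.5]
#' percentile interval of the difference distribution. Optionally resamples
#' contiguous blocks of samples (block bootstrap) to acknowledge temporal
#' autocorrelation of spectrogram windows.
#'
#' @param group_a,group_b `wp_aligned` objects or lists of them.
#' @param bin_width Wake-probability bin width.
#' @param n_iterations Bootstrap iterations per bin (default 10000).
#' @param seed Integer seed.
#' @param block_length Resampling block length in samples (1 = ordinary
#'   bootstrap).
#' @return A list of class `wp_popspec_compare`: `p_centers`, `freqs`,
#'   `diff_median` (A - B), `lo`, `hi`, `significant` (logical mask, `NA`
#'   where a bin is empty in either group), `n_iterations`.
#' @export
bootstrap_compare <- function(group_a, group_b, bin_width = 0.0025,
                              n_iterations = 10000L, seed,
                              block_length = 1L) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_iterations >= 100L, block_length >= 1L)
  set.seed(seed)
  a <- .pool_aligned(group_a)
  b <- .pool_aligned(group_b)
  if (length(a$freqs) != length(b$freqs) ||
      max(abs(a$freqs - b$freqs)) > 1e-9)
    stop("groups must share one frequency grid")
  nb <- ceiling(1 / bin_width - 1e-9)
  nf <- length(a$freqs)
  bin_a <- .p_bin_index(a$p, bin_width)
  bin_b <- .p_bin_index(b$p, bin_width)
  diff_med <- matrix(NA_real_, nb, nf)
  lo <- matrix(NA_real_, nb, nf)
  hi <- matrix(NA_real_, nb, nf)
  sig <- matrix(NA, nb, nf)
  for (bb in seq_len(nb)) {
    ra <- which(bin_a == bb)
    rb <- which(bin_b == bb)
    if (length(ra) == 0L || length(rb) == 0L) next
    Sa <- a$spectra[ra, , drop = FALSE]
    Sb <- b$spectra[rb, , drop = FALSE]
    ia <- .boot_indices(length(ra), n_iterations, block_length)
    ib <- .boot_indices(length(rb), n_iterations, block_length)
    for (f in seq_len(nf)) {
      da <- matrix(Sa[, f][ia], n_iterations)
      db_ <- matrix(Sb[, f][ib], n_iterations)
      d <- apply(da, 1L, stats::median) - apply(db_, 1L, stats::median)
      qq <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
      diff_med[bb, f] <- stats::median(Sa[, f]) - stats::median(Sb[, f])
      lo[bb, f] <- qq[1L]
      hi[bb, f] <- qq[2L]
      sig[bb, f] <- qq[1L] > 0 || qq[2L] < 0
    }
  }
  structure(list(p_centers = (seq_len(nb) - 0.5) * bin_width,
                 freqs = a$freqs, diff_median = diff_med, lo = lo, hi = hi,
                 significant = sig, n_iterations = n_iterations,
                 bin_width = bin_width, seed = seed),
            class = "wp_popspec_compare")
}

# n_iter x n matrix of resampling indices; block_length > 1 draws circular
# contiguous blocks
.boot_indices <- function(n, n_iter, block_length) {
  if (block_length <= 1L || n <= block_length) {
    matrix(sample.int(n, n * n_iter, replace = TRUE), n_iter, n)
  } else {
    nblk <- ceiling(n / block_length)
    starts <- matrix(sample.int(n, nblk * n_iter, replace = TRUE), n_iter, nblk)
    idx <- matrix(0L, n_iter, nblk * block_length)
    for (j in seq_len(block_length)) {
      idx[, seq.int(j, by = block_length, length.out = nblk)] <-
        (starts + j - 2L) %% n + 1L
    }
    idx[, seq_len(n), drop = FALSE]
  }
}

#' @export
print.wp_popspec_compare <- function(x, ...) {
  comp <- !is.na(x$significant)
  cat(sprintf("<wp_popspec_compare> %d comparable cells, %d significant (%.1f%%), %d iterations\n",
              sum(comp), sum(x$significant[comp]),
              100 * mean(x$significant[comp]), x$n_iterations))
  invisible(x)
}
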
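test_that("EMG filtering is zero-phase, linear, and rejects the mains tone", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  sig30 <- raw_signal(sin(2 * pi * 30 * t), fs, "EMG")
  sig60 <- raw_signal(sin(2 * pi * 60 * t), fs, "EMG")

  # passband tone survives with little loss and no phase shift
  y30 <- filter_emg(sig30)
  mid <- 2000:3000
  expect_gt(stats::cor(y30$samples[mid], sig30$samples[mid]), 0.999)
  expect_gt(sqrt(mean(y30$samples[mid]^2)), 0.9 * sqrt(0.5))

  # mains tone is rejected: output RMS under 1% of input RMS
  y60 <- filter_emg(sig60)
  expect_lt(sqrt(mean(y60$samples^2)), 0.01 * sqrt(mean(sig60$samples^2)))

  # constant-zero input stays zero; linearity to numerical tolerance
  z <- filter_emg(raw_signal(rep(0, length(t)), fs))
  expect_equal(z$samples, rep(0, length(t)))
  set.seed(11)
  x1 <- raw_signal(rnorm(length(t)), fs)
  x2 <- raw_signal(rnorm(length(t)), fs)
  combo <- raw_signal(2 * x1$samples - 3 * x2$samples, fs)
  expect_equal(filter_emg(combo)$samples,
               2 * filter_emg(x1)$samples - 3 * filter_emg(x2)$samples,
               tolerance = 1e-8)

  # configuration errors
  expect_error(filter_emg(raw_signal(rnorm(100), fs = 100)), "too low")
  expect_error(filter_emg(sig30, low = 80, high = 70), "low < high")
})

test_that("squeeze amplitude is the log mean Hilbert envelope in a centered window", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  carrier <- raw_signal(sin(2 * pi * 30 * t), fs, "EMG")

  # unit-amplitude carrier: envelope ~ 1, log amplitude ~ 0
  obs <- squeeze_amplitude(carrier, trial_time = 5, window = 1)
  expect_true(obs$present)
  expect_equal(obs$log_amplitude, 0, tolerance = 1e-3)

  # amplitude-modulated carrier recovers the local amplitude
  am <- raw_signal(3 * sin(2 * pi * 30 * t), fs)
  expect_equal(squeeze_amplitude(am, 5, 1)$log_amplitude, log(3),
               tolerance = 1e-3)

  # window off the edge of the recording: missing, not an error
  edge <- squeeze_amplitude(carrier, trial_time = 0.2, window = 1)
  expect_false(edge$present)
  expect_true(is.na(edge$log_amplitude))

  # vectorized extraction agrees with scalar calls
  many <- squeeze_amplitudes(carrier, c(0.1, 2, 5, 9.99))
  expect_equal(many$present, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(many$log_amplitude[3],
               squeeze_amplitude(carrier, 5, 1)$log_amplitude)

  # zero signal is floored, not -Inf
  silent <- raw_signal(rep(0, length(t)), fs)
  expect_equal(squeeze_amplitude(silent, 5, 1)$log_amplitude, log(1e-12))
})

test_that("multitaper spectrogram satisfies Parseval and localizes tones", {
  fs <- 100
  set.seed(21)
  sigma <- 1.7
  wn <- raw_signal(rnorm(30 * fs, sd = sigma), fs)
  sp <- multitaper_spectrogram(wn)
  expect_s3_class(sp, "wp_spectrogram")
  expect_true(all(sp$power >= 0))
  expect_true(all(diff(sp$times) > 0) && all(diff(sp$freqs) > 0))
  # window centers advance by the step
  expect_equal(diff(sp$times)[1], 0.25, tolerance = 1e-9)
  # Parseval: integrated power per window ~ signal variance, within 10%
  tot <- rowSums(sp$power) * sp$df
  expect_equal(mean(tot), sigma^2, tolerance = 0.1)

  # a 10 Hz tone concentrates in the alpha band
  tone <- raw_signal(sin(2 * pi * 10 * seq(0, 30, by = 1 / fs)), fs)
  bp <- band_powers(multitaper_spectrogram(tone))
  expect_gt(mean(bp$alpha / (bp$delta + bp$theta + bp$alpha)), 0.95)

  # zero signal: all-zero power
  zp <- multitaper_spectrogram(raw_signal(rep(0, 10 * fs), fs))
  expect_true(all(zp$power == 0))

  # signal shorter than one window: single-window spectrogram
  short <- multitaper_spectrogram(raw_signal(rnorm(3 * fs), fs), win = 6)
  expect_equal(nrow(short$power), 1L)
})

test_that("DPSS tapers are orthonormal and match their defining bandwidth ordering", {
  tp <- dpss_tapers(256, nw = 3, k = 5)
  gram <- crossprod(tp)
  expect_equal(gram, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  # first taper is bell-shaped and positive
  expect_true(all(tp[, 1] > 0))
  # energy concentration decreases with taper order
  conc <- apply(tp, 2, function(v) {
    sp <- Mod(stats::fft(c(v, rep(0, 768))))^2
    inband <- sum(sp[c(1:13, 1013:1024)]) # |f| <= 3/256 cycles/sample
    inband / sum(sp)
  })
  expect_gt(conc[1], 0.9999)
  expect_true(all(diff(conc) < 0))
})

test_that("median across channel spectrograms is robust to an outlier channel", {
  fs <- 100
  set.seed(31)
  base <- raw_signal(rnorm(10 * fs), fs)
  specs <- lapply(1:8, function(i) multitaper_spectrogram(base))
  # channel 8 has 10x power at every bin
  specs[[8]]$power <- specs[[8]]$power * 10
  med <- median_channel_spectrogram(specs)
  # sorted-middle oracle per cell
  arr <- vapply(specs, function(s) s$power,
                matrix(0, nrow(base <- specs[[1]]$power), ncol(specs[[1]]$power)))
  oracle <- apply(arr, c(1, 2), function(v) mean(sort(v)[4:5]))
  expect_equal(med$power, oracle, tolerance = 1e-12)
  # identical to the uncontaminated channel (median of 7 equal + 1 outlier)
  expect_equal(med$power, specs[[1]]$power, tolerance = 1e-12)

  # single channel: identity; identical channels: identity
  expect_equal(median_channel_spectrogram(specs[1])$power, specs[[1]]$power)
  expect_equal(median_channel_spectrogram(specs[c(1, 1, 1)])$power,
               specs[[1]]$power)

  # mismatched grids rejected
  other <- multitaper_spectrogram(raw_signal(rnorm(8 * fs), fs))
  expect_error(median_channel_spectrogram(list(specs[[1]], other)),
               "identical time and frequency grids")
})

test_that("band powers use half-open intervals that partition the spectrum", {
  fs <- 100
  set.seed(41)
  sp <- multitaper_spectrogram(raw_signal(rnorm(20 * fs), fs))
  bp <- band_powers(sp)
  # partition: delta + theta + alpha == total power in [0.5, 12) exactly
  sel <- sp$freqs >= 0.5 & sp$freqs < 12
  total <- rowSums(sp$power[, sel, drop = FALSE]) * sp$df
  expect_equal(bp$delta + bp$theta + bp$alpha, total, tolerance = 1e-12)
  # 5 Hz bin belongs to theta only
  bin5 <- band_powers(sp, bands = list(onebin = c(5, 5 + sp$df)))
  expect_equal(bp$theta,
               band_powers(sp, bands = list(th = c(5, 8)))$th)
  expect_true(all(bin5$onebin <= bp$theta + 1e-12))

  expect_error(band_powers(sp, bands = list(bad = c(4.05, 4.1))), "no frequency bins")
  expect_error(band_powers(sp, bands = list(bad = c(40, 60))), "outside")

  # zero spectrogram: zero in every band
  zsp <- sp; zsp$power[] <- 0
  zbp <- band_powers(zsp)
  expect_true(all(zbp$delta == 0 & zbp$theta == 0 & zbp$alpha == 0))
})

test_that("trial scoring marks correct, incorrect and artifact-masked breaths", {
  inh <- c(5, 10, 15, 20, 25)
  sq <- list(c(9.5, 10.5), c(18, 19.2), c(24.9, 25.3))
  art <- list(c(14, 16))
  tr <- score_trials(inh, sq, art)
  expect_s3_class(tr, "wp_trials")
  expect_equal(nrow(tr), length(inh))
  # t=10: overlapping squeeze -> correct; t=5: none -> incorrect
  # t=15: artifact -> missing; t=20: squeeze [18,19.2] within half-breath
  # window (2.5 s) -> correct; t=25 -> correct
  expect_equal(tr$response, c(0L, 1L, NA_integer_, 1L, 1L))

  # empty inputs
  expect_equal(nrow(score_trials(numeric(0))), 0L)
  # explicit alignment window overrides the local-breath default
  tight <- score_trials(inh, sq, half_breath = 0.25)
  expect_equal(tight$response[4], 0L)
  expect_error(score_trials(inh, list(c(3, 2))), "start < end")
  expect_error(score_trials(c(2, 1)), "sorted")
})

test_that("scoring window starts at 3 consecutive correct and stops 10 min after last correct", {
  # start rule: first run of >= 3 correct
  times <- seq(0, by = 4, length.out = 200)
  resp <- rep(0L, 200)
  resp[2:4] <- 1L            # run of 3 starting at trial 2
  resp[50] <- 1L             # last correct at t = 196 s
  tr <- breath_trials(times, resp)
  win <- scoring_window(tr, lights_out = 0)
  expect_equal(win$time[1], times[2])
  # stop rule: last correct + 600 s
  expect_true(all(win$time <= times[50] + 600))
  expect_equal(max(win$time), max(times[times <= times[50] + 600]))
  # trimming preserves order and labels
  expect_equal(win$response,
               resp[seq(2, length.out = nrow(win))])

  # exact stop-rule example: last correct at t = 600 -> window ends at 1200
  t2 <- seq(0, by = 100, length.out = 15)
  r2 <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L, rep(0L, 8))  # last correct at t = 600
  w2 <- scoring_window(breath_trials(t2, r2))
  expect_equal(max(w2$time), 1200)

  # an interrupted run does not start the window
  r3 <- c(0L, 1L, 1L, 0L, 1L, 1L, 1L, 0L)
  w3 <- scoring_window(breath_trials(seq_along(r3), r3))
  expect_equal(w3$time[1], 5)

  # all incorrect: empty output with a warning
  expect_warning(w4 <- scoring_window(breath_trials(1:5, rep(0L, 5))),
                 "no run")
  expect_equal(nrow(w4), 0L)
})
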
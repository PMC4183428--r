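#' Read a sampled signal from CSV
#'
#' Two-column CSV `time_s,value` with a declared sampling rate. The times are
#' checked for consistency with `fs`.
#'
#' @param path CSV file path.
#' @param fs Sampling rate (Hz).
#' @param label Channel label to attach.
#' @return A [raw_signal()].
#' @export
read_signal_csv <- function(path, fs, label = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("signal CSV must have columns time_s,value (", path, ")")
  if (nrow(d) > 1L) {
    dts <- diff(d$time_s)
    if (max(abs(dts - 1 / fs)) > 0.01 / fs)
      stop("time_s spacing inconsistent with fs = ", fs, " Hz in ", path)
  }
  raw_signal(d$value, fs = fs, label = label, start_time = d$time_s[1L])
}

#' Write a sampled signal to CSV
#' @param x A `wp_raw_signal`.
#' @param path Output path.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "wp_raw_signal"))
  utils::write.csv(data.frame(time_s = signal_times(x), value = x$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read signals from an EDF or CSV file
#'
#' Dispatches on the file extension: `.edf` uses the built-in EDF reader,
#' anything else is read as a two-column signal CSV (`fs` then required).
#'
#' @param path File path.
#' @param channel_labels For EDF, the channel labels to extract (all when
#'   `NULL`).
#' @param fs Sampling rate for CSV input.
#' @return A list of [raw_signal()] objects.
#' @export
read_signals <- function(path, channel_labels = NULL, fs = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    return(read_edf(path, channel_labels))
  if (is.null(fs)) stop("fs must be supplied for CSV signal input")
  list(read_signal_csv(path, fs))
}

#' Read breath trials from CSV
#'
#' Schema `time_s,response` with response in `{1, 0, NA}`.
#'
#' @param path CSV path.
#' @return A [breath_trials()] data frame.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "response") %in% names(d)))
    stop("trials CSV must have columns time_s,response (", path, ")")
  bad <- which(!d$response %in% c(0, 1) & !is.na(d$response))
  if (length(bad))
    stop("invalid response value in column 'response', row ", bad[1L],
         " of ", path)
  breath_trials(d$time_s, d$response)
}

#' Write breath trials to CSV
#' @param trials A `wp_trials` data frame.
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "wp_trials"))
  utils::write.csv(data.frame(time_s = trials$time, response = trials$response),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' Schema `epoch_index,stage` with stages in `{W, N1, N2, N3, R}`.
#'
#' @param path CSV path.
#' @param epoch_length Epoch length in seconds.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_length = 30) {
  d <- utils::read.csv(path)
  if (!all(c("epoch_index", "stage") %in% names(d)))
    stop("hypnogram CSV must have columns epoch_index,stage (", path, ")")
  bad <- which(!d$stage %in% c("W", "N1", "N2", "N3", "R"))
  if (length(bad))
    stop("invalid stage code in column 'stage', row ", bad[1L], " of ", path)
  d <- d[order(d$epoch_index), ]
  hypnogram(d$stage, epoch_length)
}

#' Write a hypnogram to CSV
#' @param h A `wp_hypnogram`.
#' @param path Output path.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "wp_hypnogram"))
  utils::write.csv(data.frame(epoch_index = h$epoch, stage = h$stage),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a wake probability curve to CSV
#' @param curve A `wp_curve` (columns `time`, `p_lo`, `p_median`, `p_hi`).
#' @param path Output path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(all(c("time", "p_lo", "p_median", "p_hi") %in% names(curve)))
  utils::write.csv(data.frame(time_s = curve$time, p_lo = curve$p_lo,
                              p_median = curve$p_median, p_hi = curve$p_hi),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a wake probability curve from CSV
#' @param path CSV path with columns `time_s,p_lo,p_median,p_hi`.
#' @return A `wp_curve` data frame.
#' @export
read_curve <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "p_lo", "p_median", "p_hi")
  if (!all(need %in% names(d)))
    stop("curve CSV must have columns ", paste(need, collapse = ","),
         " (", path, ")")
  out <- data.frame(time = d$time_s, p_lo = d$p_lo, p_median = d$p_median,
                    p_hi = d$p_hi)
  bad <- which(!(out$p_lo <= out$p_median & out$p_median <= out$p_hi))
  if (length(bad))
    stop("curve quantile ordering violated at row ", bad[1L], " of ", path)
  class(out) <- c("wp_curve", "data.frame")
  out
}

#' Write band powers to CSV
#' @param bp A `wp_band_powers` data frame.
#' @param path Output path.
#' @export
write_band_powers <- function(bp, path) {
  stopifnot(inherits(bp, "wp_band_powers"))
  d <- as.data.frame(bp)
  names(d)[names(d) == "time"] <- "time_s"
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read band powers from CSV
#' @param path CSV with columns `time_s`, band columns, `present`.
#' @return A `wp_band_powers` data frame.
#' @export
read_band_powers <- function(path) {
  d <- utils::read.csv(path)
  if (!"time_s" %in% names(d))
    stop("band-power CSV must have a time_s column (", path, ")")
  names(d)[names(d) == "time_s"] <- "time"
  if (!"present" %in% names(d)) d$present <- TRUE
  class(d) <- c("wp_band_powers", "data.frame")
  d
}

#' Write an observation grid to CSV
#' @param grid A `wp_obs_grid`.
#' @param path Output path.
#' @export
write_observation_grid <- function(grid, path) {
  stopifnot(inherits(grid, "wp_obs_grid"))
  utils::write.csv(data.frame(time_s = grid$time, b = grid$b, m = grid$m,
                              y_alpha = grid$y_alpha, y_dt = grid$y_dt),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an observation grid from CSV
#' @param path CSV with columns `time_s,b,m,y_alpha,y_dt` (NA = missing).
#' @return A [observation_grid()].
#' @export
read_observation_grid <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "b", "m", "y_alpha", "y_dt")
  if (!all(need %in% names(d)))
    stop("observation-grid CSV must have columns ",
         paste(need, collapse = ","), " (", path, ")")
  observation_grid(d$time_s, b = d$b, m = d$m, y_alpha = d$y_alpha,
                   y_dt = d$y_dt)
}

#' Echo a run configuration to JSON
#'
#' Writes the configuration, seed and input file names to `config.json` in
#' the output directory so any run can be reproduced bit-exactly.
#'
#' @param config A [wp_config()] or plain list.
#' @param seed The run seed.
#' @param inputs Named character vector/list of input file paths.
#' @param out_dir Output directory (created if needed).
#' @return The path of the written JSON, invisibly.
#' @export
write_config_echo <- function(config, seed, inputs = list(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "config.json")
  payload <- list(package = "wakeprob",
                  version = as.character(utils::packageVersion("wakeprob")),
                  seed = seed, inputs = inputs,
                  config = unclass(config),
                  written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
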
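# Minimal EDF (European Data Format) support: fixed-layout ASCII header plus
# little-endian 16-bit samples, enough to ingest standard PSG exports. Only
# continuous recordings with one sampling rate per channel are handled.

.edf_field <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read channels from an EDF file
#'
#' Parses the EDF header and returns the requested channels as
#' [raw_signal()] objects, converting digital to physical units with each
#' channel's calibration. Unknown labels are reported together with the
#' available ones.
#'
#' @param path EDF file path.
#' @param channel_labels Labels to extract (`NULL` = all channels).
#' @return A list of `wp_raw_signal` objects.
#' @export
read_edf <- function(path, channel_labels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  .edf_field(con, 8L)                      # version
  .edf_field(con, 80L); .edf_field(con, 80L)  # patient, recording ids
  .edf_field(con, 8L); .edf_field(con, 8L)    # start date, time
  header_bytes <- suppressWarnings(as.integer(.edf_field(con, 8L)))
  .edf_field(con, 44L)                     # reserved
  n_records <- suppressWarnings(as.integer(.edf_field(con, 8L)))
  record_dur <- suppressWarnings(as.numeric(.edf_field(con, 8L)))
  ns <- suppressWarnings(as.integer(.edf_field(con, 4L)))
  if (is.na(ns) || ns < 1L || is.na(n_records) || is.na(header_bytes))
    stop("malformed EDF header in ", path, " (byte offset < 256)")
  labels <- vapply(seq_len(ns), function(i) .edf_field(con, 16L), character(1))
  for (i in seq_len(ns)) .edf_field(con, 80L)   # transducer
  for (i in seq_len(ns)) .edf_field(con, 8L)    # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8L)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8L)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8L)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8L)), numeric(1))
  for (i in seq_len(ns)) .edf_field(con, 80L)   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(.edf_field(con, 8L)), integer(1))
  for (i in seq_len(ns)) .edf_field(con, 32L)   # reserved
  if (any(is.na(spr)) || any(is.na(phys_min)))
    stop("malformed EDF signal headers in ", path,
         " (byte offset < ", 256L + 256L * ns, ")")
  want <- if (is.null(channel_labels)) labels else channel_labels
  missing_ch <- setdiff(want, labels)
  if (length(missing_ch))
    stop("channel(s) not in EDF: ", paste(missing_ch, collapse = ", "),
         "; available: ", paste(labels, collapse = ", "))
  seek(con, header_bytes)
  store <- lapply(spr, function(k) matrix(0L, k, n_records))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      store[[i]][, r] <- readBin(con, "integer", n = spr[i], size = 2L,
                                 signed = TRUE, endian = "little")
    }
  }
  out <- lapply(match(want, labels), function(i) {
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys <- phys_min[i] + (as.numeric(store[[i]]) - dig_min[i]) * gain
    raw_signal(phys, fs = spr[i] / record_dur, label = labels[i])
  })
  names(out) <- want
  out
}

#' Write signals to a minimal EDF file
#'
#' Writes continuous channels (all sharing one duration) as an EDF file with
#' 1-second data records, quantizing to the 16-bit digital range. Intended
#' for round-trip tests and for exporting synthetic recordings; values are
#' preserved to the EDF recording precision (the physical range divided by
#' 2^16).
#'
#' @param signals List of `wp_raw_signal` objects; each channel's sampling
#'   rate must be an integer (samples per 1-s record).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path) {
  stopifnot(is.list(signals), length(signals) >= 1L)
  ns <- length(signals)
  spr <- vapply(signals, function(s) {
    if (abs(s$fs - round(s$fs)) > 1e-9) stop("EDF writer needs integer Hz sampling rates")
    as.integer(round(s$fs))
  }, integer(1))
  n_records <- min(vapply(seq_len(ns), function(i)
    length(signals[[i]]$samples) %/% spr[i], integer(1)))
  if (n_records < 1L) stop("signals shorter than one 1-s record")
  pad <- function(x, n) formatC(substr(x, 1L, n), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  header_bytes <- 256L + 256L * ns
  writeChar(paste0(pad("0", 8L), pad("synthetic subject", 80L),
                   pad("synthetic recording", 80L), pad("01.01.26", 8L),
                   pad("00.00.00", 8L), pad(as.character(header_bytes), 8L),
                   pad("", 44L), pad(as.character(n_records), 8L),
                   pad("1", 8L), pad(as.character(ns), 4L)),
            con, eos = NULL)
  pmin_ <- numeric(ns); pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    rng <- range(signals[[i]]$samples, finite = TRUE)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    pmin_[i] <- rng[1L]; pmax_[i] <- rng[2L]
  }
  fields <- function(vals, width) paste(vapply(vals, pad, character(1), width),
                                        collapse = "")
  writeChar(paste0(
    fields(vapply(signals, `[[`, character(1), "label"), 16L),
    fields(rep("", ns), 80L),
    fields(rep("uV", ns), 8L),
    fields(formatC(pmin_, format = "g", digits = 6), 8L),
    fields(formatC(pmax_, format = "g", digits = 6), 8L),
    fields(rep("-32768", ns), 8L),
    fields(rep("32767", ns), 8L),
    fields(rep("", ns), 80L),
    fields(as.character(spr), 8L),
    fields(rep("", ns), 32L)), con, eos = NULL)
  # re-read the printed physical ranges so digital quantization is exact
  pmin_r <- as.numeric(formatC(pmin_, format = "g", digits = 6))
  pmax_r <- as.numeric(formatC(pmax_, format = "g", digits = 6))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- signals[[i]]$samples[((r - 1L) * spr[i] + 1L):(r * spr[i])]
      dig <- round((seg - pmin_r[i]) / (pmax_r[i] - pmin_r[i]) * 65535) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
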
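#' Multichannel session recording
#'
#' Container for one recording session: a channels x samples voltage matrix
#' with its sampling rate, start time, per-channel electrode impedances
#' (measured at 1 kHz) and the array geometry.
#'
#' @param signals channels x samples numeric matrix, microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param layout an [ecog_layout()] whose channel count matches `nrow(signals)`.
#' @param impedances per-channel impedance in megohms (>= 0). Default 0.5.
#' @param t0 session start time in seconds. Default 0.
#' @param channel_mask logical inclusion flag per channel. Default all `TRUE`.
#'
#' @return an object of class `ecog_session`.
#' @export
ecog_session <- function(signals, fs, layout,
                         impedances = rep(0.5, nrow(signals)),
                         t0 = 0, channel_mask = rep(TRUE, nrow(signals))) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stopf("signals must be a numeric channels x samples matrix")
  n_ch <- nrow(signals)
  if (!inherits(layout, "ecog_layout"))
    stopf("layout must be an ecog_layout")
  if (length(layout$channel_ids) != n_ch)
    stopf("layout has %d channels but signals has %d rows",
          length(layout$channel_ids), n_ch)
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be a positive rate")
  if (length(impedances) != n_ch || any(impedances < 0))
    stopf("impedances must be %d non-negative values", n_ch)
  if (length(channel_mask) != n_ch || !is.logical(channel_mask))
    stopf("channel_mask must be %d logical flags", n_ch)

  structure(
    list(signals = signals, fs = fs, t0 = t0,
         impedances = as.numeric(impedances), layout = layout,
         channel_mask = channel_mask),
    class = "ecog_session"
  )
}

#' @export
print.ecog_session <- function(x, ...) {
  cat(sprintf(
    "ecog_session: %d channels x %d samples @ %g Hz (%.4g s), %d channels masked out\n",
    nrow(x$signals), ncol(x$signals), x$fs, ncol(x$signals) / x$fs,
    sum(!x$channel_mask)))
  invisible(x)
}

session_duration <- function(session) ncol(session$signals) / session$fs

.ECOG_MAGIC <- "ECOGSESS"
.ECOG_SCHEMA_VERSION <- 1L

#' Write / read a session container
#'
#' Single-file binary container: an 8-byte magic string, an integer schema
#' version, a length-prefixed JSON header (geometry, sampling rate, start
#' time, impedances, channel mask, matrix dimensions) and a float64 signal
#' block in column-major order. Round-trips are bit-exact for the signal
#' matrix and lossless for all metadata.
#'
#' @param session an [ecog_session()].
#' @param path file path to write to / read from.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the reconstructed [ecog_session()].
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ecog_session"))
  con <- file(path, "wb")
  on.exit(close(con))
  lay <- session$layout
  header <- jsonlite::toJSON(list(
    n_rows = lay$n_rows, n_cols = lay$n_cols,
    pitch_um = lay$pitch_mm * 1000, diameter_um = lay$diameter_mm * 1000,
    fs = session$fs, t0 = session$t0,
    impedances = session$impedances,
    channel_mask = session$channel_mask,
    n_channels = nrow(session$signals), n_samples = ncol(session$signals)
  ), auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  writeBin(charToRaw(.ECOG_MAGIC), con)
  writeBin(.ECOG_SCHEMA_VERSION, con, size = 4L, endian = "little")
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(session$signals), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stopf("session file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 8L))
  if (!identical(magic, .ECOG_MAGIC))
    stopf("not a session container (bad magic): %s", path)
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!identical(version, .ECOG_SCHEMA_VERSION))
    stopf("unsupported session schema version %s (expected %d): %s",
          version, .ECOG_SCHEMA_VERSION, path)
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L)
    stopf("corrupt session container (bad header length): %s", path)
  hraw <- readBin(con, "raw", n = hlen)
  if (length(hraw) < hlen)
    stopf("corrupt session container (truncated header): %s", path)
  h <- jsonlite::fromJSON(rawToChar(hraw))
  n_vals <- h$n_channels * h$n_samples
  sig <- readBin(con, "double", n = n_vals, size = 8L, endian = "little")
  if (length(sig) < n_vals)
    stopf("corrupt session container (truncated signal block, %d of %d values): %s",
          length(sig), n_vals, path)
  signals <- matrix(sig, nrow = h$n_channels, ncol = h$n_samples)
  layout <- ecog_layout(h$n_rows, h$n_cols, h$pitch_um, h$diameter_um)
  ecog_session(signals, fs = as.numeric(h$fs), layout = layout,
               impedances = as.numeric(h$impedances), t0 = as.numeric(h$t0),
               channel_mask = as.logical(h$channel_mask))
}
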
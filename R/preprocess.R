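#' Impedance-based channel exclusion
#'
#' Channels with impedance above the threshold (1 Mohm at 1 kHz by default)
#' are flagged for exclusion. The signal matrix is left untouched; the mask
#' governs all downstream stages.
#'
#' @param session an [ecog_session()].
#' @param threshold_mohm exclusion threshold in Mohm.
#' @return logical vector, `TRUE` for retained channels.
#' @export
exclude_high_impedance <- function(session, threshold_mohm = 1) {
  stopifnot(inherits(session, "ecog_session"))
  mask <- session$impedances <= threshold_mohm
  if (!any(mask))
    warnf("all %d channels exceed %g Mohm; retained set is empty",
          length(mask), threshold_mohm)
  mask
}

# RBJ biquad notch at f0 with quality factor Q
biquad_notch <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1L], a = a / a[1L])
}

#' Mains notch filtering
#'
#' Cascaded second-order IIR notches (Q = 30) at the mains fundamental and
#' its harmonics, applied forward-backward for zero phase. Attenuation at
#' each notch frequency exceeds 40 dB while the passband outside +/- 2 Hz of
#' the notches stays within 1 dB.
#'
#' @param signals channels x samples matrix (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param base_hz mains fundamental (Hz).
#' @param n_harmonics number of notched harmonics, fundamental included;
#'   `base_hz * n_harmonics` must stay below the Nyquist rate.
#' @return filtered matrix of the same shape.
#' @export
notch_filter <- function(signals, fs, base_hz = 50, n_harmonics = 4L) {
  vec <- is.null(dim(signals))
  if (vec) signals <- matrix(signals, nrow = 1L)
  freqs <- base_hz * seq_len(n_harmonics)
  if (any(freqs >= fs / 2))
    stopf("notch harmonic %g Hz is at or above the Nyquist rate %g Hz",
          max(freqs), fs / 2)
  filters <- lapply(freqs, biquad_notch, fs = fs)
  # narrow notches ring for ~Q cycles; reflect-pad generously
  npad <- min(ncol(signals) - 1L, round(2 * fs))
  out <- signals
  blocks <- split(seq_len(nrow(out)), ceiling(seq_len(nrow(out)) / 64))
  for (bl in blocks)
    out[bl, ] <- t(filtfilt_mat(filters, t(out[bl, , drop = FALSE]), npad = npad))
  if (vec) out[1L, ] else out
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over the retained channels from each
#' retained channel; excluded channels pass through unreferenced (they stay
#' excluded downstream). Requires at least two retained channels.
#'
#' @param signals channels x samples matrix.
#' @param mask logical retained-channel flags (default: all).
#' @return re-referenced matrix of the same shape.
#' @export
common_average_reference <- function(signals, mask = rep(TRUE, nrow(signals))) {
  if (sum(mask) < 2L) stopf("common average reference needs >= 2 retained channels")
  ref <- colMeans(signals[mask, , drop = FALSE])
  signals[mask, ] <- sweep(signals[mask, , drop = FALSE], 2L, ref)
  signals
}

#' Anti-aliased downsampling
#'
#' Zero-phase 8th-order Butterworth low-pass at 90% of the output Nyquist
#' rate, then resampling onto the output grid (pure decimation for integer
#' rate ratios). Output length is `round(n * fs_out / fs_in)`. Upsampling is
#' not supported.
#'
#' @param signals channels x samples matrix (or vector).
#' @param fs_in,fs_out input and output rates in Hz, `fs_out <= fs_in`.
#' @return resampled matrix (or vector).
#' @export
resample_to <- function(signals, fs_in, fs_out) {
  if (fs_out > fs_in) stopf("no upsampling path: fs_out %g > fs_in %g", fs_out, fs_in)
  if (fs_out == fs_in) return(signals)
  vec <- is.null(dim(signals))
  if (vec) signals <- matrix(signals, nrow = 1L)
  n <- ncol(signals)
  n_out <- round(n * fs_out / fs_in)
  lp <- signal::butter(8, 0.9 * fs_out / fs_in, type = "low")
  t_in <- (seq_len(n) - 1L) / fs_in
  t_out <- (seq_len(n_out) - 1L) / fs_out
  out <- matrix(0, nrow(signals), n_out)
  ratio <- fs_in / fs_out
  integer_ratio <- abs(ratio - round(ratio)) < 1e-9
  blocks <- split(seq_len(nrow(signals)), ceiling(seq_len(nrow(signals)) / 64))
  for (bl in blocks) {
    X <- filtfilt_mat(lp, t(signals[bl, , drop = FALSE]))
    out[bl, ] <- t(if (integer_ratio)
      X[seq(1L, by = round(ratio), length.out = n_out), , drop = FALSE]
    else apply(X, 2L, function(x) stats::approx(t_in, x, xout = t_out, rule = 2)$y))
  }
  if (vec) out[1L, ] else out
}

#' Binned high-gamma band power features
#'
#' Splits each channel into consecutive `bin_ms` segments (a trailing partial
#' bin is dropped), computes a Hann-windowed periodogram per bin, and takes
#' the mean power spectral density over the frequency bins whose centre lies
#' inside the band (endpoints inclusive). With the defaults — 100 ms bins at
#' 500 Hz — each periodogram has 10 Hz resolution and the 70-150 Hz band
#' averages 9 frequency bins.
#'
#' @param signals channels x samples matrix (or vector).
#' @param fs sampling rate in Hz.
#' @param bin_ms bin duration in milliseconds; each bin must hold >= 8
#'   samples.
#' @param band `(low, high)` band in Hz, inside `(0, fs/2)`.
#' @param t0 session start time (s), used for bin timestamps.
#' @param channel_ids channel identifiers for the columns.
#' @return object of class `ecog_features` with `values` (bins x channels,
#'   raw band power), `bin_s`, `band`, `channel_ids`, `bin_time` (right-edge
#'   timestamps) and `zscored = FALSE`.
#' @export
extract_hg_features <- function(signals, fs, bin_ms = 100, band = c(70, 150),
                                t0 = 0, channel_ids = NULL) {
  vec <- is.null(dim(signals))
  if (vec) signals <- matrix(signals, nrow = 1L)
  if (band[1L] <= 0 || band[2L] >= fs / 2)
    stopf("band [%g, %g] Hz must lie inside (0, %g) Hz", band[1L], band[2L], fs / 2)
  L <- round(fs * bin_ms / 1000)
  if (L < 8L) stopf("bin of %g ms holds only %d samples at %g Hz (>= 8 required)",
                    bin_ms, L, fs)
  n_bins <- floor(ncol(signals) / L)
  if (n_bins < 1L) stopf("signal shorter than one bin")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann window
  scale <- 1 / (fs * sum(w^2))
  freqs <- (seq_len(L) - 1L) * fs / L
  half <- seq_len(floor(L / 2) + 1L)
  in_band <- half[freqs[half] >= band[1L] & freqs[half] <= band[2L]]
  if (length(in_band) == 0L) stopf("no periodogram frequency falls in the band")
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(signals))

  values <- matrix(0, n_bins, nrow(signals))
  for (c in seq_len(nrow(signals))) {
    seg <- matrix(signals[c, seq_len(n_bins * L)], nrow = L) * w
    pgram <- abs(stats::mvfft(seg))^2 * scale     # L x n_bins periodogram
    values[, c] <- colMeans(pgram[in_band, , drop = FALSE])
  }
  structure(
    list(values = values, bin_s = bin_ms / 1000, band = band,
         channel_ids = channel_ids,
         bin_time = t0 + seq_len(n_bins) * (bin_ms / 1000),
         norm_mean = NULL, norm_std = NULL, zero_variance = logical(ncol(values)),
         zscored = FALSE),
    class = "ecog_features"
  )
}

#' @export
print.ecog_features <- function(x, ...) {
  cat(sprintf("ecog_features: %d bins x %d channels, %g ms bins, %g-%g Hz band%s\n",
              nrow(x$values), ncol(x$values), x$bin_s * 1000,
              x$band[1L], x$band[2L],
              if (x$zscored) " (z-scored)" else " (raw)"))
  invisible(x)
}

#' Z-score features on training statistics
#'
#' Per-channel mean and standard deviation are computed on the training bin
#' range only and applied to every bin, preventing leakage into the held-out
#' evaluation segment. Channels with zero training variance are set to zero
#' and flagged. Stored statistics can be re-applied to a later session
#' (cross-session recalibration) via `stats_from`.
#'
#' @param features an `ecog_features` (raw).
#' @param train_range integer bin indices of the training segment.
#' @param stats_from optional previously z-scored `ecog_features` whose
#'   `norm_mean` / `norm_std` are reused instead of refitting.
#' @return the z-scored `ecog_features` with `norm_mean`, `norm_std` and
#'   `zero_variance` filled in.
#' @export
zscore_features <- function(features, train_range, stats_from = NULL) {
  stopifnot(inherits(features, "ecog_features"))
  if (!is.null(stats_from)) {
    mu <- stats_from$norm_mean
    sdv <- stats_from$norm_std
    if (is.null(mu)) stopf("stats_from carries no normalization statistics")
  } else {
    if (length(train_range) == 0L) stopf("train_range must be non-empty")
    train <- features$values[train_range, , drop = FALSE]
    mu <- colMeans(train)
    sdv <- apply(train, 2L, stats::sd)
  }
  zero_var <- !is.finite(sdv) | sdv <= .Machine$double.eps
  sdv_safe <- ifelse(zero_var, 1, sdv)
  v <- sweep(sweep(features$values, 2L, mu), 2L, sdv_safe, "/")
  v[, zero_var] <- 0
  features$values <- v
  features$norm_mean <- mu
  features$norm_std <- sdv
  features$zero_variance <- zero_var
  features$zscored <- TRUE
  features
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: impedance exclusion, mains notch, common average
#' reference over the retained set, anti-aliased downsampling, binned
#' high-gamma band power. The returned feature matrix keeps only retained
#' channels. Z-scoring is applied separately ([zscore_features()]) because
#' its statistics depend on the train/test split.
#'
#' @param session an [ecog_session()].
#' @param config a [run_config()].
#' @return a raw `ecog_features` whose `channel_ids` are the retained
#'   channels; the stage order is recorded in `attr(, "stages")`.
#' @export
preprocess_session <- function(session, config = run_config()) {
  stopifnot(inherits(session, "ecog_session"), inherits(config, "run_config"))
  mask <- session$channel_mask & exclude_high_impedance(session, config$impedance_threshold)
  x <- notch_filter(session$signals, session$fs,
                    base_hz = config$notch_base, n_harmonics = config$n_harmonics)
  x <- common_average_reference(x, mask)
  x <- x[mask, , drop = FALSE]
  x <- resample_to(x, session$fs, config$target_fs)
  fm <- extract_hg_features(x, config$target_fs, bin_ms = config$bin_ms,
                            band = config$band, t0 = session$t0,
                            channel_ids = which(mask))
  attr(fm, "stages") <- c("exclude", "notch", "car", "resample", "psd")
  fm
}
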
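#' Spatially specific kinematic tuning map
#'
#' Places `n_sources` Gaussian activation bumps at random locations on the
#' array, each coupled to one kinematic axis, and evaluates every bump at the
#' electrode sites. The per-channel, per-axis gain is the sum of its bump
#' values, so tuned activity is spatially clustered on the scale
#' `spatial_scale_mm` — emulating the millimetre-scale, directionally tuned
#' micro-architecture that high-density grids resolve.
#'
#' @param layout an [ecog_layout()].
#' @param n_sources number of cortical sources (>= 1); axes are assigned
#'   round-robin so all three kinematic axes are represented.
#' @param spatial_scale_mm Gaussian sigma of each source footprint (mm, > 0).
#' @param seed integer seed; maps are fully reproducible.
#' @param source_amp_uV mean source coupling amplitude (uV of high-gamma
#'   envelope per unit kinematic drive).
#' @param baseline_hg_uV per-channel resting high-gamma envelope amplitude.
#' @return object of class `ecog_tuning`: `gains` (channels x 3, >= 0),
#'   `source_centers`, `source_axis`, `spatial_scale`, `baseline_hg`.
#' @export
make_tuning_maps <- function(layout, n_sources, spatial_scale_mm, seed,
                             source_amp_uV = 12, baseline_hg_uV = 2) {
  stopifnot(inherits(layout, "ecog_layout"))
  if (!is_count(n_sources)) stopf("n_sources must be a positive integer")
  if (!is_scalar_num(spatial_scale_mm) || spatial_scale_mm <= 0)
    stopf("spatial_scale_mm must be positive")
  n_ch <- length(layout$channel_ids)
  with_seed(seed, {
    rng <- apply(layout$site_xy, 2L, range)
    centers <- cbind(stats::runif(n_sources, rng[1L, 1L], rng[2L, 1L]),
                     stats::runif(n_sources, rng[1L, 2L], rng[2L, 2L]))
    axis <- sample(rep_len(1:3, n_sources))
    amp <- stats::rlnorm(n_sources, meanlog = log(source_amp_uV), sdlog = 0.3)
    gains <- matrix(0, n_ch, 3L, dimnames = list(NULL, c("x", "y", "z")))
    for (s in seq_len(n_sources)) {
      d2 <- (layout$site_xy[, 1L] - centers[s, 1L])^2 +
            (layout$site_xy[, 2L] - centers[s, 2L])^2
      gains[, axis[s]] <- gains[, axis[s]] +
        amp[s] * exp(-d2 / (2 * spatial_scale_mm^2))
    }
    structure(
      list(gains = gains, source_centers = centers, source_axis = axis,
           spatial_scale = spatial_scale_mm,
           baseline_hg = rep(baseline_hg_uV, n_ch)),
      class = "ecog_tuning"
    )
  })
}

#' Additive noise model for synthetic sessions
#'
#' Layered noise matching the artefacts the preprocessing stages target:
#' a 1/f background, a mains sinusoid plus harmonics (removed by the notch
#' filter), a common-mode process shared by all channels (removed by the
#' common average reference) and white sensor noise.
#'
#' @param one_over_f_scale RMS of the 1/f background (uV).
#' @param line_hz mains fundamental (Hz).
#' @param line_amp amplitude of the mains fundamental (uV); harmonic h has
#'   amplitude `line_amp / h`, with a small per-channel amplitude jitter.
#' @param n_harmonics number of mains harmonics (fundamental included).
#' @param common_mode_amp RMS of the shared common-mode process (uV).
#' @param white_rms white noise RMS per channel (uV).
#' @param pink_exponent spectral magnitude exponent of the background
#'   (magnitude ~ 1/f^exponent).
#' @return object of class `ecog_noise`.
#' @export
noise_model <- function(one_over_f_scale = 8, line_hz = 50, line_amp = 15,
                        n_harmonics = 3L, common_mode_amp = 15,
                        white_rms = 2, pink_exponent = 1) {
  amps <- c(one_over_f_scale, line_amp, common_mode_amp, white_rms)
  if (any(amps < 0)) stopf("noise amplitudes must be non-negative")
  structure(
    list(one_over_f_scale = one_over_f_scale, line_hz = line_hz,
         line_amp = line_amp, n_harmonics = as.integer(n_harmonics),
         common_mode_amp = common_mode_amp, white_rms = white_rms,
         pink_exponent = pink_exponent),
    class = "ecog_noise"
  )
}

# unit-RMS noise with spectral magnitude ~ 1/f^exponent
pink_noise <- function(n, fs, exponent = 1) {
  m <- stats::nextn(n, c(2, 3, 5))  # keep the FFT length composite
  z <- stats::fft(stats::rnorm(m))
  f <- c(1, seq_len(m - 1)) * fs / m          # guard DC
  f <- pmin(f, fs - f + fs / m)               # mirror for negative freqs
  shaped <- Re(stats::fft(z / f^exponent, inverse = TRUE))[seq_len(n)] / m
  shaped / rms(shaped)
}

#' Generate synthetic 3-D kinematics
#'
#' Two motion profiles are available. `"gait"` produces a smooth
#' quasi-periodic joint-angle trajectory (fundamental plus second harmonic
#' with slow random amplitude and phase drift); amplitudes differ per axis
#' and are largest in Y, mirroring primary knee-flexion kinematics, and all
#' axes stay positive as joint angles do. `"center_out_reach"` produces
#' piecewise minimum-jerk point-to-point movements whose speed vanishes at
#' segment endpoints.
#'
#' @param duration_s trace duration in seconds (> 0).
#' @param fs_kin kinematic sampling rate in Hz (> 0).
#' @param profile `"gait"` or `"center_out_reach"`.
#' @param seed integer seed.
#' @return a [kinematic_trace()] with `duration_s * fs_kin` samples.
#' @export
make_kinematics <- function(duration_s, fs_kin, profile = c("gait", "center_out_reach"),
                            seed = 1L) {
  profile <- match.arg(profile)
  if (!is_scalar_num(duration_s) || duration_s <= 0)
    stopf("duration_s must be positive")
  if (!is_scalar_num(fs_kin) || fs_kin <= 0) stopf("fs_kin must be positive")
  n <- floor(duration_s * fs_kin)
  if (n < 2L) stopf("empty trace: duration %g s at %g Hz gives < 2 samples",
                    duration_s, fs_kin)
  t <- (seq_len(n) - 1L) / fs_kin
  pos <- with_seed(seed, {
    if (profile == "gait") {
      stride_hz <- 1.2
      offset <- c(5, 8, 3.5)         # joint-angle offsets; Y largest swing
      amp1 <- 0.8 * offset           # deep flexion swing
      amp2 <- 0.2 * amp1
      sapply(1:3, function(a) {
        # slow drift processes make the gait quasi- rather than strictly periodic
        drift_a <- 1 + 0.08 * pmax(pmin(smooth_rw(n, fs_kin, cutoff_hz = 0.1), 2), -2)
        drift_p <- 0.5 * smooth_rw(n, fs_kin, cutoff_hz = 0.1)
        ph <- stats::runif(1, 0, 2 * pi)
        p <- offset[a] +
          amp1[a] * drift_a * sin(2 * pi * stride_hz * t + ph + drift_p) +
          amp2[a] * sin(2 * pi * 2 * stride_hz * t + 2 * ph + drift_p)
        # full extension floors the angle during the stance phase
        pmax(p, 0.05 * offset[a])
      })
    } else {
      targets_needed <- ceiling(duration_s / 0.8) + 2L
      pts <- matrix(stats::runif(3L * targets_needed, 2, 10), ncol = 3L)
      seg_dur <- stats::runif(targets_needed, 0.8, 1.4)
      pos <- matrix(0, n, 3L)
      seg <- 1L; t_seg <- 0
      p0 <- pts[1L, ]; p1 <- pts[2L, ]
      for (i in seq_len(n)) {
        tau <- min((t[i] - t_seg) / seg_dur[seg], 1)
        s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5  # minimum-jerk profile
        pos[i, ] <- p0 + (p1 - p0) * s
        if (tau >= 1 && seg < targets_needed - 1L) {
          seg <- seg + 1L; t_seg <- t[i]
          p0 <- p1; p1 <- pts[seg + 1L, ]
        }
      }
      pos
    }
  })
  kinematic_trace(t, pos, effector_label = profile)
}

# unit-variance smooth random process: low-pass filtered white noise
smooth_rw <- function(n, fs, cutoff_hz) {
  w <- stats::rnorm(n + 200L)
  bf <- signal::butter(2, min(cutoff_hz / (fs / 2), 0.99), type = "low")
  x <- filtfilt_mat(bf, w)[101:(n + 100L)]
  s <- stats::sd(x)
  if (s < .Machine$double.eps) rep(0, n) else (x - mean(x)) / s
}

#' Synthesize a grid session with known ground truth
#'
#' Each channel carries a band-limited (high-gamma band) carrier — white
#' noise band-passed with a zero-phase filter and normalized to unit RMS —
#' amplitude-modulated by the channel's envelope
#' `baseline_hg + sum_axis gain * |drive_axis|`, where each kinematic drive
#' axis is the position trace normalized to unit RMS and resampled to the
#' acquisition rate. On top of the modulated carrier the session adds a 1/f
#' background, a mains sinusoid with harmonics, a shared common-mode process
#' and white noise (see [noise_model()]). The output is fully deterministic
#' given the seed.
#'
#' @param layout an [ecog_layout()].
#' @param tuning an `ecog_tuning` from [make_tuning_maps()].
#' @param kin a [kinematic_trace()] covering the session duration.
#' @param noise an [noise_model()].
#' @param fs acquisition rate in Hz; must be at least twice the carrier band
#'   top plus margin (>= 320 Hz for the 70-150 Hz band).
#' @param seed integer seed.
#' @param band carrier band in Hz.
#' @return an [ecog_session()]; impedances are drawn in (0.3, 0.9) Mohm.
#' @export
synthesize_session <- function(layout, tuning, kin, noise = noise_model(),
                               fs = 1000, seed = 1L, band = c(70, 150)) {
  stopifnot(inherits(layout, "ecog_layout"), inherits(tuning, "ecog_tuning"),
            inherits(kin, "kinematic_trace"), inherits(noise, "ecog_noise"))
  if (fs < 2 * (band[2L] + 10))
    stopf("fs = %g Hz aliases the %g-%g Hz carrier band", fs, band[1L], band[2L])
  n_ch <- length(layout$channel_ids)
  dur <- kin$timestamps[length(kin$timestamps)] - kin$timestamps[1L]
  n <- floor(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  tk <- kin$timestamps - kin$timestamps[1L]

  drive <- sapply(1:3, function(a) {
    d <- stats::approx(tk, kin$position[, a], xout = t, rule = 2)$y
    d / rms(d)
  })
  bp <- signal::butter(4, band / (fs / 2), type = "pass")

  # each component draws from its own sub-seed, so switching one noise layer
  # on or off never alters the realization of the others
  signals <- with_seed(seed, {
    out <- matrix(0, n_ch, n)
    adrive <- abs(drive)
    for (bl in split(seq_len(n_ch), ceiling(seq_len(n_ch) / 32))) {
      W <- matrix(stats::rnorm(n * length(bl)), n, length(bl))
      W <- filtfilt_mat(bp, W)
      W <- sweep(W, 2L, apply(W, 2L, rms), "/")
      env_bl <- tuning$baseline_hg[bl] +
        tuning$gains[bl, , drop = FALSE] %*% t(adrive)  # block x samples
      out[bl, ] <- t(W) * env_bl
    }
    out
  })
  if (noise$one_over_f_scale > 0) with_seed(seed + 101L, {
    for (c in seq_len(n_ch))
      signals[c, ] <- signals[c, ] +
        noise$one_over_f_scale * pink_noise(n, fs, noise$pink_exponent)
  })
  if (noise$line_amp > 0) with_seed(seed + 102L, {
    line <- numeric(n)
    for (h in seq_len(noise$n_harmonics)) {
      ph <- stats::runif(1, 0, 2 * pi)
      line <- line + (noise$line_amp / h) * sin(2 * pi * noise$line_hz * h * t + ph)
    }
    jitter <- stats::runif(n_ch, 0.9, 1.1)
    for (c in seq_len(n_ch))
      signals[c, ] <- signals[c, ] + jitter[c] * line
  })
  if (noise$common_mode_amp > 0) with_seed(seed + 103L, {
    common <- noise$common_mode_amp * pink_noise(n, fs, noise$pink_exponent)
    signals <- sweep(signals, 2L, common, "+")
  })
  if (noise$white_rms > 0) with_seed(seed + 104L, {
    signals <- signals + matrix(stats::rnorm(n_ch * n, sd = noise$white_rms), n_ch)
  })
  impedances <- with_seed(seed + 105L, stats::runif(n_ch, 0.3, 0.9))
  ecog_session(signals, fs = fs, layout = layout, impedances = impedances,
               t0 = kin$timestamps[1L])
}

#' Corrupt a fraction of channels
#'
#' Emulates failed electrodes: `round(fraction * n_channels)` channels,
#' sampled without replacement, receive an impedance above 1 Mohm and their
#' signal is replaced by high-amplitude white noise. All other channels keep
#' impedances below 1 Mohm.
#'
#' @param session an [ecog_session()].
#' @param fraction fraction of channels to corrupt, in `[0, 1)`.
#' @param seed integer seed.
#' @return the modified [ecog_session()]; corrupted indices are in
#'   `attr(, "bad_channels")`.
#' @export
inject_bad_channels <- function(session, fraction, seed = 1L) {
  stopifnot(inherits(session, "ecog_session"))
  if (!is_scalar_num(fraction) || fraction < 0 || fraction >= 1)
    stopf("fraction must be in [0, 1)")
  n_ch <- nrow(session$signals)
  n_bad <- round(fraction * n_ch)
  with_seed(seed, {
    bad <- if (n_bad > 0L) sort(sample.int(n_ch, n_bad)) else integer(0)
    session$impedances <- pmin(session$impedances, 0.95)
    if (n_bad > 0L) {
      session$impedances[bad] <- stats::runif(n_bad, 1.2, 3)
      session$signals[bad, ] <- matrix(
        stats::rnorm(n_bad * ncol(session$signals), sd = 300),
        nrow = n_bad)
    }
    attr(session, "bad_channels") <- bad
    session
  })
}

#' Trial sequence for the cursor paradigms
#'
#' Center-out trials place 8 targets at equally spaced angles on a circle of
#' radius 0.7 (normalized screen coordinates); target order is drawn as
#' shuffled blocks of all 8 targets so every block is balanced. Webgrids
#' trials draw uniformly from a 15 x 17 grid of 255 cells. Every trial
#' carries the standard 4 s time limit and 200 ms hold requirement.
#'
#' @param task `"center_out"` or `"webgrids"`.
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed.
#' @return list of trial specs, each with `task`, `target_id` (0-based),
#'   `target_xy`, `max_duration` (s) and `hold_ms`.
#' @export
make_trial_sequence <- function(task = c("center_out", "webgrids"), n_trials,
                                seed = 1L) {
  task <- match.arg(task)
  if (!is_count(n_trials)) stopf("n_trials must be a positive integer")
  with_seed(seed, {
    if (task == "center_out") {
      angles <- 2 * pi * (0:7) / 8
      xy <- cbind(0.7 * cos(angles), 0.7 * sin(angles))
      n_blocks <- ceiling(n_trials / 8)
      ids <- unlist(lapply(seq_len(n_blocks), function(b) sample(0:7)))[seq_len(n_trials)]
    } else {
      grid_rows <- 15L; grid_cols <- 17L   # 255 cells
      ids <- sample.int(grid_rows * grid_cols, n_trials, replace = TRUE) - 1L
      col <- ids %% grid_cols
      row <- ids %/% grid_cols
      xy <- cbind((col + 0.5) / grid_cols * 2 - 1,
                  (row + 0.5) / grid_rows * 2 - 1)
      xy <- xy[seq_len(n_trials), , drop = FALSE]
    }
    lapply(seq_len(n_trials), function(i) {
      tid <- ids[i]
      txy <- if (task == "center_out") xy[tid + 1L, ] else xy[i, ]
      list(task = task, target_id = as.integer(tid),
           target_xy = as.numeric(txy), max_duration = 4, hold_ms = 200)
    })
  })
}

#' The packaged synthetic benchmark session
#'
#' One named preset used throughout the analysis experiments: a 16 x 16 grid
#' (1250 um pitch, 850 um sites), a 300 s gait kinematic trace at 100 Hz,
#' acquisition at 1000 Hz, 12 tuned cortical sources with a 1.5 mm spatial
#' scale, and the default [noise_model()]. All sub-seeds derive from `seed`.
#'
#' @param seed master seed (default 1, the packaged preset).
#' @param duration_s session duration in seconds.
#' @param fs acquisition rate in Hz.
#' @param n_rows,n_cols grid dimensions.
#' @param n_sources,spatial_scale_mm tuning-map parameters.
#' @param noise a [noise_model()].
#' @return list with `session`, `kin`, `tuning`, `layout`.
#' @export
simulate_benchmark <- function(seed = 1L, duration_s = 300, fs = 1000,
                               n_rows = 16L, n_cols = 16L, n_sources = 12L,
                               spatial_scale_mm = 1.5, noise = noise_model()) {
  layout <- ecog_layout(n_rows, n_cols, 1250, 850)
  tuning <- make_tuning_maps(layout, n_sources, spatial_scale_mm, seed = seed + 1L)
  kin <- make_kinematics(duration_s, fs_kin = 100, profile = "gait", seed = seed + 2L)
  session <- synthesize_session(layout, tuning, kin, noise, fs = fs, seed = seed + 3L)
  list(session = session, kin = kin, tuning = tuning, layout = layout)
}
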
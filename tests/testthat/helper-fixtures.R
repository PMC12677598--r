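# shared fixtures, built once per test run and cached

# small grid session with localized tuning: cheap enough for unit tests,
# rich enough that decoding and importance recovery work
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lay <- ecog_layout(8, 8, 1250, 850)
      tun <- make_tuning_maps(lay, 6, 1.5, seed = 11)
      kin <- make_kinematics(90, 100, "gait", seed = 12)
      ses <- synthesize_session(lay, tun, kin, noise_model(), fs = 1000, seed = 13)
      fm <- preprocess_session(ses, run_config())
      cache <<- list(layout = lay, tuning = tun, kin = kin, session = ses,
                     features = fm)
    }
    cache
  }
})

# independent bin/kinematics alignment for oracle checks: right-edge
# interpolation and the per-axis unit-RMS rectified drive
align_to_bins_oracle <- function(fm, kin) {
  rows <- which(fm$bin_time <= max(kin$timestamps) + 1e-9 &
                  (fm$bin_time - fm$bin_s) >= min(kin$timestamps) - 1e-9)
  tq <- pmin(fm$bin_time[rows], max(kin$timestamps))
  drive <- sapply(1:3, function(a) {
    d <- approx(kin$timestamps, kin$position[, a], xout = tq)$y
    abs(d) / sqrt(mean(kin$position[, a]^2))
  })
  list(rows = rows, drive = drive, time = tq)
}

# tiny session for I/O tests
tiny_session <- function(n_ch = 4L, n_s = 1000L, fs = 1000, seed = 1L) {
  lay <- ecog_layout(2, n_ch / 2L, 1250, 850)
  sig <- withr::with_seed(seed, matrix(rnorm(n_ch * n_s), n_ch))
  ecog_session(sig, fs = fs, layout = lay,
               impedances = seq(0.4, 0.9, length.out = n_ch))
}

# planted-channel fixture: exactly `n_tuned` channels carry kinematic signal
planted_fixture <- local({
  cache <- list()
  function(...) {
    key <- paste(deparse(list(...)), collapse = "")
    if (is.null(cache[[key]])) cache[[key]] <<- planted_fixture_impl(...)
    cache[[key]]
  }
})

planted_fixture_impl <- function(n_rows = 6L, n_tuned = 8L, duration_s = 60,
                                 gain = 18, seed = 21L) {
  lay <- ecog_layout(n_rows, n_rows, 1250, 850)
  n_ch <- n_rows^2
  tuned <- withr::with_seed(seed, sort(sample.int(n_ch, n_tuned)))
  gains <- matrix(0, n_ch, 3L, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_along(tuned)) gains[tuned[i], ((i - 1L) %% 3L) + 1L] <- gain
  tun <- structure(
    list(gains = gains, source_centers = lay$site_xy[tuned, , drop = FALSE],
         source_axis = ((seq_along(tuned) - 1L) %% 3L) + 1L,
         spatial_scale = 0, baseline_hg = rep(2, n_ch)),
    class = "ecog_tuning")
  kin <- make_kinematics(duration_s, 100, "gait", seed = seed + 1L)
  ses <- synthesize_session(lay, tun, kin, noise_model(), fs = 1000,
                            seed = seed + 2L)
  fm <- preprocess_session(ses, run_config())
  list(layout = lay, tuned = tuned, tuning = tun, kin = kin, session = ses,
       features = fm)
}
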
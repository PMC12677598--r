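test_that("impedance screening applies the 1 Mohm rule", {
  lay <- ecog_layout(1, 3, 1250, 850)
  ses <- ecog_session(matrix(0, 3, 100), 1000, lay,
                      impedances = c(0.5, 1.2, 0.9))
  expect_equal(exclude_high_impedance(ses, 1), c(TRUE, FALSE, TRUE))
  ses$impedances <- rep(0.3, 3)
  expect_equal(exclude_high_impedance(ses, 1), rep(TRUE, 3))
  ses$impedances <- rep(2, 3)
  expect_warning(mask <- exclude_high_impedance(ses, 1), "empty")
  expect_false(any(mask))
})

test_that("mains notch removes the fundamental and harmonics, spares the passband", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  for (f0 in c(50, 100, 150, 200)) {
    s <- sin(2 * pi * f0 * t)
    out <- notch_filter(s, fs)
    atten_db <- 20 * log10(sqrt(mean(out^2)) / sqrt(mean(s^2)))
    expect_lt(atten_db, -40)  # >= 40 dB at every notched harmonic
  }
  s50 <- sin(2 * pi * 50 * t)
  expect_lt(sqrt(mean(notch_filter(s50, fs)^2)) / sqrt(mean(s50^2)), 0.01)
  s80 <- sin(2 * pi * 80 * t)
  change_db <- abs(20 * log10(sqrt(mean(notch_filter(s80, fs)^2)) / sqrt(mean(s80^2))))
  expect_lt(change_db, 1)
  expect_identical(notch_filter(rep(0, 1000), fs), rep(0, 1000))
  expect_error(notch_filter(s50, fs, base_hz = 50, n_harmonics = 12), "Nyquist")
})

test_that("common average reference cancels common-mode exactly", {
  set.seed(4)
  x <- matrix(rnorm(5 * 200), 5)
  # after CAR the channel mean at every sample is zero
  y <- common_average_reference(x)
  expect_lt(max(abs(colMeans(y))), 1e-12)
  # adding a shared offset changes nothing
  y2 <- common_average_reference(x + 100)
  expect_equal(y2, y, tolerance = 1e-10)
  # a +a/-a pair is already zero-mean
  pair <- rbind(x[1, ], -x[1, ])
  expect_equal(common_average_reference(pair), pair, tolerance = 1e-12)
  # shared sinusoid removed, inter-channel differences preserved
  shared <- sin(2 * pi * 7 * seq_len(200) / 200)
  xs <- sweep(x, 2, shared, "+")
  ys <- common_average_reference(xs)
  expect_equal(ys[1, ] - ys[2, ], x[1, ] - x[2, ], tolerance = 1e-10)
  expect_error(common_average_reference(x, mask = c(TRUE, rep(FALSE, 4))), ">= 2")
  # excluded channels pass through unreferenced
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  ym <- common_average_reference(x, mask)
  expect_identical(ym[5, ], x[5, ])
})

test_that("downsampling anti-aliases and preserves length arithmetic", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 300 * t)        # above the new Nyquist of 250 Hz
  y <- resample_to(x, fs, 500)
  expect_equal(length(y), 5000)
  expect_lt(20 * log10(sqrt(mean(y^2)) / sqrt(mean(x^2))), -40)
  keep <- sin(2 * pi * 100 * t)     # inside the new band
  yk <- resample_to(keep, fs, 500)
  expect_equal(sqrt(mean(yk^2)), sqrt(mean(keep^2)), tolerance = 0.01)
  expect_identical(resample_to(keep, fs, fs), keep)
  expect_error(resample_to(keep, fs, 2000), "no upsampling")
})

test_that("binned periodograms measure in-band power", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  fm <- extract_hg_features(matrix(rnorm(3 * length(t)), 3), fs)
  expect_equal(dim(fm$values), c(100, 3))
  hg <- extract_hg_features(sin(2 * pi * 100 * t), fs)   # in band
  lo <- extract_hg_features(sin(2 * pi * 30 * t), fs)    # below band
  expect_gt(mean(hg$values) / mean(lo$values), 10)
  expect_error(extract_hg_features(sin(t), fs, band = c(70, 400)), "band")
  expect_error(extract_hg_features(sin(t), fs, bin_ms = 4), ">= 8")
})

test_that("features track a strongly modulated high-gamma envelope", {
  set.seed(9)
  fs <- 500
  n <- 60 * fs
  bp <- signal::butter(4, c(70, 150) / (fs / 2), type = "pass")
  carrier <- signal::filtfilt(bp, rnorm(n))
  carrier <- carrier / sqrt(mean(carrier^2))
  # bursty on/off envelope (deep modulation, bin-aligned 0.4 s bursts);
  # the single-periodogram estimator has ~40% intrinsic per-bin noise, which
  # caps the attainable correlation below the ideal of 1
  tt <- (seq_len(n) - 1) / fs
  env <- ifelse((tt %% 2) < 0.4, 8, 0.1)
  fm <- extract_hg_features(carrier * env, fs)
  nb <- nrow(fm$values)
  env2 <- colMeans(matrix(env[seq_len(nb * 50)]^2, 50))
  expect_gt(cor(fm$values[, 1], env2), 0.8)
})

test_that("z-scoring uses training statistics only and flags dead channels", {
  set.seed(5)
  raw <- extract_hg_features(matrix(rnorm(4 * 5000), 4), 500)
  raw$values[, 4] <- 3.14  # constant channel
  z <- zscore_features(raw, train_range = 1:60)
  expect_equal(colMeans(z$values[1:60, 1:3]), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z$values[1:60, 1:3], 2, sd), rep(1, 3), tolerance = 1e-12)
  # held-out bins are scaled with the same statistics (not re-fit)
  expect_false(isTRUE(all.equal(colMeans(z$values[61:100, 1:3]), rep(0, 3))))
  expect_true(z$zero_variance[4])
  expect_true(all(z$values[, 4] == 0))
  # stored statistics can be re-applied to a new session
  raw2 <- extract_hg_features(matrix(rnorm(4 * 5000), 4), 500)
  z2 <- zscore_features(raw2, stats_from = z)
  manual <- (raw2$values[, 2] - z$norm_mean[2]) / z$norm_std[2]
  expect_equal(z2$values[, 2], manual)
})

test_that("the pipeline preserves stage order and commutes with channel subsetting", {
  fx <- small_fixture()
  expect_identical(attr(fx$features, "stages"),
                   c("exclude", "notch", "car", "resample", "psd"))
  # features of a channel subset equal the subset of full-array features when
  # the CAR reference set is the same (computed over the full retained array)
  sub <- c(3, 17, 40)
  ses <- fx$session
  mask <- exclude_high_impedance(ses, 1)
  x <- notch_filter(ses$signals, ses$fs)
  x <- common_average_reference(x, mask)
  x <- resample_to(x[sub, , drop = FALSE], ses$fs, 500)
  fm_sub <- extract_hg_features(x, 500, t0 = ses$t0)
  expect_equal(fm_sub$values, fx$features$values[, sub], tolerance = 1e-10)
})
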
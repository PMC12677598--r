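test_that("density strides reproduce the published density ladder", {
  lay <- ecog_layout(16, 16, 1250, 850)
  subs <- density_subsets(lay)
  strides <- vapply(subs, function(s) s$stride, integer(1))
  expect_equal(strides, c(8L, 4L, 2L, 1L))
  expect_equal(vapply(subs, function(s) length(s$channel_indices), integer(1)),
               c(4L, 16L, 64L, 256L))
  expect_equal(vapply(subs, function(s) s$density, numeric(1)), c(1, 4, 16, 64))
  # anchored at the top-left site
  expect_equal(subs[[1]]$channel_indices[1], 1L)
  expect_error(density_subsets(lay, strides = 20), "exceeds")
  expect_error(density_subsets(ecog_layout(4, 8, 1250, 850)), "square")
})

test_that("centred coverage subsets are strictly nested", {
  lay <- ecog_layout(16, 16, 1250, 850)
  subs <- centered_grid_subsets(lay, c(16, 14, 12, 10, 8, 6, 4))
  expect_equal(length(subs[[1]]$channel_indices), 256)
  expect_equal(length(subs[[7]]$channel_indices), 16)
  for (i in 2:length(subs))
    expect_true(all(subs[[i]]$channel_indices %in% subs[[i - 1]]$channel_indices))
  # the 4x4 block hugs the centroid: mean site position at the centre
  xy <- lay$site_xy[subs[[7]]$channel_indices, ]
  expect_equal(unname(colMeans(xy)), c(0, 0), tolerance = 1e-9)
  expect_error(centered_grid_subsets(lay, 0), "outside")
})

test_that("random-forest Gini importance is normalized and recovers planted channels", {
  fx <- planted_fixture(n_rows = 6, n_tuned = 8, duration_s = 60)
  imp <- rf_importance(fx$features, fx$kin, n_trees = 400, seed = 1)
  expect_equal(colSums(imp$importance), c(x = 1, y = 1, z = 1), tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  top8 <- order(imp$mean_importance, decreasing = TRUE)[1:8]
  expect_gte(length(intersect(top8, fx$tuned)), 6)
})

test_that("importance under label shuffling is near-uniform", {
  fx <- planted_fixture(n_rows = 6, n_tuned = 8, duration_s = 60)
  shuffled <- fx$kin
  perm <- withr::with_seed(3, sample(nrow(shuffled$position)))
  shuffled$position <- shuffled$position[perm, ]
  shuffled$speed <- shuffled$speed[perm, ]
  imp <- rf_importance(fx$features, shuffled, n_trees = 500, seed = 2)
  expect_lt(max(imp$mean_importance) / min(imp$mean_importance), 3)
})

test_that("degenerate kinematic labels raise an error", {
  fx <- planted_fixture(n_rows = 4, n_tuned = 4, duration_s = 30)
  flat <- fx$kin
  flat$position[] <- 1
  expect_error(rf_importance(fx$features, flat, n_trees = 50, seed = 1),
               "degenerate")
})

test_that("the accuracy curve peaks near the planted channel count", {
  fx <- planted_fixture(n_rows = 5, n_tuned = 10, duration_s = 90, gain = 22)
  imp <- rf_importance(fx$features, fx$kin, n_trees = 400, seed = 4)
  res <- optimal_subset(fx$features, fx$kin, imp$mean_importance, start_k = 5)
  expect_equal(nrow(res$accuracy_curve), 25 - 5 + 1)
  expect_gte(res$optimal_size, 5)
  expect_lte(res$optimal_size, 16)
  expect_gte(length(intersect(res$optimal_subset, fx$tuned)), 8)
})

test_that("contribution frequencies count sessions and normalize to the maximum", {
  maps <- contribution_map(list(c(1, 2, 3), c(1, 2), c(2, 4)), n_channels = 5)
  expect_equal(maps$frequency, c(2 / 3, 1, 1 / 3, 1 / 3, 0))
  expect_equal(maps$contribution, c(2 / 3, 1, 1 / 3, 1 / 3, 0))
  expect_equal(max(maps$contribution), 1)
})

test_that("inter-electrode high-gamma correlation ranks signal sharing", {
  fs <- 500
  n <- 10 * fs
  set.seed(6)
  bp <- signal::butter(4, c(70, 150) / (fs / 2), type = "pass")
  shared <- signal::filtfilt(bp, rnorm(n))
  noise1 <- signal::filtfilt(bp, rnorm(n))
  noise2 <- signal::filtfilt(bp, rnorm(n))
  ident <- rbind(shared, shared)
  hc <- hg_correlation(ident, fs)
  expect_equal(hc$peak_matrix[1, 2], 1, tolerance = 1e-6)
  indep <- rbind(noise1, noise2)
  hc0 <- hg_correlation(indep, fs)
  expect_lt(hc0$peak_matrix[1, 2], 0.3)
  # peak correlation grows monotonically with the mixing ratio
  peaks <- sapply(c(0.2, 0.5, 0.8), function(r) {
    x <- rbind(r * shared + (1 - r) * noise1, r * shared + (1 - r) * noise2)
    hg_correlation(x, fs)$peak_matrix[1, 2]
  })
  expect_true(all(diff(peaks) > 0))
  expect_error(hg_correlation(matrix(0, 1, 100), fs), "2 channels")
})

test_that("high- and low-contribution blocks are selected geometrically", {
  lay <- ecog_layout(16, 16, 1250, 850)
  cmap <- numeric(256)
  hot <- as.vector(sapply(3:6, function(cc)
    (3:6 - 1) * 16 + cc))  # a hot 4x4 region at rows/cols 3-6
  cmap[hot] <- 1
  fx <- small_fixture()  # decode inputs; geometry comes from cmap
  # geometry-only check via the internal block scan
  res <- compare_contribution_subsets(
    cmap, lay,
    features = structure(list(values = matrix(rnorm(600 * 256), 600),
                              bin_s = 0.1, band = c(70, 150),
                              channel_ids = 1:256,
                              bin_time = seq(0.1, 60, by = 0.1),
                              zero_variance = logical(256), zscored = FALSE,
                              norm_mean = NULL, norm_std = NULL),
                         class = "ecog_features"),
    kin = make_kinematics(60, 100, "gait", seed = 3),
    session = ecog_session(matrix(rnorm(256 * 2000), 256), 1000, lay),
    size = 4, n_splits = 5, burn_in = 3)
  expect_setequal(res$high$channels, hot)
  expect_false(any(res$low$channels %in% hot))
  expect_gt(res$high$mean_contribution, res$low$mean_contribution)
  expect_equal(length(res$test$p_value), 1)
})

test_that("localized tuning yields a better and less redundant high block", {
  fx <- planted_fixture(n_rows = 8, n_tuned = 6, duration_s = 90, gain = 25,
                        seed = 31)
  # plant the tuned channels inside one 3x3 corner so they are contiguous
  lay <- fx$layout
  corner <- as.vector(sapply(1:3, function(cc) (1:3 - 1) * 8 + cc))
  gains <- matrix(0, 64, 3)
  for (i in seq_along(corner[1:6])) gains[corner[i], ((i - 1) %% 3) + 1] <- 25
  tun <- fx$tuning; tun$gains <- gains
  kin <- fx$kin
  ses <- synthesize_session(lay, tun, kin, noise_model(), fs = 1000, seed = 33)
  fm <- preprocess_session(ses, run_config())
  cmap <- numeric(64); cmap[corner[1:6]] <- 1
  res <- compare_contribution_subsets(cmap, lay, fm, kin, ses, size = 3,
                                      n_splits = 5, burn_in = 3)
  expect_gt(res$high$mean_cc, res$low$mean_cc)
  # tuned channels carry independent task signal; untuned share background
  expect_lt(res$high$mean_hg_correlation, res$low$mean_hg_correlation + 0.2)
})

test_that("subsample performance is deterministic and flags tiny subsets", {
  fx <- small_fixture()
  subs <- list(list(kind = "explicit", channel_indices = 1:20),
               list(kind = "explicit", channel_indices = 1:20),
               list(kind = "explicit", channel_indices = 1:3))
  out <- subsample_performance(list(list(features = fx$features, kin = fx$kin)),
                               subs)
  expect_equal(out$mean_cc[1], out$mean_cc[2])  # duplicate subset, same result
  expect_true(is.na(out$mean_cc[3]))            # below the state dimension
})
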
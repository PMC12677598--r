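# build a known position-velocity model to simulate from
known_model <- function(n_channels = 12L, seed = 42L, q_scale = 0.3) {
  withr::with_seed(seed, {
    A <- matrix(0, 7, 7)
    A[1:3, 1:3] <- diag(3); A[1:3, 4:6] <- 0.1 * diag(3); A[7, 7] <- 1
    A[4:6, 4:6] <- 0.9 * diag(3) + matrix(rnorm(9, sd = 0.02), 3)
    W <- matrix(0, 7, 7); W[4:6, 4:6] <- 0.05 * diag(3)
    H <- matrix(rnorm(n_channels * 7), n_channels, 7)
    Q <- q_scale * diag(n_channels)
    structure(list(A = A, W = W, H = H, Q = Q, dt = 0.1, state_dim = 7L,
                   n_channels = n_channels, n_train_bins = 0L,
                   train_log = list()), class = "ecog_kalman")
  })
}

test_that("closed-form fitting recovers the generating observation model", {
  m0 <- known_model()
  sim <- simulate(m0, nsim = 3000, seed = 1)
  fit <- ecog_kalman(sim$features, sim$states, dt = 0.1)
  rel_H <- norm(fit$H - m0$H, "F") / norm(m0$H, "F")
  expect_lt(rel_H, 0.05)
  rel_A <- norm(fit$A[4:6, 4:6] - m0$A[4:6, 4:6], "F") / norm(m0$A[4:6, 4:6], "F")
  expect_lt(rel_A, 0.05)
  # kinematic identity rows are exact
  expect_equal(fit$A[1:3, 1:6], cbind(diag(3), 0.1 * diag(3)),
               ignore_attr = TRUE)
})

test_that("estimation error shrinks by at least half from 300 to 3000 bins", {
  m0 <- known_model()
  err <- sapply(c(300, 3000), function(n) {
    e <- sapply(1:3, function(r) {
      sim <- simulate(m0, nsim = n, seed = 100 + r)
      fit <- ecog_kalman(sim$features, sim$states, dt = 0.1)
      norm(fit$H - m0$H, "F") / norm(m0$H, "F")
    })
    mean(e)
  })
  expect_lt(err[2], err[1] / 2)
})

test_that("a noiseless consistent system is reproduced to numerical tolerance", {
  m0 <- known_model(q_scale = 0)
  sim <- simulate(m0, nsim = 800, seed = 2)
  fit <- ecog_kalman(sim$features, sim$states, dt = 0.1)
  expect_lt(mean(diag(fit$Q)), 1e-6)
  dec <- predict(fit, sim$features)
  err <- rowMeans((dec$position - sim$states[, 1:3])^2)
  expect_lt(mean(err[101:800]), 1e-3)   # converges after burn-in
  expect_true(dec$psd_ok)               # P stays PSD throughout
})

test_that("degenerate state matrices raise a singular-fit error naming the dimension", {
  m0 <- known_model()
  sim <- simulate(m0, nsim = 300, seed = 3)
  st <- sim$states
  st[, 2] <- 5  # constant py
  expect_error(ecog_kalman(sim$features, st, dt = 0.1), "py")
  expect_error(ecog_kalman(sim$features[1:50, ], sim$states[1:50, ], 0.1),
               "at least")
})

test_that("dynamics help: decoding beats the regression baseline under noise", {
  # in the noisy regime the filter's state dynamics smooth out observation
  # noise that an instantaneous least-squares readout cannot
  kal <- base <- numeric(0)
  for (seed in c(22L, 30L)) {
    lay <- ecog_layout(4, 4, 1250, 850)
    gains <- matrix(0, 16, 3); tuned <- c(2, 7, 11, 14)
    for (i in 1:4) gains[tuned[i], ((i - 1) %% 3) + 1] <- 6
    tun <- structure(
      list(gains = gains, source_centers = lay$site_xy[tuned, , drop = FALSE],
           source_axis = ((1:4 - 1) %% 3) + 1, spatial_scale = 0,
           baseline_hg = rep(2, 16)), class = "ecog_tuning")
    kin <- make_kinematics(90, 100, "gait", seed = seed)
    ses <- synthesize_session(lay, tun, kin, noise_model(white_rms = 15),
                              fs = 1000, seed = seed + 1L)
    fm <- preprocess_session(ses, run_config())
    res <- decode_session(fm, kin)
    sync <- align_streams(ses, kin, 100)
    n <- nrow(sync$position)
    train <- seq_len(floor(0.7 * n)); test <- (floor(0.7 * n) + 1):n
    fmz <- zscore_features(fm, train)
    mu <- colMeans(sync$position[train, ])
    sdv <- apply(sync$position[train, ], 2, sd)
    P <- sweep(sweep(sync$position, 2, mu), 2, sdv, "/")
    X <- cbind(fmz$values, 1)
    B <- solve(crossprod(X[train, ]) + 1e-8 * diag(ncol(X)),
               crossprod(X[train, ], P[train, ]))
    cc_base <- mean(diag(cor(X[test, ] %*% B, P[test, ])))
    kal <- c(kal, res$mean_cc_position); base <- c(base, cc_base)
  }
  expect_gt(mean(kal), mean(base))
  expect_gt(mean(kal), 0.5)
})

test_that("decoded accuracy is invariant to feature channel permutation", {
  fx <- small_fixture()
  res1 <- decode_session(fx$features, fx$kin, channels = 1:64)
  perm <- withr::with_seed(5, sample(64))
  res2 <- decode_session(fx$features, fx$kin, channels = perm)
  expect_equal(res2$cc_position, res1$cc_position, tolerance = 1e-8)
})

test_that("empty and non-finite feature input is handled explicitly", {
  m0 <- known_model()
  dec <- predict(m0, matrix(0, 0, 12))
  expect_equal(nrow(dec$position), 0)
  z <- matrix(0, 5, 12); z[3, 4] <- NA
  expect_error(predict(m0, z), "bin 3")
})

test_that("channel dropout degrades accuracy monotonically from the exact baseline", {
  fx <- small_fixture()
  res <- decode_session(fx$features, fx$kin)
  dd <- eval_channel_dropout(res, fx$features, fx$kin,
                             drop_fractions = c(0, 0.3, 0.6, 0.9),
                             n_repeats = 4, seed = 2)
  sm <- attr(dd, "summary")
  expect_equal(sm$mean_cc[1], res$mean_cc_position)  # fraction 0 is a no-op
  # monotone non-increasing within one sd
  for (i in 2:nrow(sm))
    expect_lte(sm$mean_cc[i], sm$mean_cc[i - 1] + max(sm$sd_cc[i], 0.02, na.rm = TRUE))
  expect_error(eval_channel_dropout(res, fx$features, fx$kin,
                                    drop_fractions = 1), "\\[0, 1\\)")
})

test_that("dropping the only informative channels collapses decoding", {
  fx <- planted_fixture(n_rows = 4, n_tuned = 4, duration_s = 60, gain = 25)
  res <- decode_session(fx$features, fx$kin)
  expect_gt(res$mean_cc_position, 0.5)
  # zero exactly the tuned channels at test time
  sync <- align_streams(fx$session, fx$kin, 100)
  n <- nrow(sync$position); train <- seq_len(floor(0.7 * n))
  test <- (floor(0.7 * n) + 1):n
  fmz <- zscore_features(fx$features, train)
  Z <- fmz$values[test, ]
  Z[, fx$tuned] <- 0
  dec <- predict(res$fit, Z)
  mu <- colMeans(sync$position[train, ]); sdv <- apply(sync$position[train, ], 2, sd)
  P <- sweep(sweep(sync$position, 2, mu), 2, sdv, "/")
  cc <- mean(pearson_cc(dec$position[-(1:10), ], P[test[-(1:10)], ]), na.rm = TRUE)
  expect_lt(cc, res$mean_cc_position - 0.3)
})
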
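#' Train/evaluate the Kalman decoder on one session
#'
#' Convenience wrapper implementing the standard evaluation protocol:
#' chronological 7:3 train/test split of the feature bins, per-channel
#' z-scoring on the training segment only, z-scoring of the kinematic states
#' by training statistics, closed-form Kalman fit on the training segment,
#' filtering over the held-out segment from a fresh initial state, and
#' Pearson correlation per axis with a burn-in excluded.
#'
#' @param features raw (non-z-scored) `ecog_features` from
#'   [preprocess_session()] or [extract_hg_features()].
#' @param kin a [kinematic_trace()] overlapping the feature bins, or a
#'   pre-aligned list from [align_streams()].
#' @param split_ratio training fraction (chronological). Default 0.7.
#' @param burn_in number of initial test bins excluded from scoring.
#' @param channels optional channel subset (indices into feature columns)
#'   evaluated after preprocessing, mirroring the analysis of electrode
#'   subsets within one recorded session.
#' @return list of class `ecog_eval`: `fit` (the [ecog_kalman()]),
#'   `cc_position`, `cc_speed` (per-axis Pearson CC on the scored test
#'   bins), `mean_cc_position`, `pred` (decoded, z-scored units), `actual`
#'   (aligned z-scored states), `test_bins`, `scored_bins`.
#' @export
decode_session <- function(features, kin, split_ratio = 0.7, burn_in = 10L,
                           channels = NULL) {
  stopifnot(inherits(features, "ecog_features"))
  if (features$zscored) stopf("decode_session expects raw features; z-scoring is internal")
  if (inherits(kin, "kinematic_trace")) {
    sync <- align_to_bins(features, kin)
  } else {
    sync <- kin
  }
  n <- nrow(sync$position)
  n_train <- floor(split_ratio * n)
  if (n_train < 70L) stopf("training segment too short (%d bins)", n_train)
  train <- seq_len(n_train)
  test <- (n_train + 1L):n

  fm <- features
  fm$values <- fm$values[sync$feature_rows, , drop = FALSE]
  if (!is.null(channels)) {
    fm$values <- fm$values[, channels, drop = FALSE]
    fm$channel_ids <- fm$channel_ids[channels]
    fm$zero_variance <- fm$zero_variance[channels]
  }
  fm <- zscore_features(fm, train)

  mu_p <- colMeans(sync$position[train, , drop = FALSE])
  sd_p <- apply(sync$position[train, , drop = FALSE], 2L, stats::sd)
  sd_p[sd_p < .Machine$double.eps] <- 1
  P <- sweep(sweep(sync$position, 2L, mu_p), 2L, sd_p, "/")
  V <- finite_diff_cols(P, features$bin_s)
  states <- cbind(P, V)

  fit <- ecog_kalman(fm$values[train, , drop = FALSE],
                     states[train, , drop = FALSE], dt = features$bin_s)
  dec <- predict(fit, fm$values[test, , drop = FALSE])
  scored <- if (length(test) > burn_in) seq_along(test)[-seq_len(burn_in)]
            else seq_along(test)
  cc_p <- pearson_cc(dec$position[scored, , drop = FALSE],
                     P[test[scored], , drop = FALSE])
  cc_v <- pearson_cc(dec$velocity[scored, , drop = FALSE],
                     V[test[scored], , drop = FALSE])
  structure(
    list(fit = fit, cc_position = cc_p, cc_speed = cc_v,
         mean_cc_position = mean(cc_p), pred = dec,
         actual = list(position = P[test, , drop = FALSE],
                       velocity = V[test, , drop = FALSE]),
         test_bins = test, scored_bins = test[scored],
         norm = list(mean = mu_p, sd = sd_p)),
    class = "ecog_eval"
  )
}

#' @export
print.ecog_eval <- function(x, ...) {
  cat(sprintf(
    "ecog_eval: position CC (x, y, z) = %.3f, %.3f, %.3f (mean %.3f)\n       speed CC (x, y, z) = %.3f, %.3f, %.3f\n",
    x$cc_position[1L], x$cc_position[2L], x$cc_position[3L],
    x$mean_cc_position, x$cc_speed[1L], x$cc_speed[2L], x$cc_speed[3L]))
  invisible(x)
}

#' Plot decoded versus actual test trajectories
#'
#' @param x an `ecog_eval` from [decode_session()].
#' @param axes which axes to draw (subset of 1:3).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ecog_eval <- function(x, axes = 1:3, ...) {
  old <- graphics::par(mfrow = c(length(axes), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  lbl <- c("X", "Y", "Z")
  for (a in axes) {
    graphics::matplot(cbind(x$actual$position[, a], x$pred$position[, a]),
                      type = "l", lty = c(1, 2), col = c("black", "red"),
                      ylab = sprintf("%s (z)", lbl[a]), xlab = "test bin", ...)
  }
  invisible(x)
}

# align feature bins with a kinematic trace; returns matched feature rows
align_to_bins <- function(features, kin) {
  t_right <- features$bin_time
  bin_s <- features$bin_s
  k_lo <- kin$timestamps[1L]
  k_hi <- kin$timestamps[length(kin$timestamps)]
  eps <- 1e-9
  keep <- (t_right - bin_s) >= k_lo - eps & t_right <= k_hi + eps
  if (!any(keep)) stopf("feature bins and kinematics do not overlap")
  tq <- pmin(t_right[keep], k_hi)
  pos <- sapply(1:3, function(a)
    stats::approx(kin$timestamps, kin$position[, a], xout = tq)$y)
  spd <- sapply(1:3, function(a)
    stats::approx(kin$timestamps, kin$speed[, a], xout = tq)$y)
  list(feature_rows = which(keep), time = tq,
       position = matrix(pos, ncol = 3L), speed = matrix(spd, ncol = 3L))
}

#' Decoding robustness to channel loss
#'
#' For each dropout fraction, a random subset of feature channels is zeroed
#' at test time (z-scored features, so zero equals the training mean) and
#' the decoder is re-evaluated; repeats use distinct seeds. Reports mean and
#' standard deviation of the per-axis position CC versus dropout fraction.
#'
#' @param eval_res an `ecog_eval` from [decode_session()] — its fitted
#'   decoder and held-out segment are reused.
#' @param features,kin the same inputs given to [decode_session()].
#' @param drop_fractions fractions of channels to zero, each in `[0, 1)`.
#' @param n_repeats random subsets per fraction.
#' @param seed integer seed.
#' @param split_ratio,burn_in evaluation protocol (must match the fit).
#' @return data frame with `fraction`, `repeat_id`, `cc_x`, `cc_y`, `cc_z`,
#'   `mean_cc`; summary mean/sd per fraction in `attr(, "summary")`.
#' @export
eval_channel_dropout <- function(eval_res, features, kin,
                                 drop_fractions = c(0, 0.25, 0.5, 0.75),
                                 n_repeats = 5L, seed = 1L,
                                 split_ratio = 0.7, burn_in = 10L) {
  stopifnot(inherits(eval_res, "ecog_eval"), inherits(features, "ecog_features"))
  if (any(drop_fractions < 0 | drop_fractions >= 1))
    stopf("drop fractions must be in [0, 1)")
  sync <- if (inherits(kin, "kinematic_trace")) align_to_bins(features, kin) else kin
  n <- nrow(sync$position)
  n_train <- floor(split_ratio * n)
  train <- seq_len(n_train)
  test <- (n_train + 1L):n
  fm <- features
  fm$values <- fm$values[sync$feature_rows, , drop = FALSE]
  fm <- zscore_features(fm, train)
  Ztest <- fm$values[test, , drop = FALSE]
  P <- sweep(sweep(sync$position, 2L, eval_res$norm$mean), 2L, eval_res$norm$sd, "/")
  scored <- if (length(test) > burn_in) seq_along(test)[-seq_len(burn_in)]
            else seq_along(test)
  actual <- P[test[scored], , drop = FALSE]
  n_ch <- ncol(Ztest)

  rows <- list()
  for (i in seq_along(drop_fractions)) {
    f <- drop_fractions[i]
    n_drop <- round(f * n_ch)
    for (r in seq_len(n_repeats)) {
      Z <- Ztest
      if (n_drop > 0L) {
        drop <- with_seed(seed + 1000L * i + r,
                          sample.int(n_ch, n_drop))
        Z[, drop] <- 0
      }
      dec <- predict(eval_res$fit, Z)
      cc <- pearson_cc(dec$position[scored, , drop = FALSE], actual)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, repeat_id = r,
        cc_x = cc[1L], cc_y = cc[2L], cc_z = cc[3L], mean_cc = mean(cc))
      if (n_drop == 0L) break  # no randomness at fraction 0
    }
  }
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$fraction), function(d)
    data.frame(fraction = d$fraction[1L], mean_cc = mean(d$mean_cc),
               sd_cc = stats::sd(d$mean_cc))))
  attr(out, "summary") <- smry
  out
}
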
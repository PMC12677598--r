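#' Electrode-density subsets
#'
#' Uniformly strided subsets of a square grid emulating lower electrode
#' density over the same cortical extent: stride `s` on a grid of pitch `p`
#' behaves like a grid of pitch `s * p`. On the 16 x 16, 1250 um array,
#' strides 8/4/2/1 give densities 1/4/16/64 channels per cm^2. Subsets are
#' anchored at the top-left site.
#'
#' @param layout an [ecog_layout()] (square grid).
#' @param strides integer strides, each at most the grid dimension.
#' @return list of subset specs, each with `kind = "density_stride"`,
#'   `stride`, `channel_indices` (row-major) and `density` (channels/cm^2).
#' @export
density_subsets <- function(layout, strides = c(8L, 4L, 2L, 1L)) {
  stopifnot(inherits(layout, "ecog_layout"))
  if (layout$n_rows != layout$n_cols) stopf("density subsets require a square grid")
  lapply(strides, function(s) {
    if (s > layout$n_rows) stopf("stride %d exceeds grid dimension %d", s, layout$n_rows)
    rows <- seq(1L, layout$n_rows, by = s)
    cols <- seq(1L, layout$n_cols, by = s)
    idx <- as.integer(t(outer(rows, cols, function(r, c) grid_channel(layout, r, c))))
    list(kind = "density_stride", stride = as.integer(s),
         channel_indices = sort(idx),
         density = (10 / (layout$pitch_mm * s))^2)
  })
}

#' Centred coverage subsets
#'
#' For each size `k`, the `k x k` block of channels closest to the array
#' centroid, emulating reduced cortical coverage at constant density. When
#' the centred block is ambiguous (parity mismatch) it is shifted toward the
#' top-left. Blocks of decreasing size are strictly nested.
#'
#' @param layout an [ecog_layout()].
#' @param sizes block edge lengths, each in `[1, min(n_rows, n_cols)]`.
#' @return list of subset specs with `kind = "centered_grid"`, `grid_size`
#'   and `channel_indices`.
#' @export
centered_grid_subsets <- function(layout, sizes) {
  stopifnot(inherits(layout, "ecog_layout"))
  lapply(sizes, function(k) {
    if (k < 1L || k > min(layout$n_rows, layout$n_cols))
      stopf("grid size %d outside [1, %d]", k, min(layout$n_rows, layout$n_cols))
    r0 <- floor((layout$n_rows - k) / 2)
    c0 <- floor((layout$n_cols - k) / 2)
    idx <- as.integer(sapply(seq_len(k) + c0, function(cc)
      grid_channel(layout, seq_len(k) + r0, cc)))
    list(kind = "centered_grid", grid_size = as.integer(k),
         channel_indices = sort(idx))
  })
}

#' Decoding performance across electrode subsets
#'
#' For every subset, features are restricted to the subset's channels (the
#' common average reference having been computed once over the full retained
#' array, as when analysing subsets of a single recorded session) and the
#' Kalman decoder is trained and evaluated on the chronological 7:3 split.
#' Repeats run over independently generated sessions (distinct noise seeds),
#' yielding a mean, standard deviation and normalized coefficient of
#' variation per subset.
#'
#' @param feature_sets list of repeats, each a list with elements `features`
#'   (raw `ecog_features`) and `kin` (a [kinematic_trace()]).
#' @param subsets list of subset specs from [density_subsets()],
#'   [centered_grid_subsets()], or explicit
#'   `list(kind = "explicit", channel_indices = ...)`.
#' @param split_ratio,burn_in evaluation protocol.
#' @return data frame with one row per subset: `label`, `n_channels`,
#'   `mean_cc`, `sd_cc`, `cv`, `cv_norm` (CV scaled to its maximum across
#'   subsets); per-repeat values in `attr(, "per_repeat")`. Subsets with
#'   fewer channels than the state dimension are reported as `NA` and
#'   flagged.
#' @export
subsample_performance <- function(feature_sets, subsets, split_ratio = 0.7,
                                  burn_in = 10L) {
  if (length(feature_sets) == 0L) stopf("need at least one feature set")
  labels <- vapply(subsets, subset_label, character(1L))
  per <- matrix(NA_real_, length(subsets), length(feature_sets),
                dimnames = list(labels, NULL))
  for (r in seq_along(feature_sets)) {
    fs_r <- feature_sets[[r]]
    for (i in seq_along(subsets)) {
      ch <- match_subset(subsets[[i]], fs_r$features$channel_ids)
      if (length(ch) < 7L) next  # below state dimension: undefined
      res <- decode_session(fs_r$features, fs_r$kin, split_ratio = split_ratio,
                            burn_in = burn_in, channels = ch)
      per[i, r] <- res$mean_cc_position
    }
  }
  mean_cc <- rowMeans(per)
  sd_cc <- apply(per, 1L, stats::sd)
  cv <- ifelse(abs(mean_cc) > .Machine$double.eps, sd_cc / abs(mean_cc), NA_real_)
  cv_norm <- if (all(is.na(cv))) cv else cv / max(cv, na.rm = TRUE)
  out <- data.frame(label = labels,
                    n_channels = vapply(subsets, function(s)
                      length(s$channel_indices), integer(1L)),
                    mean_cc = mean_cc, sd_cc = sd_cc, cv = cv,
                    cv_norm = cv_norm, row.names = NULL)
  attr(out, "per_repeat") <- per
  out
}

subset_label <- function(s) {
  switch(s$kind,
         density_stride = sprintf("stride %d (%.3g ch/cm^2)", s$stride, s$density),
         centered_grid = sprintf("%dx%d grid", s$grid_size, s$grid_size),
         sprintf("explicit (%d ch)", length(s$channel_indices)))
}

# map layout channel indices onto feature columns (retained channels only)
match_subset <- function(subset, channel_ids) {
  which(channel_ids %in% subset$channel_indices)
}

#' Random-forest channel importance
#'
#' Stage one of the electrode-contribution algorithm: per kinematic axis,
#' the continuous kinematics at the feature bins are discretized into
#' tertile classes and a classification random forest predicts the class
#' from the per-channel high-gamma features. Channel importance is the mean
#' decrease in Gini impurity, normalized to sum to one per axis.
#'
#' @param features raw `ecog_features`.
#' @param kin a [kinematic_trace()] (or pre-aligned list).
#' @param n_trees trees per forest.
#' @param n_classes number of kinematic classes (default 3, tertiles).
#' @param seed integer seed.
#' @return list with `importance` (channels x 3, columns x/y/z, each summing
#'   to 1), `mean_importance` (across axes) and `channel_ids`.
#' @export
rf_importance <- function(features, kin, n_trees = 500L, n_classes = 3L,
                          seed = 1L) {
  stopifnot(inherits(features, "ecog_features"))
  sync <- if (inherits(kin, "kinematic_trace")) align_to_bins(features, kin) else kin
  Z <- features$values[sync$feature_rows, , drop = FALSE]
  if (nrow(Z) < 200L)
    warnf("only %d bins; importance estimates may be unstable", nrow(Z))
  imp <- matrix(0, ncol(Z), 3L, dimnames = list(NULL, c("x", "y", "z")))
  for (a in 1:3) {
    y <- sync$position[, a]
    br <- stats::quantile(y, probs = seq(0, 1, length.out = n_classes + 1L))
    br <- unique(br)
    if (length(br) < 3L) stopf("degenerate labels: axis %d kinematics are constant", a)
    cls <- cut(y, breaks = br, include.lowest = TRUE)
    rf <- with_seed(seed + a, randomForest::randomForest(
      x = as.data.frame(Z), y = cls, ntree = n_trees))
    g <- rf$importance[, "MeanDecreaseGini"]
    imp[, a] <- if (sum(g) > 0) g / sum(g) else rep(1 / length(g), length(g))
  }
  list(importance = imp, mean_importance = rowMeans(imp),
       channel_ids = features$channel_ids)
}

#' Optimal electrode subset by incremental accuracy curve
#'
#' Stage two of the contribution algorithm: starting from the `start_k`
#' channels with the highest importance, channels are added one at a time
#' in descending importance and the decoding CC is recorded at each size.
#' The optimal subset is the one at the peak of the accuracy curve; ties
#' resolve to the smallest subset (parsimony).
#'
#' @param features raw `ecog_features`.
#' @param kin a [kinematic_trace()] or pre-aligned list.
#' @param importance per-channel importance (e.g. `mean_importance` from
#'   [rf_importance()]); length must match the feature channels.
#' @param start_k initial subset size (default 5).
#' @param split_ratio,burn_in evaluation protocol.
#' @return list with `accuracy_curve` (data frame `size`, `cc`),
#'   `optimal_subset` (channel ids), `optimal_size`, `order` (channels by
#'   descending importance).
#' @export
optimal_subset <- function(features, kin, importance, start_k = 5L,
                           split_ratio = 0.7, burn_in = 10L) {
  stopifnot(inherits(features, "ecog_features"))
  n_ch <- ncol(features$values)
  if (length(importance) != n_ch)
    stopf("importance length %d != %d feature channels", length(importance), n_ch)
  if (start_k < 1L) stopf("start_k must be >= 1")
  ord <- order(importance, decreasing = TRUE)
  sync <- if (inherits(kin, "kinematic_trace")) align_to_bins(features, kin) else kin
  sizes <- seq(start_k, n_ch)
  cc <- vapply(sizes, function(k) {
    res <- decode_session(features, sync, split_ratio = split_ratio,
                          burn_in = burn_in, channels = ord[seq_len(k)])
    res$mean_cc_position
  }, numeric(1L))
  k_opt <- sizes[which.max(cc)]  # which.max takes the first (smallest) peak
  list(accuracy_curve = data.frame(size = sizes, cc = cc),
       optimal_subset = features$channel_ids[ord[seq_len(k_opt)]],
       optimal_size = k_opt,
       order = features$channel_ids[ord])
}

#' Cross-session contribution map
#'
#' The frequency with which each channel appears in the per-session optimal
#' subset, normalized so the most frequent channel maps to 1.
#'
#' @param optimal_subsets list of per-session optimal subsets (channel ids),
#'   or of results from [optimal_subset()].
#' @param n_channels total channel count of the layout.
#' @return list with `frequency` (appearances / sessions) and `contribution`
#'   (max-normalized), both length `n_channels`.
#' @export
contribution_map <- function(optimal_subsets, n_channels) {
  if (length(optimal_subsets) == 0L) stopf("need at least one session")
  subs <- lapply(optimal_subsets, function(s)
    if (is.list(s) && !is.null(s$optimal_subset)) s$optimal_subset else s)
  counts <- numeric(n_channels)
  for (s in subs) counts[s] <- counts[s] + 1
  freq <- counts / length(subs)
  contrib <- if (max(freq) > 0) freq / max(freq) else freq
  list(frequency = freq, contribution = contrib)
}

#' Inter-electrode high-gamma correlation
#'
#' Band-passes the signals to the high-gamma band, splits them into 2 s
#' bins, and records per bin and channel pair the peak of the absolute
#' normalized cross-correlation over lags of +/- 100 ms. Returns the
#' pairwise matrix of mean peaks and, per channel, its similarity curve
#' (mean peak versus its partners over bins, z-scored per channel to remove
#' amplitude differences).
#'
#' @param signals channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param band high-gamma band (Hz).
#' @param bin_s bin duration in seconds.
#' @param max_lag_s cross-correlation lag window (s).
#' @return list with `peak_matrix` (channels x channels, mean peak |xcorr|,
#'   sign of the peak in `sign_matrix`), `similarity` (channels x bins,
#'   z-scored), `skipped_pairs` (count of flat-bin pairs skipped).
#' @export
hg_correlation <- function(signals, fs, band = c(70, 150), bin_s = 2,
                           max_lag_s = 0.1) {
  if (is.null(dim(signals)) || nrow(signals) < 2L)
    stopf("need at least 2 channels")
  n_ch <- nrow(signals)
  L <- round(bin_s * fs)
  n_bins <- floor(ncol(signals) / L)
  if (n_bins < 1L) stopf("signal shorter than one %g s bin", bin_s)
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  X <- t(filtfilt_mat(bp, t(signals)))
  max_lag <- round(max_lag_s * fs)
  peak_sum <- matrix(0, n_ch, n_ch)
  sign_sum <- matrix(0, n_ch, n_ch)
  pair_n <- matrix(0, n_ch, n_ch)
  sim <- matrix(NA_real_, n_ch, n_bins)
  skipped <- 0L
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1L) * L + 1L):(b * L)
    seg <- X[, idx, drop = FALSE]
    seg <- seg - rowMeans(seg)
    ss <- sqrt(rowSums(seg^2))
    flat <- ss < .Machine$double.eps
    peaks_b <- matrix(NA_real_, n_ch, n_ch)
    for (i in seq_len(n_ch - 1L)) {
      if (flat[i]) { skipped <- skipped + sum(!flat[(i + 1L):n_ch]); next }
      for (j in (i + 1L):n_ch) {
        if (flat[j]) { skipped <- skipped + 1L; next }
        cc <- xcorr_norm(seg[i, ], seg[j, ], ss[i], ss[j], max_lag)
        k <- which.max(abs(cc))
        peak_sum[i, j] <- peak_sum[i, j] + abs(cc[k])
        sign_sum[i, j] <- sign_sum[i, j] + sign(cc[k])
        pair_n[i, j] <- pair_n[i, j] + 1
        peaks_b[i, j] <- peaks_b[j, i] <- abs(cc[k])
      }
    }
    sim[, b] <- rowMeans(peaks_b, na.rm = TRUE)
  }
  peak <- ifelse(pair_n > 0, peak_sum / pair_n, NA_real_)
  peak[lower.tri(peak)] <- t(peak)[lower.tri(peak)]
  diag(peak) <- 1
  sgn <- ifelse(pair_n > 0, sign(sign_sum), NA_real_)
  sgn[lower.tri(sgn)] <- t(sgn)[lower.tri(sgn)]
  sim_z <- t(apply(sim, 1L, function(r) {
    s <- stats::sd(r, na.rm = TRUE)
    if (!is.finite(s) || s < .Machine$double.eps) r * 0
    else (r - mean(r, na.rm = TRUE)) / s
  }))
  list(peak_matrix = peak, sign_matrix = sgn, similarity = sim_z,
       skipped_pairs = skipped)
}

# normalized cross-correlation of mean-removed segments over +/- max_lag
xcorr_norm <- function(x, y, sx, sy, max_lag) {
  n <- length(x)
  lags <- -max_lag:max_lag
  vapply(lags, function(l) {
    if (l >= 0) sum(x[1:(n - l)] * y[(1 + l):n]) / (sx * sy)
    else sum(x[(1 - l):n] * y[1:(n + l)]) / (sx * sy)
  }, numeric(1L))
}

#' Compare high- and low-contribution electrode blocks
#'
#' Selects the contiguous `size x size` block with the highest mean
#' contribution and a non-overlapping neighbouring block of the same size
#' with lower mean contribution (ties resolve to the top-left candidate).
#' For each block it reports the mean inter-electrode high-gamma
#' correlation, the decoding CC over repeated chronological splits, and the
#' normality-gated paired comparison of the two CC samples.
#'
#' @param cmap contribution vector over all layout channels (e.g.
#'   `contribution` from [contribution_map()]).
#' @param layout the [ecog_layout()].
#' @param features raw `ecog_features` of the session.
#' @param kin a [kinematic_trace()].
#' @param session the [ecog_session()] (for the signal-domain correlation).
#' @param size block edge length (default 4).
#' @param n_splits number of contiguous evaluation splits.
#' @param burn_in burn-in bins per split.
#' @return list with `high`, `low` (each: `channels`, `mean_contribution`,
#'   `mean_hg_correlation`, `cc_splits`, `mean_cc`), `test` (from
#'   [paired_compare()]), and `tie` flag.
#' @export
compare_contribution_subsets <- function(cmap, layout, features, kin, session,
                                         size = 4L, n_splits = 6L,
                                         burn_in = 5L) {
  stopifnot(inherits(layout, "ecog_layout"))
  if (length(cmap) != length(layout$channel_ids))
    stopf("contribution map length %d != %d layout channels",
          length(cmap), length(layout$channel_ids))
  R <- layout$n_rows; C <- layout$n_cols
  if (size > min(R, C)) stopf("block size %d exceeds grid", size)

  block_channels <- function(r0, c0)
    as.integer(sapply(c0 + seq_len(size) - 1L, function(cc)
      grid_channel(layout, r0 + seq_len(size) - 1L, cc)))
  block_mean <- function(r0, c0) mean(cmap[block_channels(r0, c0)])

  pos <- expand.grid(r0 = seq_len(R - size + 1L), c0 = seq_len(C - size + 1L))
  means <- mapply(block_mean, pos$r0, pos$c0)
  best <- which(means == max(means))
  tie <- length(best) > 1L
  best <- best[order(pos$r0[best], pos$c0[best])][1L]  # top-left tie rule
  hr <- pos$r0[best]; hc <- pos$c0[best]

  # non-overlapping neighbours: shifted by `size` in the four directions
  cand <- list(c(hr - size, hc), c(hr + size, hc), c(hr, hc - size), c(hr, hc + size))
  cand <- Filter(function(p) p[1L] >= 1L && p[1L] + size - 1L <= R &&
                   p[2L] >= 1L && p[2L] + size - 1L <= C, cand)
  if (length(cand) == 0L)
    stopf("no non-overlapping neighbouring %dx%d block exists", size, size)
  cmeans <- vapply(cand, function(p) block_mean(p[1L], p[2L]), numeric(1L))
  low_i <- which.min(cmeans)
  if (cmeans[low_i] >= means[best] && !tie)
    warnf("neighbouring block has no lower mean contribution (flat map?)")
  lr <- cand[[low_i]][1L]; lc <- cand[[low_i]][2L]

  high_ch <- block_channels(hr, hc)
  low_ch <- block_channels(lr, lc)

  hg_mean <- function(ch) {
    hc_res <- hg_correlation(session$signals[ch, , drop = FALSE], session$fs,
                             band = features$band)
    m <- hc_res$peak_matrix
    mean(m[upper.tri(m)], na.rm = TRUE)
  }

  cc_splits <- function(ch) {
    cols <- match_subset(list(channel_indices = ch), features$channel_ids)
    sync <- align_to_bins(features, kin)
    n <- nrow(sync$position)
    bounds <- floor(seq(0L, n, length.out = n_splits + 1L))
    vapply(seq_len(n_splits), function(s) {
      test <- (bounds[s] + 1L):bounds[s + 1L]
      train <- setdiff(seq_len(n), test)
      fm <- features
      fm$values <- fm$values[sync$feature_rows, cols, drop = FALSE]
      fm <- zscore_features(fm, train)
      mu <- colMeans(sync$position[train, , drop = FALSE])
      sdv <- apply(sync$position[train, , drop = FALSE], 2L, stats::sd)
      sdv[sdv < .Machine$double.eps] <- 1
      P <- sweep(sweep(sync$position, 2L, mu), 2L, sdv, "/")
      V <- finite_diff_cols(P, features$bin_s)
      fit <- ecog_kalman(fm$values[train, , drop = FALSE],
                         cbind(P, V)[train, , drop = FALSE], dt = features$bin_s)
      dec <- predict(fit, fm$values[test, , drop = FALSE])
      scored <- if (length(test) > burn_in) seq_along(test)[-seq_len(burn_in)]
                else seq_along(test)
      mean(pearson_cc(dec$position[scored, , drop = FALSE],
                      P[test[scored], , drop = FALSE]), na.rm = TRUE)
    }, numeric(1L))
  }

  cc_high <- cc_splits(high_ch)
  cc_low <- cc_splits(low_ch)
  list(
    high = list(channels = high_ch, origin = c(hr, hc),
                mean_contribution = means[best],
                mean_hg_correlation = hg_mean(high_ch),
                cc_splits = cc_high, mean_cc = mean(cc_high)),
    low = list(channels = low_ch, origin = c(lr, lc),
               mean_contribution = cmeans[low_i],
               mean_hg_correlation = hg_mean(low_ch),
               cc_splits = cc_low, mean_cc = mean(cc_low)),
    test = paired_compare(cc_high, cc_low),
    tie = tie
  )
}
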
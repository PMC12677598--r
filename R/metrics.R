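#' Per-axis Pearson correlation between trajectories
#'
#' @param pred,real equal-length numeric vectors, or samples x k matrices
#'   compared column by column. At least 3 samples.
#' @return named numeric vector of correlation coefficients, one per column.
#'   A column that is constant on either side yields `NA` with the
#'   `"undefined"` attribute listing the affected columns (no silent NaN
#'   propagation).
#' @export
pearson_cc <- function(pred, real) {
  pred <- as.matrix(pred); real <- as.matrix(real)
  if (!all(dim(pred) == dim(real)))
    stopf("pred (%d x %d) and real (%d x %d) must have identical dimensions",
          nrow(pred), ncol(pred), nrow(real), ncol(real))
  if (nrow(pred) < 3L) stopf("need at least 3 samples")
  k <- ncol(pred)
  cc <- numeric(k)
  undef <- integer(0)
  for (j in seq_len(k)) {
    if (stats::sd(pred[, j]) < .Machine$double.eps ||
        stats::sd(real[, j]) < .Machine$double.eps) {
      cc[j] <- NA_real_
      undef <- c(undef, j)
    } else {
      cc[j] <- stats::cor(pred[, j], real[, j])
    }
  }
  names(cc) <- if (k == 3L) c("x", "y", "z") else paste0("axis", seq_len(k))
  if (length(undef) > 0L) attr(cc, "undefined") <- undef
  cc
}

#' In-session sliding-window accuracy curve
#'
#' Pearson CC (averaged over axes) computed in half-open windows
#' `[t, t + window)` slid at a fixed step; output timestamps are window
#' centres. The number of windows is `floor((duration - window) / step) + 1`.
#'
#' @param pred,real samples x k trajectory matrices (or vectors).
#' @param fs sample rate of the traces in Hz (feature-bin rate, e.g. 10 Hz
#'   for 100 ms bins).
#' @param window_s window length in seconds; must not exceed the trace
#'   duration.
#' @param step_s stride in seconds.
#' @return data frame with `time` (window centre, s) and `cc`.
#' @export
sliding_cc <- function(pred, real, fs, window_s, step_s) {
  pred <- as.matrix(pred); real <- as.matrix(real)
  if (!all(dim(pred) == dim(real))) stopf("pred and real dimensions differ")
  n <- nrow(pred)
  dur <- n / fs
  if (window_s > dur) stopf("window %g s exceeds trace duration %g s", window_s, dur)
  wlen <- round(window_s * fs)
  step <- round(step_s * fs)
  starts <- seq(1L, n - wlen + 1L, by = step)
  cc <- vapply(starts, function(s) {
    idx <- s:(s + wlen - 1L)
    mean(pearson_cc(pred[idx, , drop = FALSE], real[idx, , drop = FALSE]),
         na.rm = TRUE)
  }, numeric(1L))
  data.frame(time = (starts - 1L) / fs + window_s / 2, cc = cc)
}

#' Per-channel signal-to-noise ratio (activity-state definition)
#'
#' Segments each channel into high- and low-activity states from its
#' smoothed envelope (rectified signal low-passed at 10 Hz): high state =
#' envelope above `median + 2 * MAD` sustained for at least 100 ms; low
#' state = envelope below the median. The SNR is the amplitude ratio
#' `20 * log10(peak-to-peak(high) / RMS(low))` in dB.
#'
#' @param signals channels x samples matrix (or vector).
#' @param fs sampling rate in Hz; at least 10 s of signal is recommended so
#'   both states occur.
#' @return numeric vector of per-channel SNR in dB; channels without both
#'   states yield `NA` with attribute `"undefined"`.
#' @export
snr_db <- function(signals, fs) {
  vec <- is.null(dim(signals))
  if (vec) signals <- matrix(signals, nrow = 1L)
  lp <- signal::butter(4, min(10 / (fs / 2), 0.99), type = "low")
  min_run <- max(1L, round(0.1 * fs))
  out <- numeric(nrow(signals))
  undef <- integer(0)
  for (c in seq_len(nrow(signals))) {
    x <- signals[c, ]
    env <- filtfilt_mat(lp, abs(x))
    med <- stats::median(env)
    thr <- med + 2 * stats::mad(env)
    high <- sustained_runs(env > thr, min_run)
    low <- env < med
    if (!any(high) || !any(low) || stats::mad(env) < .Machine$double.eps) {
      out[c] <- NA_real_
      undef <- c(undef, c)
      next
    }
    pp_high <- max(x[high]) - min(x[high])
    rms_low <- rms(x[low])
    out[c] <- 20 * log10(pp_high / rms_low)
  }
  if (length(undef) > 0L) attr(out, "undefined") <- undef
  if (vec && length(undef) == 0L) out else out
}

# keep only TRUE runs of length >= min_run
sustained_runs <- function(flag, min_run) {
  r <- rle(flag)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' Information throughput of a target-selection paradigm
#'
#' `BR = log2(N) * max(S - F, 0) / T` bits per second, where `N` is the
#' number of selectable targets, `S` and `F` the counts of successful and
#' failed trials, and `T` the total task time in seconds (timed-out trials
#' count as failed and their full duration is included in `T`).
#'
#' @param N number of selectable targets (>= 1).
#' @param S,F successful / failed trial counts (>= 0).
#' @param T_s total time in seconds (> 0).
#' @return bit rate in bits/s (>= 0).
#' @examples
#' bit_rate(8, 10, 2, 30)  # 0.8 bits/s
#' @export
bit_rate <- function(N, S, F, T_s) {
  if (!is_count(N)) stopf("N must be a positive integer")
  if (S < 0 || F < 0) stopf("S and F must be non-negative")
  if (!is_scalar_num(T_s) || T_s <= 0) stopf("total time must be positive")
  log2(N) * max(S - F, 0) / T_s
}

#' Adjudicate a block of trials
#'
#' Counts successes and failures, accumulates the total time (timed-out
#' trials contribute their full consumed duration) and computes the bit
#' rate. Conserves trials: `S + F` equals the input count.
#'
#' @param trials list of trial records from [run_closed_loop()] (each with
#'   `success`, `t_start`, `t_end`).
#' @param N number of selectable targets of the paradigm.
#' @return list with `S`, `F`, `T_s`, `bit_rate`.
#' @export
adjudicate <- function(trials, N) {
  if (length(trials) == 0L) stopf("empty trial list")
  S <- sum(vapply(trials, function(tr) isTRUE(tr$success), logical(1L)))
  F <- length(trials) - S
  T_s <- sum(vapply(trials, function(tr) tr$t_end - tr$t_start, numeric(1L)))
  list(S = S, F = F, T_s = T_s, bit_rate = bit_rate(N, S, F, T_s))
}

#' Normality-gated paired comparison
#'
#' Both groups are tested for normality (Shapiro-Wilk, alpha = 0.05) and for
#' variance homogeneity (F test). If both groups are compatible with
#' normality and equal variances, a two-sided paired t-test is applied;
#' otherwise the Wilcoxon signed-rank test (the rank-based test appropriate
#' for paired designs).
#'
#' @param group_a,group_b paired samples of equal length (>= 5).
#' @param alpha gate level for the normality and variance checks.
#' @return list with `method`, `statistic`, `p_value`, `normal_a`,
#'   `normal_b`, `equal_var`.
#' @export
paired_compare <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) != length(group_b))
    stopf("groups must have equal length (paired design)")
  if (length(group_a) < 5L) stopf("need at least 5 pairs")
  if (stats::sd(group_a - group_b) < .Machine$double.eps)
    return(list(method = "degenerate (identical pairs)", statistic = 0,
                p_value = 1, normal_a = NA, normal_b = NA, equal_var = NA))
  sw_a <- tryCatch(stats::shapiro.test(group_a)$p.value, error = function(e) 0)
  sw_b <- tryCatch(stats::shapiro.test(group_b)$p.value, error = function(e) 0)
  normal_a <- sw_a > alpha
  normal_b <- sw_b > alpha
  equal_var <- tryCatch(stats::var.test(group_a, group_b)$p.value > alpha,
                        error = function(e) FALSE)
  if (normal_a && normal_b && equal_var) {
    ht <- stats::t.test(group_a, group_b, paired = TRUE)
    method <- "paired t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(group_a, group_b, paired = TRUE,
                                              exact = FALSE))
    method <- "Wilcoxon signed-rank test"
  }
  list(method = method, statistic = unname(ht$statistic),
       p_value = ht$p.value, normal_a = normal_a, normal_b = normal_b,
       equal_var = equal_var)
}
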
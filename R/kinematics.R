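#' Time-stamped 3-D kinematic trace
#'
#' @param timestamps strictly increasing sample times in seconds.
#' @param position samples x 3 matrix of X/Y/Z positions (arbitrary units).
#' @param speed optional samples x 3 matrix of per-axis velocities (units/s);
#'   derived by central finite differences when omitted (uniform sampling
#'   assumed).
#' @param effector_label free-text label of the tracked effector.
#' @return an object of class `kinematic_trace`.
#' @export
kinematic_trace <- function(timestamps, position, speed = NULL,
                            effector_label = "effector") {
  position <- as.matrix(position)
  if (ncol(position) != 3L) stopf("position must have 3 columns (X, Y, Z)")
  n <- length(timestamps)
  if (n == 0L) stopf("empty trace: no timestamps")
  if (nrow(position) != n) stopf("position rows must match timestamps")
  if (n > 1L && any(diff(timestamps) <= 0))
    stopf("timestamps must be strictly increasing")
  if (is.null(speed)) {
    dt <- if (n > 1L) stats::median(diff(timestamps)) else 1
    speed <- finite_diff_cols(position, dt)
  }
  speed <- as.matrix(speed)
  if (!all(dim(speed) == dim(position)))
    stopf("speed must have the same dimensions as position")
  colnames(position) <- colnames(speed) <- c("x", "y", "z")
  structure(
    list(timestamps = as.numeric(timestamps), position = position,
         speed = speed, effector_label = effector_label),
    class = "kinematic_trace"
  )
}

#' @export
print.kinematic_trace <- function(x, ...) {
  cat(sprintf("kinematic_trace '%s': %d samples over [%.3f, %.3f] s\n",
              x$effector_label, length(x$timestamps),
              x$timestamps[1L], x$timestamps[length(x$timestamps)]))
  invisible(x)
}

#' Read / write kinematics CSV
#'
#' Plain CSV with header `time_s,x,y,z[,vx,vy,vz]`. Velocities are derived by
#' finite differences when the file omits them.
#'
#' @param trace a [kinematic_trace()].
#' @param path CSV file path.
#' @return `read_kinematics` returns a [kinematic_trace()].
#' @export
write_kinematics <- function(trace, path) {
  stopifnot(inherits(trace, "kinematic_trace"))
  df <- data.frame(time_s = trace$timestamps,
                   x = trace$position[, 1L], y = trace$position[, 2L],
                   z = trace$position[, 3L],
                   vx = trace$speed[, 1L], vy = trace$speed[, 2L],
                   vz = trace$speed[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics
#' @export
read_kinematics <- function(path) {
  if (!file.exists(path)) stopf("kinematics file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "x", "y", "z")
  if (!all(need %in% names(df)))
    stopf("kinematics CSV must have header columns %s", paste(need, collapse = ", "))
  speed <- NULL
  if (all(c("vx", "vy", "vz") %in% names(df)))
    speed <- as.matrix(df[, c("vx", "vy", "vz")])
  kinematic_trace(df$time_s, as.matrix(df[, c("x", "y", "z")]), speed = speed)
}

#' Align neural feature bins with a kinematic trace
#'
#' Feature bins are half-open `[t, t + bin)` intervals starting at the
#' session start time. For every bin fully inside the overlap of the neural
#' and kinematic time ranges, the kinematic position and speed are linearly
#' interpolated at the bin's right edge. Bins extending outside the overlap
#' are dropped; the returned mapping is monotone in time.
#'
#' @param neural an [ecog_session()] (or a list with `t0`, `fs` and a signal
#'   length, as produced by the pipeline).
#' @param kin a [kinematic_trace()].
#' @param bin_ms bin duration in milliseconds.
#' @return list with `bin` (kept bin indices, 1-based), `time` (right-edge
#'   timestamps), `position` and `speed` (interpolated, bins x 3).
#' @export
align_streams <- function(neural, kin, bin_ms) {
  stopifnot(inherits(neural, "ecog_session"), inherits(kin, "kinematic_trace"))
  if (!is_scalar_num(bin_ms) || bin_ms <= 0) stopf("bin_ms must be positive")
  bin_s <- bin_ms / 1000
  t0 <- neural$t0
  t_end <- t0 + session_duration(neural)
  k_lo <- kin$timestamps[1L]
  k_hi <- kin$timestamps[length(kin$timestamps)]
  lo <- max(t0, k_lo)
  hi <- min(t_end, k_hi)
  if (hi <= lo) stopf("neural [%g, %g] s and kinematic [%g, %g] s ranges do not overlap",
                      t0, t_end, k_lo, k_hi)
  n_bins <- floor((t_end - t0) / bin_s + 1e-9)
  if (n_bins < 1L) stopf("session shorter than one bin")
  left <- t0 + (seq_len(n_bins) - 1L) * bin_s
  right <- left + bin_s
  eps <- 1e-9
  keep <- left >= lo - eps & right <= hi + eps
  if (!any(keep)) stopf("no feature bin lies fully inside the stream overlap")
  idx <- which(keep)
  tq <- pmin(right[idx], k_hi)  # guard fp overshoot at the boundary
  pos <- sapply(1:3, function(a)
    stats::approx(kin$timestamps, kin$position[, a], xout = tq)$y)
  spd <- sapply(1:3, function(a)
    stats::approx(kin$timestamps, kin$speed[, a], xout = tq)$y)
  pos <- matrix(pos, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
  spd <- matrix(spd, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
  list(bin = idx, time = right[idx], position = pos, speed = spd)
}
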
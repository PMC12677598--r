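#' Position-velocity Kalman filter decoder
#'
#' Fits a linear-Gaussian state-space decoder whose state stacks 3-D
#' position, 3-D velocity and a constant bias term,
#' `x_t = (px, py, pz, vx, vy, vz, 1)`. The state transition encodes the
#' kinematic identity `p_{t+1} = p_t + dt * v_t` exactly; the velocity block
#' and its process noise are estimated by least squares on successive state
#' pairs. The observation model maps state to neural features (the standard
#' generative direction in BCI Kalman practice): `z_t = H x_t + q_t`, with
#' `H` and the observation-noise covariance `Q` estimated by least squares.
#' All estimates are closed-form.
#'
#' @param features bins x channels feature matrix, or an `ecog_features`.
#' @param states bins x 6 matrix of positions and velocities (columns
#'   px, py, pz, vx, vy, vz), time-aligned with the feature bins.
#' @param dt bin duration in seconds.
#' @param ridge small diagonal loading added to `Q` for numerical stability.
#' @return an object of class `ecog_kalman` with components `A`, `W`, `H`,
#'   `Q`, `dt`, `state_dim` (7), `n_channels`, and the training log
#'   (residual variances).
#' @seealso [predict.ecog_kalman()], [simulate.ecog_kalman()],
#'   [eval_channel_dropout()]
#' @examples
#' # a tiny synthetic fit
#' set.seed(1)
#' n <- 300; dt <- 0.1
#' v <- apply(matrix(rnorm(n * 3, sd = 0.3), n), 2, cumsum) * 0.1
#' p <- apply(v * dt, 2, cumsum)
#' st <- cbind(p, v)
#' z <- st %*% matrix(rnorm(6 * 12), 6) + matrix(rnorm(n * 12, sd = 0.2), n)
#' fit <- ecog_kalman(z, st, dt)
#' dec <- predict(fit, z)
#' @export
ecog_kalman <- function(features, states, dt, ridge = 1e-6) {
  Z <- if (inherits(features, "ecog_features")) features$values else as.matrix(features)
  states <- as.matrix(states)
  if (ncol(states) != 6L)
    stopf("states must have 6 columns (3 position + 3 velocity)")
  n <- nrow(Z)
  if (nrow(states) != n) stopf("features and states must have equal bin counts")
  d <- 7L
  if (n < d * 10L)
    stopf("need at least %d aligned bins to fit (got %d)", d * 10L, n)

  X <- cbind(states, 1)  # bins x 7, bias absorbs feature offsets
  axis_names <- c("px", "py", "pz", "vx", "vy", "vz", "bias")
  colnames(X) <- axis_names

  sds <- apply(states, 2L, stats::sd)
  if (any(sds < 1e-10))
    stopf("singular fit: state dimension '%s' is constant",
          axis_names[which(sds < 1e-10)[1L]])
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    stopf("singular fit: state matrix is rank-deficient (collinear dimensions)")
  }

  # transition: position rows are kinematic identities; velocity block by LS
  A <- matrix(0, d, d, dimnames = list(axis_names, axis_names))
  A[1:3, 1:3] <- diag(3)
  A[1:3, 4:6] <- dt * diag(3)
  A[7L, 7L] <- 1
  V0 <- states[-n, 4:6, drop = FALSE]
  V1 <- states[-1L, 4:6, drop = FALSE]
  Av <- t(solve(crossprod(V0), crossprod(V0, V1)))  # v_{t+1} = Av v_t
  A[4:6, 4:6] <- Av
  W <- matrix(0, d, d, dimnames = list(axis_names, axis_names))
  Ev <- V1 - V0 %*% t(Av)
  W[4:6, 4:6] <- crossprod(Ev) / max(nrow(Ev) - 3L, 1L)
  W[4:6, 4:6] <- W[4:6, 4:6] + 1e-10 * diag(3)

  # observation model z = H x + q
  H <- t(solve(XtX, crossprod(X, Z)))               # channels x 7
  E <- Z - X %*% t(H)
  Q <- crossprod(E) / max(n - d, 1L)
  Q <- Q + ridge * mean(diag(Q)) * diag(ncol(Z)) + 1e-12 * diag(ncol(Z))

  structure(
    list(A = A, W = W, H = H, Q = Q, dt = dt, state_dim = d,
         n_channels = ncol(Z), n_train_bins = n,
         train_log = list(obs_resid_var = mean(diag(Q)),
                          vel_resid_var = mean(diag(W[4:6, 4:6])))),
    class = "ecog_kalman"
  )
}

#' @export
print.ecog_kalman <- function(x, ...) {
  cat(sprintf(
    "ecog_kalman: position-velocity Kalman decoder\n  %d feature channels, state dim %d (3 pos + 3 vel + bias), dt = %g s\n  fitted on %d bins\n",
    x$n_channels, x$state_dim, x$dt, x$n_train_bins))
  invisible(x)
}

#' @export
summary.ecog_kalman <- function(object, ...) {
  ev <- eigen(object$A[4:6, 4:6], only.values = TRUE)$values
  out <- list(
    n_channels = object$n_channels,
    dt = object$dt,
    n_train_bins = object$n_train_bins,
    velocity_eigenvalues = ev,
    mean_obs_noise_var = mean(diag(object$Q)),
    mean_abs_H = mean(abs(object$H[, 1:6]))
  )
  class(out) <- "summary.ecog_kalman"
  out
}

#' @export
print.summary.ecog_kalman <- function(x, ...) {
  cat("Position-velocity Kalman decoder\n")
  cat(sprintf("  channels: %d   bins fitted: %d   dt: %g s\n",
              x$n_channels, x$n_train_bins, x$dt))
  cat(sprintf("  velocity transition |eigenvalues|: %s\n",
              paste(sprintf("%.3f", Mod(x$velocity_eigenvalues)), collapse = ", ")))
  cat(sprintf("  mean observation-noise variance: %.4g\n", x$mean_obs_noise_var))
  invisible(x)
}

#' @export
coef.ecog_kalman <- function(object, ...) {
  object[c("A", "W", "H", "Q")]
}

#' Decode kinematics from features
#'
#' Runs the standard Kalman predict/update recursion over the feature bins:
#' predict `x <- A x`, `P <- A P A' + W`; update with the Kalman gain formed
#' from `H` and `Q`. The filter starts from a zero state (bias fixed at 1)
#' with a large diagonal covariance (`P0 = 10 I`). The state covariance is
#' re-symmetrized each step and checked for positive semi-definiteness.
#'
#' @param object a fitted [ecog_kalman()].
#' @param features bins x channels matrix or `ecog_features`; channel count
#'   must match the fit.
#' @param ... unused.
#' @return list of class `ecog_decode` with `position`, `velocity` (bins x
#'   3), and `psd_ok` (all state covariances PSD).
#' @export
predict.ecog_kalman <- function(object, features, ...) {
  Z <- if (inherits(features, "ecog_features")) features$values else as.matrix(features)
  if (nrow(Z) == 0L)
    return(structure(list(position = matrix(0, 0, 3), velocity = matrix(0, 0, 3),
                          psd_ok = TRUE), class = "ecog_decode"))
  if (ncol(Z) != object$n_channels)
    stopf("feature channel count %d does not match the fitted model (%d)",
          ncol(Z), object$n_channels)
  bad <- which(!is.finite(rowSums(Z)))
  if (length(bad) > 0L)
    stopf("non-finite features at bin %d", bad[1L])
  d <- object$state_dim
  A <- object$A; W <- object$W; H <- object$H; Q <- object$Q
  x <- c(rep(0, 6), 1)
  P <- diag(10, d); P[d, d] <- 0
  n <- nrow(Z)
  pos <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  vel <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  psd_ok <- TRUE
  Id <- diag(d)
  for (t in seq_len(n)) {
    x <- A %*% x
    P <- A %*% P %*% t(A) + W
    S <- H %*% P %*% t(H) + Q
    K <- t(solve(S, H %*% P))            # P H' S^-1
    x <- x + K %*% (Z[t, ] - H %*% x)
    P <- (Id - K %*% H) %*% P
    P <- (P + t(P)) / 2
    if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) < -1e-6)
      psd_ok <- FALSE
    pos[t, ] <- x[1:3]
    vel[t, ] <- x[4:6]
  }
  structure(list(position = pos, velocity = vel, psd_ok = psd_ok),
            class = "ecog_decode")
}

#' @export
print.ecog_decode <- function(x, ...) {
  cat(sprintf("ecog_decode: %d decoded bins (3-D position + velocity)\n",
              nrow(x$position)))
  invisible(x)
}

#' Simulate trajectories and observations from a fitted decoder
#'
#' Draws state trajectories from the fitted linear-Gaussian dynamics and
#' feature observations from the observation model — useful as an
#' independent data source for parameter-recovery checks.
#'
#' @param object an [ecog_kalman()].
#' @param nsim number of bins to simulate.
#' @param seed integer seed.
#' @param x0 optional initial state (length 7).
#' @param ... unused.
#' @return list with `states` (bins x 6) and `features` (bins x channels).
#' @export
simulate.ecog_kalman <- function(object, nsim = 1000, seed = NULL, x0 = NULL, ...) {
  d <- object$state_dim
  if (is.null(x0)) x0 <- c(rep(0, 6), 1)
  cw <- chol_psd(object$W[4:6, 4:6])
  cq <- chol_psd(object$Q)
  run <- function() {
    X <- matrix(0, nsim, 6L)
    x <- x0
    for (t in seq_len(nsim)) {
      x <- object$A %*% x
      x[4:6] <- x[4:6] + t(cw) %*% stats::rnorm(3)
      X[t, ] <- x[1:6]
    }
    Z <- cbind(X, 1) %*% t(object$H) +
      matrix(stats::rnorm(nsim * object$n_channels), nsim) %*% cq
    list(states = X, features = Z)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Cholesky factor tolerant of PSD (rank-deficient) matrices
chol_psd <- function(M) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(eg$values, 0)
  R <- diag(sqrt(v), length(v)) %*% t(eg$vectors)
  R
}

#' Observation residuals of the fitted model
#'
#' @param object an [ecog_kalman()].
#' @param features,states the training data (bins x channels, bins x 6).
#' @param ... unused.
#' @return bins x channels residual matrix `Z - X H'`.
#' @export
residuals.ecog_kalman <- function(object, features, states, ...) {
  Z <- if (inherits(features, "ecog_features")) features$values else as.matrix(features)
  X <- cbind(as.matrix(states), 1)
  Z - X %*% t(object$H)
}

#' Observation-weight map of the fitted decoder
#'
#' Displays per-channel absolute observation weights `|H|` for the six
#' kinematic state dimensions.
#'
#' @param x an [ecog_kalman()].
#' @param ... passed to [graphics::image()].
#' @export
plot.ecog_kalman <- function(x, ...) {
  graphics::image(seq_len(x$n_channels), 1:6, abs(x$H[, 1:6]),
                  xlab = "feature channel", ylab = "state dimension",
                  main = "|H| observation weights", axes = FALSE, ...)
  graphics::axis(1)
  graphics::axis(2, at = 1:6, labels = c("px", "py", "pz", "vx", "vy", "vz"))
  invisible(x)
}
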
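#' Synthetic closed-loop user model
#'
#' Emulates a participant performing cursor tasks: at every control tick the
#' user intends a unit velocity toward the target, corrupted by angular
#' noise, and the model emits a neural feature row linearly coupled to the
#' intended velocity plus sensor noise. Together with
#' [train_user_decoder()] this provides a fully synthetic closed-loop stack.
#'
#' @param n_features number of neural feature channels.
#' @param angle_noise_sd angular noise on the intended direction (radians).
#' @param feature_noise_sd additive feature noise (z-units).
#' @param speed intended cursor speed (screen units/s).
#' @param seed integer seed (fixes the coupling matrix).
#' @return object of class `ecog_user_model` with the coupling matrix `G`
#'   (features x 2) and the noise parameters.
#' @export
make_user_model <- function(n_features = 32L, angle_noise_sd = 0.3,
                            feature_noise_sd = 0.5, speed = 1, seed = 1L) {
  G <- with_seed(seed, matrix(stats::rnorm(n_features * 2L), n_features, 2L))
  structure(
    list(G = G, angle_noise_sd = angle_noise_sd,
         feature_noise_sd = feature_noise_sd, speed = speed),
    class = "ecog_user_model"
  )
}

#' Train a velocity decoder on open-loop user-model data
#'
#' Samples random intended velocities, generates features from the user
#' model and fits the ridge-regularized least-squares map from features to
#' 2-D velocity.
#'
#' @param user an [make_user_model()].
#' @param n_bins training bins.
#' @param seed integer seed.
#' @param lambda ridge penalty.
#' @return a function mapping a feature row to a 2-D velocity estimate.
#' @export
train_user_decoder <- function(user, n_bins = 500L, seed = 2L, lambda = 1e-3) {
  stopifnot(inherits(user, "ecog_user_model"))
  with_seed(seed, {
    ang <- stats::runif(n_bins, 0, 2 * pi)
    V <- user$speed * cbind(cos(ang), sin(ang))
    Z <- V %*% t(user$G) +
      matrix(stats::rnorm(n_bins * nrow(user$G), sd = user$feature_noise_sd),
             n_bins)
    D <- solve(crossprod(Z) + lambda * diag(ncol(Z)), crossprod(Z, V))
    function(z) as.numeric(z %*% D)
  })
}

#' Run the closed-loop cursor task
#'
#' Simulates target-acquisition trials on a normalized `[-1, 1]^2` screen at
#' one control tick per feature bin (100 ms). The commanded cursor velocity
#' blends the decoded velocity with an assistive attractor toward the
#' target:
#' `v = (1 - alpha) * v_decoded + alpha * g * (target - cursor) / ||target - cursor||`
#' (the attractor step is capped so it never overshoots the target). A trial
#' succeeds on a continuous 200 ms in-target dwell within the 4 s limit;
#' otherwise it fails with its full consumed time recorded.
#'
#' @param decoder function mapping a feature row to a 2-D velocity (e.g.
#'   from [train_user_decoder()]), or `NULL` for a pure-assistance run.
#' @param trials list of trial specs from [make_trial_sequence()].
#' @param alpha assistance level in `[0, 1]`; 1 = pure attractor
#'   ("flexible fixturing" during early training), 0 = full volitional
#'   control.
#' @param user an [make_user_model()] generating the feature stream.
#' @param seed integer seed.
#' @param gain assistance gain `g` in screen units/s.
#' @param target_radius in-target radius (normalized screen units).
#' @param tick_s control tick duration (one feature bin).
#' @return list of trial records, each with `spec`, `t_start`, `t_end`,
#'   `success`, `cursor_path` (ticks x 2) and `time_to_target` (s, `NA` on
#'   failure).
#' @export
run_closed_loop <- function(decoder, trials, alpha, user = make_user_model(),
                            seed = 1L, gain = 1.5, target_radius = 0.12,
                            tick_s = 0.1) {
  if (!is_scalar_num(alpha) || alpha < 0 || alpha > 1)
    stopf("assistance alpha must be in [0, 1]")
  stopifnot(inherits(user, "ecog_user_model"))
  hold_ticks <- NULL
  max_ticks <- NULL
  with_seed(seed, {
    lapply(seq_along(trials), function(i) {
      spec <- trials[[i]]
      target <- spec$target_xy
      max_ticks <- ceiling(spec$max_duration / tick_s)
      hold_ticks <- max(1L, ceiling(spec$hold_ms / 1000 / tick_s))
      cursor <- c(0, 0)
      path <- matrix(0, max_ticks + 1L, 2L)
      path[1L, ] <- cursor
      dwell <- 0L
      success <- FALSE
      tick <- 0L
      while (tick < max_ticks) {
        tick <- tick + 1L
        delta <- target - cursor
        dist <- sqrt(sum(delta^2))
        dir <- if (dist > 1e-12) delta / dist else c(0, 0)
        # user intention with angular noise drives the feature stream
        th <- atan2(dir[2L], dir[1L]) + stats::rnorm(1L, sd = user$angle_noise_sd)
        v_int <- user$speed * c(cos(th), sin(th))
        z <- as.numeric(user$G %*% v_int) +
          stats::rnorm(nrow(user$G), sd = user$feature_noise_sd)
        v_dec <- if (is.null(decoder)) c(0, 0) else decoder(z)
        v_assist <- min(gain, dist / tick_s) * dir
        v_cmd <- (1 - alpha) * v_dec + alpha * v_assist
        cursor <- pmin(pmax(cursor + v_cmd * tick_s, -1), 1)
        path[tick + 1L, ] <- cursor
        if (sqrt(sum((target - cursor)^2)) <= target_radius) {
          dwell <- dwell + 1L
          if (dwell >= hold_ticks) { success <- TRUE; break }
        } else dwell <- 0L
      }
      list(spec = spec, t_start = 0, t_end = tick * tick_s, success = success,
           cursor_path = path[seq_len(tick + 1L), , drop = FALSE],
           time_to_target = if (success) tick * tick_s else NA_real_)
    })
  })
}
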
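#' Control parameters for simulation
#'
#' Collects every tunable of the simulated learner in one place, in the style
#' of `glm.control()`. Defaults are the package's standing choices (see the
#' methods vignette for rationale):
#'
#' * `gamma`: proportional gain of the delayed online feedback controller,
#'   per sample; tuned as the largest gain that keeps corrections overdamped
#'   while still pulling the endpoint onto the target.
#' * `delay_samples`: visual feedback delay in samples; 5 samples at 50 Hz
#'   is the 100-ms visual reaction delay.
#' * `lambda`: LMS learning rate of the task (trajectory) network, tuned so a
#'   20-degree rotation is largely (at least 80 percent of the induced
#'   initial-direction error) compensated within 20 trials. [motor_model()]
#'   lowers it for the two-system architecture, whose task network is the
#'   slow system.
#' * `alpha_e`: learning rate of the environment adapter (the "fast" system);
#'   applied per sample as `alpha_e / n_samples` so that the per-trial
#'   effective rate does not depend on the update cadence.
#' * `adapter_cadence`: `"trial"` (default) accumulates the per-instant rank-1
#'   updates over the movement and applies their sum once per trial, on the
#'   same schedule as the task network; `"sample"` applies them at every
#'   time step.
#' * `degree`: monomial degree of the basis-function networks.
#' * `n_samples`: samples per 1-s movement (50 Hz grid plus the origin).
#' * `sigma_bell`: width of the bell-shaped speed profile in normalized time.
#' * `target_dist`: reach amplitude in tablet units.
#' * `cond_threshold`: condition-number guard for plant-model inversion.
#'
#' @param gamma Feedback gain (>= 0).
#' @param delay_samples Feedback delay in samples (>= 0).
#' @param lambda Task-network learning rate.
#' @param alpha_e Environment-adapter learning rate.
#' @param degree Basis-function degree.
#' @param n_samples Samples per movement.
#' @param sigma_bell Bell-profile width.
#' @param target_dist Reach amplitude.
#' @param adapter_cadence `"sample"` or `"trial"`.
#' @param cond_threshold Inversion guard.
#' @return A list of class `"motor_control"`.
#' @export
motor_control <- function(gamma = 0.04, delay_samples = 5, lambda = 0.03,
                          alpha_e = 2, degree = 5, n_samples = 51,
                          sigma_bell = 0.15, target_dist = 1,
                          adapter_cadence = c("trial", "sample"),
                          cond_threshold = 1e6) {
  adapter_cadence <- match.arg(adapter_cadence)
  if (gamma < 0) stop("`gamma` must be non-negative", call. = FALSE)
  if (delay_samples < 0) stop("`delay_samples` must be non-negative", call. = FALSE)
  structure(list(gamma = gamma, delay_samples = as.integer(delay_samples),
                 lambda = lambda, alpha_e = alpha_e, degree = as.integer(degree),
                 n_samples = as.integer(n_samples), sigma_bell = sigma_bell,
                 target_dist = target_dist, adapter_cadence = adapter_cadence,
                 cond_threshold = cond_threshold),
            class = "motor_control")
}

#' Planned velocity sequence
#'
#' First differences of the planned trajectory,
#' \eqn{v_x(t) = x_p(t) - x_p(t-1)}; there is an implicit zero velocity at
#' t = 0, so the returned sequence has one sample fewer than the trajectory.
#'
#' @param planned An n x 2 planned trajectory (n >= 2).
#' @return An (n-1) x 2 matrix of velocities.
#' @export
planned_velocity <- function(planned) {
  xy <- as_trajectory(planned)
  if (nrow(xy) < 2L)
    stop("`planned` must have at least two samples", call. = FALSE)
  out <- diff(xy)
  colnames(out) <- c("x", "y")
  out
}

#' Simulate one closed-loop reaching trial
#'
#' Integrates the motor command sample by sample: command velocity is the
#' planned velocity plus delayed proportional feedback of the on-screen
#' performance error, \eqn{v'(t) = v(t) + \gamma\, e(t - t_d)} and
#' \eqn{x_c(t) = x_c(t-1) + v'_x(t)}. The integrated command is optionally
#' remapped through the environment adapter's inverse
#' (\eqn{[x'_c\,y'_c] = \hat P^{-1} [x_c\,y_c]}), passed through the plant,
#' and the sensed position recorded. Error samples earlier than the delay use
#' zero feedback (the delay line is primed with zeros). The performance error
#' is measured against the desired trajectory at the same time index.
#'
#' When an `adapter` is supplied, the sensory prediction error
#' \eqn{e_p = (x_s, y_s) - \hat P (x'_c, y'_c)} is recorded per sample and the
#' plant model is trained at the cadence given in `control`
#' (per sample, or batched once per trial); the per-sample rate is
#' `alpha_e / n_samples` either way.
#'
#' @param planned Planned trajectory from the task network, n x 2 (or a
#'   [desired_trajectory()] for a perfectly planned movement).
#' @param desired The desired on-screen trajectory (same grid as `planned`).
#' @param env A [rotation_env()] or rotation angle in degrees.
#' @param adapter Optional [plant_model()]; `NULL` for architectures without
#'   an environment adapter.
#' @param control A [motor_control()] list.
#' @param update_adapter Train the adapter during the trial? (default TRUE
#'   when an adapter is supplied).
#' @return A list with `command` (pre-remap integrated command), `hand`
#'   (post-remap pen position actually moved), `sensed` (on-screen positions),
#'   `perf_err` (desired minus sensed, n x 2), `pred_err` (n x 2 or NULL),
#'   `adapter` (updated plant model or NULL) and `times`.
#' @export
closed_loop_trial <- function(planned, desired, env, adapter = NULL,
                              control = motor_control(),
                              update_adapter = !is.null(adapter)) {
  xy_p <- if (inherits(planned, "desired_trajectory")) planned$xy else as_trajectory(planned)
  xy_d <- if (inherits(desired, "desired_trajectory")) desired$xy else as_trajectory(desired)
  n <- nrow(xy_p)
  if (nrow(xy_d) != n)
    stop("`planned` and `desired` must share one time grid", call. = FALSE)
  P <- if (inherits(env, "rotation_env")) env$P else rotation_matrix(env)
  gamma <- control$gamma
  d <- control$delay_samples
  per_sample <- identical(control$adapter_cadence, "sample")

  vx <- c(0, diff(xy_p[, 1L]))
  vy <- c(0, diff(xy_p[, 2L]))
  cmd <- matrix(0, n, 2L); hand <- matrix(0, n, 2L); sensed <- matrix(0, n, 2L)
  ex <- numeric(n); ey <- numeric(n)
  use_adapter <- !is.null(adapter)
  if (use_adapter) {
    stopifnot(inherits(adapter, "plant_model"))
    Phat <- adapter$Phat
    Minv <- invert_model(adapter)
    a_rate <- adapter$alpha_e / n
    epx <- numeric(n); epy <- numeric(n)
  }

  cx <- 0; cy <- 0
  for (j in seq_len(n)) {
    fx <- if (j > d) ex[[j - d]] else 0
    fy <- if (j > d) ey[[j - d]] else 0
    cx <- cx + vx[[j]] + gamma * fx
    cy <- cy + vy[[j]] + gamma * fy
    if (use_adapter) {
      hx <- Minv[1L, 1L] * cx + Minv[1L, 2L] * cy
      hy <- Minv[2L, 1L] * cx + Minv[2L, 2L] * cy
    } else {
      hx <- cx; hy <- cy
    }
    sx <- P[1L, 1L] * hx + P[1L, 2L] * hy
    sy <- P[2L, 1L] * hx + P[2L, 2L] * hy
    ex[[j]] <- xy_d[[j, 1L]] - sx
    ey[[j]] <- xy_d[[j, 2L]] - sy
    cmd[[j, 1L]] <- cx; cmd[[j, 2L]] <- cy
    hand[[j, 1L]] <- hx; hand[[j, 2L]] <- hy
    sensed[[j, 1L]] <- sx; sensed[[j, 2L]] <- sy
    if (use_adapter) {
      px <- Phat[1L, 1L] * hx + Phat[1L, 2L] * hy
      py <- Phat[2L, 1L] * hx + Phat[2L, 2L] * hy
      epx[[j]] <- sx - px
      epy[[j]] <- sy - py
      if (update_adapter && per_sample) {
        Phat[1L, 1L] <- Phat[1L, 1L] + a_rate * epx[[j]] * hx
        Phat[1L, 2L] <- Phat[1L, 2L] + a_rate * epx[[j]] * hy
        Phat[2L, 1L] <- Phat[2L, 1L] + a_rate * epy[[j]] * hx
        Phat[2L, 2L] <- Phat[2L, 2L] + a_rate * epy[[j]] * hy
        Mnew <- inv2(Phat)
        if (!is.null(Mnew)) Minv <- Mnew   # keep last good inverse otherwise
      }
    }
  }
  colnames(cmd) <- colnames(hand) <- colnames(sensed) <- c("x", "y")
  perf_err <- cbind(x = ex, y = ey)
  pred_err <- NULL
  if (use_adapter) {
    pred_err <- cbind(x = epx, y = epy)
    if (update_adapter && !per_sample)
      Phat <- Phat + a_rate * crossprod(pred_err, hand)
    dimnames(Phat) <- NULL
    adapter$Phat <- Phat
  }
  list(command = cmd, hand = hand, sensed = sensed,
       perf_err = perf_err, pred_err = pred_err,
       adapter = if (use_adapter) adapter else NULL,
       times = seq(0, 1, length.out = n))
}

#' Tidy per-sample trace of a simulated trial
#'
#' @param trial The list returned by [closed_loop_trial()].
#' @return A data frame with columns `t`, `x_c`, `y_c`, `x_s`, `y_s`, `x_e`,
#'   `y_e`, suitable for plotting individual reach paths.
#' @export
trial_trace <- function(trial) {
  data.frame(t = trial$times,
             x_c = trial$command[, 1L], y_c = trial$command[, 2L],
             x_s = trial$sensed[, 1L], y_s = trial$sensed[, 2L],
             x_e = trial$perf_err[, 1L], y_e = trial$perf_err[, 2L])
}
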
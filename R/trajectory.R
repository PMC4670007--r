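#' Desired straight-line trajectory with a bell-shaped speed profile
#'
#' Generates the trajectory the learner "hopes" to see on screen: a straight
#' line from the origin to the target with a bell-shaped speed profile. The
#' bell is a Gaussian in normalized time, truncated to \[0, 1\] and lowered by
#' its boundary value so the speed is exactly zero at movement start and end;
#' cumulative displacement is rescaled so the path ends exactly on the target.
#'
#' @param target_deg Target direction in degrees (counterclockwise from
#'   straight up).
#' @param target_dist Distance to the target (tablet units, default 1).
#' @param n_samples Number of samples on the normalized time grid \[0, 1\]
#'   (default 51, i.e. 50 Hz over a 1-s movement).
#' @param sigma_bell Width of the Gaussian speed bump in normalized time
#'   (default 0.15).
#' @return An object of class `"desired_trajectory"`: list with `times`
#'   (normalized grid), `xy` (n x 2 positions), `target_deg`, `target_dist`.
#' @export
desired_trajectory <- function(target_deg, target_dist = 1, n_samples = 51,
                               sigma_bell = 0.15) {
  if (!(is.numeric(n_samples) && length(n_samples) == 1L && n_samples >= 3))
    stop("`n_samples` must be at least 3", call. = FALSE)
  if (!(is.numeric(target_dist) && target_dist > 0))
    stop("`target_dist` must be positive", call. = FALSE)
  n <- as.integer(n_samples)
  times <- seq(0, 1, length.out = n)
  prof <- exp(-(times - 0.5)^2 / (2 * sigma_bell^2))
  prof <- pmax(prof - prof[[1L]], 0)          # zero speed at both boundaries
  step <- (prof[-1L] + prof[-n]) / 2          # trapezoidal per-step displacement
  s <- c(0, cumsum(step))
  s <- s * (target_dist / s[[n]])
  u <- direction_vector(target_deg)
  structure(list(times = times,
                 xy = cbind(x = s * u[[1L]], y = s * u[[2L]]),
                 target_deg = target_deg, target_dist = target_dist),
            class = "desired_trajectory")
}

#' Basis-function network weights
#'
#' The task-learning network: planned x and y positions are weighted sums of
#' monomials of normalized time, \eqn{x_p(t) = \sum_i W_{xi} t^i} for
#' \eqn{i = 0, \dots, n}. Weights start at zero unless supplied.
#'
#' @param degree Highest monomial degree (default 5).
#' @param Wx,Wy Weight vectors of length `degree + 1` (including the
#'   degree-0 term).
#' @return An object of class `"bf_network"`.
#' @export
bf_network <- function(degree = 5, Wx = numeric(degree + 1),
                       Wy = numeric(degree + 1)) {
  degree <- as.integer(degree)
  if (degree < 0) stop("`degree` must be non-negative", call. = FALSE)
  if (length(Wx) != degree + 1L || length(Wy) != degree + 1L)
    stop("`Wx` and `Wy` must have length degree + 1", call. = FALSE)
  structure(list(degree = degree, Wx = as.numeric(Wx), Wy = as.numeric(Wy)),
            class = "bf_network")
}

# Design matrix of monomial basis functions Phi_i(t) = t^i, i = 0..degree.
bf_design <- function(times, degree) {
  outer(as.numeric(times), 0:degree, `^`)
}

#' Evaluate a basis-function network on a time grid
#'
#' @param w A [bf_network()].
#' @param times Numeric grid of normalized times in \[0, 1\].
#' @return An n x 2 matrix of planned positions.
#' @export
eval_network <- function(w, times) {
  stopifnot(inherits(w, "bf_network"))
  Phi <- bf_design(times, w$degree)
  cbind(x = drop(Phi %*% w$Wx), y = drop(Phi %*% w$Wy))
}

# Coerce a performance/prediction error to an n x 2 matrix.
as_error <- function(err) {
  if (is.list(err) && !is.data.frame(err) && all(c("xe", "ye") %in% names(err)))
    err <- cbind(err$xe, err$ye)
  as_trajectory(err)
}

#' Widrow-Hoff (LMS) update of the task network
#'
#' One batch update from a whole movement's performance error:
#' \eqn{\Delta W_{xi} = \lambda \sum_j x_e(t_j)\,\Phi_i(t_j)} (and likewise
#' for y). The update is applied once per trial using the errors from the
#' whole movement, and equals one batch gradient-descent step with step size
#' `lambda` on the quadratic cost \eqn{\frac12\sum_j (x_e^2 + y_e^2)}.
#'
#' @param w A [bf_network()].
#' @param err Performance error, n x 2 (desired minus sensed).
#' @param times Time grid matching `err`.
#' @param lambda Learning rate (> 0).
#' @return The updated network.
#' @export
lms_update <- function(w, err, times, lambda) {
  stopifnot(inherits(w, "bf_network"))
  err <- as_error(err)
  if (nrow(err) != length(times))
    stop("`err` and `times` must have the same length", call. = FALSE)
  if (!(is.numeric(lambda) && length(lambda) == 1L && lambda > 0))
    stop("`lambda` must be a positive number", call. = FALSE)
  Phi <- bf_design(times, w$degree)
  w$Wx <- w$Wx + lambda * drop(crossprod(Phi, err[, 1L]))
  w$Wy <- w$Wy + lambda * drop(crossprod(Phi, err[, 2L]))
  w
}

#' Trial cost: integrated error norm
#'
#' The cost the trajectory generator minimizes: the Euclidean norm of the
#' performance error integrated over the movement, approximated as a Riemann
#' sum \eqn{\epsilon = \sum_j \|(x_e(t_j), y_e(t_j))\| \, dt}.
#'
#' @param err Performance error, n x 2.
#' @param dt Time step (> 0).
#' @return A non-negative scalar.
#' @export
trial_cost <- function(err, dt) {
  if (!(is.numeric(dt) && length(dt) == 1L && dt > 0))
    stop("`dt` must be a positive number", call. = FALSE)
  err <- as_error(err)
  sum(sqrt(rowSums(err^2))) * dt
}

#' Least-squares fit of a network to a desired trajectory
#'
#' Direct polynomial least-squares fit of the desired path, used to spawn a
#' "pretrained-shape" network for a target that was never practiced, and as a
#' closed-form reference for what LMS training converges to in the veridical
#' environment.
#'
#' @param desired A [desired_trajectory()].
#' @param degree Monomial degree of the network (default 5).
#' @return A [bf_network()] fitted by least squares.
#' @export
fit_network_ls <- function(desired, degree = 5) {
  stopifnot(inherits(desired, "desired_trajectory"))
  Phi <- bf_design(desired$times, degree)
  bf_network(degree,
             Wx = qr.solve(Phi, desired$xy[, 1L]),
             Wy = qr.solve(Phi, desired$xy[, 2L]))
}
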
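#' Plant model (environment adapter state)
#'
#' The environment-learning system of the two-system architecture: a 2x2
#' estimated forward model \eqn{\hat P} of the plant, trained on sensory
#' prediction error and inverted to remap motor commands. `Phat` starts at the
#' identity, i.e. a model perfectly adapted to the veridical (unrotated)
#' environment.
#'
#' @param Phat 2x2 estimated forward matrix (default identity).
#' @param alpha_e Learning rate of the adapter.
#' @param cond_threshold Condition-number threshold above which
#'   [invert_model()] switches to a ridge-regularized inverse.
#' @return An object of class `"plant_model"`.
#' @export
plant_model <- function(Phat = diag(2), alpha_e = 2, cond_threshold = 1e6) {
  Phat <- as.matrix(Phat)
  if (!all(dim(Phat) == c(2L, 2L)) || !all(is.finite(Phat)))
    stop("`Phat` must be a finite 2x2 matrix", call. = FALSE)
  if (!(is.numeric(alpha_e) && alpha_e >= 0))
    stop("`alpha_e` must be non-negative", call. = FALSE)
  structure(list(Phat = Phat, alpha_e = alpha_e,
                 cond_threshold = cond_threshold),
            class = "plant_model")
}

#' @export
print.plant_model <- function(x, ...) {
  cat("Plant (forward) model Phat:\n")
  print(round(x$Phat, 6))
  cat(sprintf("implied rotation: %+.3f deg; alpha_e = %g\n",
              implied_rotation(x), x$alpha_e))
  invisible(x)
}

#' Rotation angle implied by a plant model
#'
#' The angle of the nearest rotation matrix to `Phat` (via the polar
#' decomposition of its symmetric/antisymmetric parts). Useful as a one-number
#' summary of what the adapter currently believes the environment is.
#'
#' @param m A [plant_model()].
#' @return Angle in degrees, clockwise-positive like the plant itself.
#' @export
implied_rotation <- function(m) {
  P <- m$Phat
  atan2((P[1L, 2L] - P[2L, 1L]) / 2, (P[1L, 1L] + P[2L, 2L]) / 2) * 180 / pi
}

#' Predict sensed positions from a plant model
#'
#' @param object A [plant_model()].
#' @param newdata Commands: an n x 2 matrix or a single 2-vector.
#' @param ... Unused.
#' @return Predicted sensed positions, n x 2.
#' @export
predict.plant_model <- function(object, newdata, ...) {
  xy <- as_trajectory(newdata)
  if (nrow(xy) == 0L) return(xy)
  out <- xy %*% t(object$Phat)
  colnames(out) <- c("x", "y")
  out
}

#' LMS update of the plant model
#'
#' The printed per-instant rank-1 rule
#' \eqn{\Delta \hat P = \alpha_e \, e_p \, [x'_c\; y'_c]^T}: the outer product
#' of the prediction error with the issued command.
#'
#' @param m A [plant_model()].
#' @param ep Prediction error, a 2-vector (sensed minus predicted).
#' @param cmd_prime The issued (remapped) command, a 2-vector.
#' @param rate Learning rate; defaults to `m$alpha_e`.
#' @return The updated plant model.
#' @export
adapter_update <- function(m, ep, cmd_prime, rate = m$alpha_e) {
  stopifnot(inherits(m, "plant_model"))
  ep <- as.numeric(ep); cmd_prime <- as.numeric(cmd_prime)
  if (length(ep) != 2L || length(cmd_prime) != 2L ||
      !all(is.finite(ep)) || !all(is.finite(cmd_prime)))
    stop("`ep` and `cmd_prime` must be finite 2-vectors", call. = FALSE)
  m$Phat <- m$Phat + rate * (ep %o% cmd_prime)
  m
}

# Closed-form 2x2 inverse; NULL when (near-)singular.
inv2 <- function(P) {
  d <- P[1L, 1L] * P[2L, 2L] - P[1L, 2L] * P[2L, 1L]
  if (!is.finite(d) || abs(d) < 1e-14) return(NULL)
  matrix(c(P[2L, 2L], -P[2L, 1L], -P[1L, 2L], P[1L, 1L]), 2L, 2L) / d
}

#' Invert the plant model
#'
#' Exact 2x2 inverse when well-conditioned. When the condition number exceeds
#' `cond_threshold` a Tikhonov-regularized inverse is returned (ridge
#' `1e-8 * |trace|`); an exactly singular model raises an error of class
#' `"rotadapt_degenerate_model"` so callers can fall back to an identity remap.
#'
#' @param m A [plant_model()].
#' @return A 2x2 matrix, the environment inverse \eqn{\hat P^{-1}}.
#' @export
invert_model <- function(m) {
  stopifnot(inherits(m, "plant_model"))
  P <- m$Phat
  d <- P[1L, 1L] * P[2L, 2L] - P[1L, 2L] * P[2L, 1L]
  if (d == 0)
    stop(errorCondition("degenerate plant model: Phat is exactly singular",
                        class = c("rotadapt_degenerate_model", "error", "condition")))
  if (kappa(P, exact = TRUE) > m$cond_threshold) {
    ridge <- 1e-8 * max(abs(P[1L, 1L] + P[2L, 2L]), .Machine$double.eps)
    return(solve(crossprod(P) + ridge * diag(2), t(P)))
  }
  solve(P)
}

#' Remap a command trajectory through the environment inverse
#'
#' Left-multiplies every command sample by \eqn{\hat P^{-1}}; with a converged
#' model, passing the remapped command through the plant recovers the original
#' command.
#'
#' @param inv A 2x2 matrix (usually from [invert_model()]).
#' @param command An n x 2 matrix of command positions.
#' @return The remapped command trajectory, n x 2.
#' @export
remap_command <- function(inv, command) {
  xy <- as_trajectory(command)
  if (nrow(xy) == 0L) return(xy)
  out <- xy %*% t(inv)
  colnames(out) <- c("x", "y")
  out
}
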
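#' Rotation matrix of the visuomotor plant
#'
#' The plant maps a motor command (a pen-tablet position) to the sensed
#' on-screen position by rotating it through `theta_deg`. With the package's
#' angle convention (angles measured counterclockwise from straight up, in a
#' y-up screen frame) a positive `theta_deg` is a clockwise screen rotation:
#' a command heading at angle `a` is displayed at angle `a - theta_deg`.
#'
#' @param theta_deg Rotation angle in degrees; positive rotates the display
#'   clockwise.
#' @return A 2x2 orthonormal matrix `[[cos, sin], [-sin, cos]]` (angles in
#'   radians internally).
#' @examples
#' rotation_matrix(0)                    # identity
#' rotation_matrix(90) %*% c(1, 0)       # (0, -1)
#' @export
rotation_matrix <- function(theta_deg) {
  if (!is.numeric(theta_deg) || length(theta_deg) != 1L || !is.finite(theta_deg))
    stop("`theta_deg` must be a single finite number", call. = FALSE)
  th <- theta_deg * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
}

#' Rotation environment
#'
#' A lightweight container for the plant: the rotation angle and its matrix.
#'
#' @param theta_deg Rotation angle in degrees (positive = clockwise on screen).
#' @return An object of class `"rotation_env"`.
#' @export
rotation_env <- function(theta_deg) {
  structure(list(theta_deg = theta_deg, P = rotation_matrix(theta_deg)),
            class = "rotation_env")
}

#' @export
print.rotation_env <- function(x, ...) {
  cat(sprintf("Visuomotor rotation environment: theta = %g deg (clockwise on screen)\n",
              x$theta_deg))
  invisible(x)
}

#' Unit vector for a reach direction
#'
#' Angles are measured counterclockwise from straight up (0 degrees = straight
#' up), the convention used throughout the package for targets, commands and
#' initial directions.
#'
#' @param angle_deg Direction in degrees.
#' @return A length-2 unit vector (x, y).
#' @export
direction_vector <- function(angle_deg) {
  a <- angle_deg * pi / 180
  c(-sin(a), cos(a))
}

#' Direction angle of a displacement
#'
#' Inverse of [direction_vector()]: the angle (degrees, counterclockwise from
#' straight up) of a 2-D displacement.
#'
#' @param v A length-2 numeric vector.
#' @return Angle in degrees in (-180, 180].
#' @export
direction_angle <- function(v) {
  atan2(-v[[1L]], v[[2L]]) * 180 / pi
}

# Coerce positions to an n x 2 matrix with columns x, y.
as_trajectory <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy)
  if (is.null(dim(xy))) {
    if (length(xy) == 0L)
      return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
    if (length(xy) != 2L)
      stop("a trajectory must be an n x 2 matrix of x/y positions", call. = FALSE)
    xy <- matrix(xy, 1L, 2L)
  }
  if (ncol(xy) != 2L)
    stop("a trajectory must be an n x 2 matrix of x/y positions", call. = FALSE)
  if (nrow(xy) > 0L && !all(is.finite(xy)))
    stop("trajectory contains non-finite positions", call. = FALSE)
  colnames(xy) <- c("x", "y")
  xy
}

#' Pass a command trajectory through the plant
#'
#' Rotates every sample of a command trajectory by the environment's rotation.
#' Sample count and per-sample Euclidean norm are preserved; an empty
#' trajectory maps to an empty trajectory.
#'
#' @param env A [rotation_env()] or a rotation angle in degrees.
#' @param command An n x 2 matrix of positions (or a single 2-vector).
#' @return The sensed (on-screen) trajectory, n x 2.
#' @export
apply_plant <- function(env, command) {
  P <- if (inherits(env, "rotation_env")) env$P else rotation_matrix(env)
  xy <- as_trajectory(command)
  if (nrow(xy) == 0L) return(xy)
  out <- xy %*% t(P)
  colnames(out) <- c("x", "y")
  out
}

#' Block schedule for one experiment
#'
#' Every experiment is three blocks (state A: baseline, state B: interference,
#' state C: re-adaptation) of reaching trials. The baseline visual environment
#' is rotated 10 degrees clockwise (`theta = +10`); interference changes are
#' relative to baseline. States A and C are always identical.
#'
#' * Experiment 1 (same task, different environment): interference rotates the
#'   feedback 20 degrees counterclockwise relative to baseline; the target does
#'   not move.
#' * Experiment 2 (different task, same environment): the rotation is
#'   unchanged but the target moves (20 -> 40 degrees).
#' * Experiment 3 (different task, different environment): the 20-degree
#'   counterclockwise rotation is paired with a 20-degree target shift in the
#'   opposite direction so the required hand movement is unchanged.
#' * Experiment 4 is a display-matched control of experiment 3 and is
#'   computationally identical to it, so it returns the same schedule.
#'
#' The `"90deg"` variant uses targets at 90/180/270 degrees and a 90-degree
#' rotation between environments.
#'
#' @param experiment Integer 1, 2, 3 or 4.
#' @param variant `"20deg"` (default) or `"90deg"`.
#' @return An object of class `"env_schedule"`: a list with `experiment`,
#'   `variant`, `thetas` (per-block rotation, degrees) and `targets`
#'   (per-block target direction, degrees).
#' @examples
#' make_schedule(1)          # thetas +10/-10/+10, target 20 throughout
#' make_schedule(3)$targets  # 20, 40, 20
#' @export
make_schedule <- function(experiment, variant = c("20deg", "90deg")) {
  variant <- match.arg(variant)
  if (!(is.numeric(experiment) && length(experiment) == 1L && experiment %in% 1:4))
    stop("`experiment` must be 1, 2, 3 or 4", call. = FALSE)
  base <- 10
  if (variant == "20deg") {
    rotated <- base - 20; t1 <- 20; t2 <- 40
  } else {
    rotated <- base - 90; t1 <- 90; t2 <- 180
  }
  thetas <- switch(as.character(experiment),
    "1" = c(base, rotated, base),
    "2" = c(base, base, base),
    "3" = ,
    "4" = c(base, rotated, base))
  targets <- switch(as.character(experiment),
    "1" = c(t1, t1, t1),
    "2" = ,
    "3" = ,
    "4" = c(t1, t2, t1))
  structure(list(experiment = as.integer(experiment), variant = variant,
                 thetas = thetas, targets = targets),
            class = "env_schedule")
}

#' @export
print.env_schedule <- function(x, ...) {
  cat(sprintf("Experiment %d (%s variant)\n", x$experiment, x$variant))
  b <- c("A (baseline)", "B (interference)", "C (re-adaptation)")
  for (i in 1:3)
    cat(sprintf("  %-18s theta = %+4g deg, target = %4g deg\n",
                b[i], x$thetas[i], x$targets[i]))
  invisible(x)
}

#' Hand direction required to hit an on-screen target
#'
#' Under a clockwise screen rotation `theta_deg`, the hand must aim
#' `target_deg + theta_deg` for the cursor to head at `target_deg`.
#'
#' @param target_deg On-screen target direction (degrees).
#' @param theta_deg Plant rotation (degrees).
#' @return Required hand direction in degrees.
#' @export
hand_direction <- function(target_deg, theta_deg) target_deg + theta_deg

#' Read or write a block schedule as YAML
#'
#' Plain-text serialization with keys `experiment`, `variant`, `thetas` and
#' `targets`; angles are always in degrees.
#'
#' @param schedule An `"env_schedule"` object.
#' @param path File path.
#' @return `read_schedule()` returns an `"env_schedule"`; `write_schedule()`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "env_schedule"))
  yaml::write_yaml(list(experiment = schedule$experiment,
                        variant = schedule$variant,
                        thetas = schedule$thetas,
                        targets = schedule$targets), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("experiment", "variant", "thetas", "targets")
  if (!all(need %in% names(x)))
    stop("schedule file must define experiment, variant, thetas and targets",
         call. = FALSE)
  structure(list(experiment = as.integer(x$experiment), variant = x$variant,
                 thetas = as.numeric(x$thetas), targets = as.numeric(x$targets)),
            class = "env_schedule")
}
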
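#' Initial movement direction of a reach
#'
#' The angle of the line connecting the start location to the point of
#' maximum speed — the standard feedforward readout, largely uncontaminated
#' by late online correction. Speed is computed by central finite differences
#' (one-sided at the ends); ties go to the earliest sample.
#'
#' @param traj An n x 2 trajectory (n >= 3) sampled on a uniform grid.
#' @return The initial direction in degrees (counterclockwise from straight
#'   up). A movement whose max-speed point coincides with the start raises an
#'   error of class `"rotadapt_undefined_direction"`.
#' @export
initial_direction <- function(traj) {
  xy <- as_trajectory(traj)
  n <- nrow(xy)
  if (n < 3L) stop("`traj` must have at least 3 samples", call. = FALSE)
  speed <- numeric(n)
  dx <- diff(xy[, 1L]); dy <- diff(xy[, 2L])
  speed[1L] <- sqrt(dx[1L]^2 + dy[1L]^2)
  speed[n] <- sqrt(dx[n - 1L]^2 + dy[n - 1L]^2)
  mid <- 2:(n - 1L)
  speed[mid] <- sqrt((xy[mid + 1L, 1L] - xy[mid - 1L, 1L])^2 +
                     (xy[mid + 1L, 2L] - xy[mid - 1L, 2L])^2) / 2
  j <- which.max(speed)                      # earliest maximum
  disp <- xy[j, ] - xy[1L, ]
  if (all(disp == 0))
    stop(errorCondition("initial direction undefined: no displacement at the point of maximum speed",
                        class = c("rotadapt_undefined_direction", "error", "condition")))
  direction_angle(disp)
}

# Accept a motor_session or a bare trial table.
session_trials <- function(session) {
  tr <- if (inherits(session, "motor_session")) session$trials else session
  if (!is.data.frame(tr) ||
      !all(c("block", "initial_direction_deg") %in% names(tr)))
    stop("a session needs columns `block` and `initial_direction_deg`",
         call. = FALSE)
  tr
}

#' Baseline statistics of a session
#'
#' Sample mean and sample (n-1) standard deviation of the initial directions
#' of the last ten baseline (state A) trials.
#'
#' @param session A `"motor_session"` or a trial data frame with columns
#'   `block` and `initial_direction_deg`.
#' @param n_baseline How many final state-A trials to use (default 10).
#' @return Named numeric vector `c(mu, sigma)` in degrees.
#' @export
baseline_stats <- function(session, n_baseline = 10) {
  tr <- session_trials(session)
  a <- tr$initial_direction_deg[tr$block == "A"]
  if (length(a) < n_baseline)
    stop(sprintf("state A must have at least %d trials", n_baseline),
         call. = FALSE)
  a <- utils::tail(a, n_baseline)
  c(mu = mean(a), sigma = stats::sd(a))
}

#' Aftereffect z-score of one session
#'
#' The magnitude of the aftereffect: the first state-C initial direction
#' expressed as a z-score against the baseline distribution estimated from
#' the last ten state-A trials, \eqn{Z = (x_{c1} - \mu)/\sigma}. The
#' aftereffect is flagged significant when \eqn{|Z|} exceeds the two-sided
#' standard-normal critical value (1.96 at `alpha = 0.05`).
#'
#' A degenerate baseline (`sigma = 0`, possible for noiseless simulations) is
#' reported with `degenerate = TRUE`, a signed infinite z, and significance
#' defined by `x_c1 != mu` rather than by a silent division.
#'
#' @param session A `"motor_session"` or trial data frame.
#' @param alpha Two-sided significance level (default 0.05).
#' @return An object of class `"aftereffect"`: list with `mu`, `sigma`,
#'   `x_c1`, `z`, `significant`, `degenerate`, `alpha`, `experiment`, `id`.
#' @export
aftereffect <- function(session, alpha = 0.05) {
  tr <- session_trials(session)
  cc <- tr$initial_direction_deg[tr$block == "C"]
  if (length(cc) == 0L) stop("state C is empty", call. = FALSE)
  bs <- baseline_stats(session)
  x_c1 <- cc[[1L]]
  z_crit <- stats::qnorm(1 - alpha / 2)
  if (bs[["sigma"]] == 0) {
    z <- if (x_c1 == bs[["mu"]]) 0 else sign(x_c1 - bs[["mu"]]) * Inf
    sig <- x_c1 != bs[["mu"]]
    degen <- TRUE
  } else {
    z <- (x_c1 - bs[["mu"]]) / bs[["sigma"]]
    sig <- abs(z) > z_crit
    degen <- FALSE
  }
  structure(list(mu = bs[["mu"]], sigma = bs[["sigma"]], x_c1 = x_c1, z = z,
                 significant = sig, degenerate = degen, alpha = alpha,
                 experiment = if (inherits(session, "motor_session")) session$experiment else NA_integer_,
                 id = if (inherits(session, "motor_session")) session$id else NA_character_),
            class = "aftereffect")
}

#' @export
print.aftereffect <- function(x, ...) {
  cat(sprintf("Aftereffect z = %.3f (baseline mu = %.2f deg, sigma = %.3f deg, first state-C trial = %.2f deg)\n",
              x$z, x$mu, x$sigma, x$x_c1))
  if (x$degenerate)
    cat("  [degenerate baseline: sigma = 0; significance means x_c1 != mu]\n")
  cat(sprintf("  %s at alpha = %g\n",
              if (x$significant) "SIGNIFICANT" else "not significant", x$alpha))
  invisible(x)
}

#' Aftereffect table for a set of sessions
#'
#' @param sessions A list of sessions (each a `"motor_session"` or trial
#'   data frame).
#' @param alpha Two-sided significance level.
#' @return A data frame with one row per session: `id`, `experiment`, `mu`,
#'   `sigma`, `x_c1`, `z`, `significant`, `degenerate`.
#' @export
aftereffect_table <- function(sessions, alpha = 0.05) {
  rows <- lapply(sessions, function(s) {
    a <- aftereffect(s, alpha)
    data.frame(id = a$id, experiment = a$experiment, mu = a$mu,
               sigma = a$sigma, x_c1 = a$x_c1, z = a$z,
               significant = a$significant, degenerate = a$degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count significant aftereffects per experiment
#'
#' @param sessions A list of sessions.
#' @param alpha Two-sided significance level.
#' @return A named integer vector: number of sessions with a significant
#'   aftereffect, per experiment.
#' @export
count_significant <- function(sessions, alpha = 0.05) {
  tab <- aftereffect_table(sessions, alpha)
  out <- tapply(tab$significant, tab$experiment, sum)
  stats::setNames(as.integer(out), paste0("exp", names(out)))
}

#' Paired last-baseline / first-readaptation table
#'
#' The table fed to group-level statistics (repeated-measures ANOVA and
#' post-hoc tests, run with standard routines outside this package): for
#' every session, the initial direction of the last state-A trial and of the
#' first state-C trial.
#'
#' @param sessions A list of sessions.
#' @return A long data frame with columns `id`, `experiment`, `state`
#'   (`"A"` or `"C"`) and `initial_direction_deg`; two rows per session.
#' @export
group_last_first_table <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    tr <- session_trials(s)
    a <- tr$initial_direction_deg[tr$block == "A"]
    cc <- tr$initial_direction_deg[tr$block == "C"]
    if (length(a) == 0L || length(cc) == 0L)
      stop("blocks A and C must be nonempty", call. = FALSE)
    exp_id <- if (inherits(s, "motor_session")) s$experiment else NA_integer_
    id <- if (inherits(s, "motor_session")) s$id else NA_character_
    data.frame(id = id, experiment = exp_id, state = c("A", "C"),
               initial_direction_deg = c(a[[length(a)]], cc[[1L]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
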
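#' Parameters of the synthetic session generator
#'
#' The generator is a deliberately phenomenological stand-in for human
#' participants: per-trial initial directions follow the block schedule with
#' exponentially decaying jumps at block transitions plus Gaussian
#' measurement noise. It shares nothing with the mechanistic simulator, so it
#' provides known ground truth for validating the analysis pipeline.
#'
#' @param n_participants Number of synthetic participants (default 10).
#' @param adaptation_rate Fraction of the remaining error removed per trial,
#'   in (0, 1\] (default 0.25).
#' @param noise_sd SD of trial-to-trial direction noise in degrees
#'   (default 3).
#' @param aftereffect_frac Fraction of the block-B adapted amount expressed as
#'   the (opposite-signed) block-C jump, in \[0, 1\] (default 0.9).
#' @param seed Integer seed; every session is reproducible from
#'   (seed, experiment, participant).
#' @return An object of class `"synth_params"`.
#' @export
synth_params <- function(n_participants = 10, adaptation_rate = 0.25,
                         noise_sd = 3, aftereffect_frac = 0.9, seed = 1) {
  if (!(adaptation_rate > 0 && adaptation_rate <= 1))
    stop("`adaptation_rate` must be in (0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (!(aftereffect_frac >= 0 && aftereffect_frac <= 1))
    stop("`aftereffect_frac` must be in [0, 1]", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 adaptation_rate = adaptation_rate, noise_sd = noise_sd,
                 aftereffect_frac = aftereffect_frac, seed = as.integer(seed)),
            class = "synth_params")
}

# Evaluate an expression with a local, restored RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

synth_session_seed <- function(p, experiment, participant) {
  (p$seed %% 1009L) * 1663L + as.integer(experiment) * 211L +
    as.integer(participant)
}

#' Generate one synthetic participant session
#'
#' Initial directions per block: state A is the target plus a decaying
#' residual (for experiment 1, the on-screen consequence of meeting the
#' +10-degree baseline field naively; zero for the later experiments, whose
#' baseline was retained); state B jumps by the on-screen consequence of the
#' block-B environment change (`theta_A - theta_B`; zero in experiment 2,
#' where only the target moves); state C jumps by `-aftereffect_frac` times
#' the amount adapted in block B. Each jump decays by `adaptation_rate` per
#' trial, and Gaussian noise of SD `noise_sd` is added to every trial.
#'
#' @param p A [synth_params()].
#' @param experiment Integer 1-4.
#' @param variant `"20deg"` or `"90deg"`.
#' @param participant Participant index (used for seeding and the session id).
#' @param trials_per_block Trials per block (default 20).
#' @return A `"motor_session"` with a 60-trial record.
#' @export
synth_session <- function(p, experiment, variant = "20deg", participant = 1,
                          trials_per_block = 20) {
  stopifnot(inherits(p, "synth_params"))
  sched <- make_schedule(experiment, variant)
  decay <- 1 - p$adaptation_rate
  nb <- trials_per_block
  jump_a <- if (experiment == 1) -sched$thetas[[1L]] else 0
  jump_b <- sched$thetas[[1L]] - sched$thetas[[2L]]
  adapted_b <- jump_b * (1 - decay^nb)
  jump_c <- -p$aftereffect_frac * adapted_b
  jumps <- c(jump_a, jump_b, jump_c)
  dirs <- with_local_seed(synth_session_seed(p, experiment, participant), {
    unlist(lapply(1:3, function(b)
      sched$targets[[b]] + jumps[[b]] * decay^(seq_len(nb) - 1) +
        stats::rnorm(nb, 0, p$noise_sd)))
  })
  trials <- data.frame(trial = seq_len(3L * nb),
                       block = rep(c("A", "B", "C"), each = nb),
                       target_deg = rep(sched$targets, each = nb),
                       theta_deg = rep(sched$thetas, each = nb),
                       initial_direction_deg = dirs,
                       trial_cost = NA_real_, success = NA)
  new_motor_session(experiment, variant,
                    sprintf("participant_%d", as.integer(participant)), trials)
}

#' Generate all synthetic sessions for one experiment
#'
#' @param p A [synth_params()].
#' @param experiment Integer 1-4.
#' @param variant `"20deg"` or `"90deg"`.
#' @return A list of `p$n_participants` sessions.
#' @export
synth_experiment <- function(p, experiment, variant = "20deg") {
  lapply(seq_len(p$n_participants),
         function(i) synth_session(p, experiment, variant, i))
}

#' Write sessions of one experiment in the deposited-dataset CSV layout
#'
#' One file per experiment: one row per trial (60 = 3 blocks x 20), one
#' column of initial angles (degrees) per participant, plus a `target` column
#' (degrees). Comma-separated, header row, decimal point, UTF-8.
#'
#' @param sessions A list of sessions from one experiment, with identical
#'   trial counts and targets.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions_csv <- function(sessions, path) {
  if (length(sessions) == 0L) stop("no sessions to write", call. = FALSE)
  trs <- lapply(sessions, session_trials)
  n <- nrow(trs[[1L]])
  if (!all(vapply(trs, nrow, 0L) == n))
    stop("all sessions in one file must have the same trial count", call. = FALSE)
  ids <- vapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    if (inherits(s, "motor_session") && !is.na(s$id) && nzchar(s$id)) s$id
    else sprintf("participant_%d", i)
  }, "")
  cols <- lapply(trs, function(tr) tr$initial_direction_deg)
  names(cols) <- make.unique(ids)
  cols$target <- trs[[1L]]$target_deg
  # full-precision text so that read . write is the identity on the numbers
  cols <- lapply(cols, function(x) sprintf("%.17g", x))
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sessions from the deposited-dataset CSV layout
#'
#' Accepts any header: the column named like "target" (case-insensitive) is
#' the per-trial target series and every other column is one participant's
#' initial angles. Trials are split into three equal consecutive blocks
#' (A, B, C). Ragged or non-numeric cells raise a parse error naming the
#' offending column and row.
#'
#' @param path CSV file path.
#' @param experiment Experiment id to attach to the sessions (NA if unknown).
#' @param variant Variant label to attach.
#' @return A list of `"motor_session"` objects, one per participant column.
#' @export
read_sessions_csv <- function(path, experiment = NA_integer_,
                              variant = "20deg") {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty session file", call. = FALSE)
  is_target <- grepl("target", names(raw), ignore.case = TRUE)
  if (sum(is_target) != 1L)
    stop("session file must contain exactly one target column", call. = FALSE)
  parse_col <- function(col, name) {
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) | !nzchar(trimws(col)))
    if (length(bad))
      stop(sprintf("parse error in column '%s', row %d: non-numeric or missing cell",
                   name, bad[[1L]]), call. = FALSE)
    val
  }
  num <- mapply(parse_col, raw, names(raw), SIMPLIFY = FALSE)
  n <- nrow(raw)
  if (n %% 3L != 0L)
    stop(sprintf("trial count %d is not divisible into three equal blocks", n),
         call. = FALSE)
  nb <- n %/% 3L
  target <- num[[which(is_target)]]
  participants <- num[!is_target]
  lapply(names(participants), function(id) {
    new_motor_session(experiment, variant, id,
      data.frame(trial = seq_len(n),
                 block = rep(c("A", "B", "C"), each = nb),
                 target_deg = target, theta_deg = NA_real_,
                 initial_direction_deg = participants[[id]],
                 trial_cost = NA_real_, success = NA))
  })
}
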
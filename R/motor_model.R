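#' Simulated motor learner for visuomotor rotation experiments
#'
#' Constructs and pretrains one of three candidate learning architectures:
#'
#' * `kind = "A"` — a single basis-function network shared across all targets
#'   and environments; both skill and environment changes are absorbed by the
#'   same weights, so practice on one target interferes with others.
#' * `kind = "B"` — one network per target ("motor program" model); each
#'   network absorbs both its task and the environment, so nothing
#'   generalizes across targets.
#' * `kind = "C"` — the two-system model: one task network per target trained
#'   on performance error, plus a single shared plant model of the
#'   environment trained on sensory prediction error and inverted to remap
#'   motor commands.
#'
#' Pretraining emulates the practice phase: several hundred reaches per target
#' in the veridical (unrotated) environment, each a full closed-loop trial
#' followed by an LMS weight update. Model C starts with an identity plant
#' model — perfectly adapted to the veridical environment.
#'
#' @param kind `"A"`, `"B"` or `"C"`.
#' @param targets Pretraining target directions in degrees
#'   (default 0, 20, 40, 60; 0 is straight up).
#' @param n_pretrain Pretraining trials per target (default 300). Use 0 for a
#'   naive, zero-weight learner.
#' @param control A [motor_control()] list of tunables. When omitted, models
#'   A and B use the default task learning rate, while model C uses
#'   `lambda = 0.002`: its task networks are the slow system, and
#'   environment changes are absorbed by the fast adapter (`alpha_e`).
#' @return An object of class `"motor_model"`.
#' @seealso [run_trial()], [run_experiment()], [run_battery()],
#'   [simulate.motor_model()]
#' @examples
#' m <- motor_model("C", n_pretrain = 50)
#' out <- run_experiment(m, experiment = 1, noise_sd = 0)
#' head(out$session$trials)
#' @export
motor_model <- function(kind = c("A", "B", "C"), targets = c(0, 20, 40, 60),
                        n_pretrain = 300, control = NULL) {
  kind <- match.arg(kind)
  if (is.null(control))
    control <- if (kind == "C") motor_control(lambda = 0.002) else motor_control()
  if (length(targets) < 1L)
    stop("at least one pretraining target is required", call. = FALSE)
  nets <- NULL
  shared <- NULL
  if (kind == "A") {
    shared <- bf_network(control$degree)
  } else {
    nets <- stats::setNames(
      lapply(targets, function(...) bf_network(control$degree)),
      target_key(targets))
  }
  model <- structure(
    list(kind = kind, targets = as.numeric(targets), control = control,
         shared = shared, nets = nets,
         plant = if (kind == "C")
           plant_model(diag(2), control$alpha_e, control$cond_threshold),
         pretrained = FALSE, n_pretrain = 0L),
    class = "motor_model")
  if (n_pretrain > 0) model <- pretrain(model, n_trials = n_pretrain)
  model
}

target_key <- function(target_deg) formatC(target_deg, format = "g")

#' Pretrain a motor model in the veridical environment
#'
#' Runs `n_trials` closed-loop practice reaches per target at `theta = 0`.
#' For per-target architectures (B, C) each target's network is trained to
#' convergence independently; for the shared-network architecture (A) the
#' targets are practiced in round-robin order, so the single network ends up
#' a compromise shaped by the most recent reaches.
#'
#' @param model A [motor_model()].
#' @param n_trials Practice trials per target.
#' @return The pretrained model.
#' @export
pretrain <- function(model, n_trials = 300) {
  stopifnot(inherits(model, "motor_model"))
  if (n_trials > 0) {
    ctl <- model$control
    ls_init <- function(tgt)
      fit_network_ls(desired_trajectory(tgt, ctl$target_dist, ctl$n_samples,
                                        ctl$sigma_bell), ctl$degree)
    # The skill itself is assumed already learned from prior experience:
    # practice starts from the optimal straight-reach plan and LMS then
    # maintains it (and, for the shared network, reshapes it per target).
    if (model$kind == "A") {
      if (all(model$shared$Wx == 0) && all(model$shared$Wy == 0))
        model$shared <- ls_init(model$targets[[1L]])
      for (tgt in rep(model$targets, times = n_trials))
        model <- run_trial(model, tgt, 0)$model
    } else {
      for (tgt in model$targets) {
        key <- target_key(tgt)
        w <- model$nets[[key]]
        if (!is.null(w) && all(w$Wx == 0) && all(w$Wy == 0))
          model$nets[[key]] <- ls_init(tgt)
        for (i in seq_len(n_trials))
          model <- run_trial(model, tgt, 0)$model
      }
    }
  }
  model$pretrained <- TRUE
  model$n_pretrain <- as.integer(n_trials)
  model
}

# Fetch the active network for a target (LS-initialized if never seen).
active_network <- function(model, target_deg, desired) {
  if (model$kind == "A") return(model$shared)
  key <- target_key(target_deg)
  w <- model$nets[[key]]
  if (is.null(w)) w <- fit_network_ls(desired, model$control$degree)
  w
}

#' Run one reaching trial and learn from it
#'
#' Executes a full closed-loop movement with the architecture's wiring
#' (models A and B reach without an adapter; model C remaps its command
#' through the plant-model inverse and trains the plant model on prediction
#' error), then applies the LMS update to the active task network from the
#' whole movement's performance error. The recorded initial direction is
#' measured on the sensed (on-screen) trajectory at the point of maximum
#' speed, with optional additive Gaussian measurement noise; the learning
#' loop itself is deterministic.
#'
#' @param model A [motor_model()].
#' @param target_deg On-screen target direction (degrees).
#' @param theta_deg Plant rotation for this trial (degrees).
#' @param noise_sd SD (degrees) of measurement noise added to the recorded
#'   initial direction (0 disables the random draw entirely).
#' @param block Optional block label ("A", "B" or "C") stored in the record.
#' @param trial_index Optional trial number stored in the record.
#' @return A list with `record` (one-row data frame: `trial`, `block`,
#'   `target_deg`, `theta_deg`, `initial_direction_deg`, `trial_cost`,
#'   `success`), the updated `model`, and `trial` (the full
#'   [closed_loop_trial()] output).
#' @export
run_trial <- function(model, target_deg, theta_deg, noise_sd = 0,
                      block = NA_character_, trial_index = NA_integer_) {
  stopifnot(inherits(model, "motor_model"))
  ctl <- model$control
  des <- desired_trajectory(target_deg, ctl$target_dist, ctl$n_samples,
                            ctl$sigma_bell)
  w <- active_network(model, target_deg, des)
  planned <- eval_network(w, des$times)
  adapter <- if (model$kind == "C") model$plant
  res <- tryCatch(
    closed_loop_trial(planned, des, rotation_env(theta_deg), adapter, ctl),
    rotadapt_degenerate_model = function(e)
      closed_loop_trial(planned, des, rotation_env(theta_deg), NULL, ctl))
  w <- lms_update(w, res$perf_err, des$times, ctl$lambda)
  if (model$kind == "A") model$shared <- w
  else model$nets[[target_key(target_deg)]] <- w
  if (model$kind == "C" && !is.null(res$adapter)) model$plant <- res$adapter

  dir <- tryCatch(initial_direction(res$sensed),
                  rotadapt_undefined_direction = function(e) NA_real_)
  if (!is.na(dir) && noise_sd > 0) dir <- dir + stats::rnorm(1L, 0, noise_sd)
  n <- nrow(res$sensed)
  dt <- res$times[[2L]] - res$times[[1L]]
  tp <- ctl$target_dist * direction_vector(target_deg)
  success <- sqrt(sum((res$sensed[n, ] - tp)^2)) < 0.05 * ctl$target_dist
  rec <- data.frame(trial = as.integer(trial_index), block = block,
                    target_deg = target_deg, theta_deg = theta_deg,
                    initial_direction_deg = dir,
                    trial_cost = trial_cost(res$perf_err, dt),
                    success = success)
  list(record = rec, model = model, trial = res)
}

new_motor_session <- function(experiment, variant, id, trials) {
  structure(list(experiment = as.integer(experiment), variant = variant,
                 id = id, trials = trials),
            class = "motor_session")
}

#' @export
print.motor_session <- function(x, ...) {
  cat(sprintf("Session '%s', experiment %d (%s): %d trials in blocks %s\n",
              x$id, x$experiment, x$variant, nrow(x$trials),
              paste(rle(x$trials$block)$values, collapse = "/")))
  invisible(x)
}

#' Run one block-design experiment
#'
#' Simulates the three blocks (baseline A, interference B, re-adaptation C)
#' of the given experiment's schedule, 20 trials per block by default,
#' carrying the learner's state through every trial.
#'
#' @param model A pretrained [motor_model()].
#' @param experiment Integer 1-4 (4 is computationally identical to 3).
#' @param variant `"20deg"` or `"90deg"`.
#' @param noise_sd Measurement noise SD in degrees (see [run_trial()]).
#' @param trials_per_block Trials per block (default 20).
#' @return A list with `session` (a `"motor_session"`: experiment id, variant,
#'   model kind and the 60-trial record) and the updated `model`.
#' @export
run_experiment <- function(model, experiment, variant = "20deg", noise_sd = 0,
                           trials_per_block = 20) {
  sched <- make_schedule(experiment, variant)
  blocks <- c("A", "B", "C")
  recs <- vector("list", 3L * trials_per_block)
  k <- 0L
  for (b in 1:3) {
    for (i in seq_len(trials_per_block)) {
      k <- k + 1L
      out <- run_trial(model, sched$targets[[b]], sched$thetas[[b]], noise_sd,
                       block = blocks[[b]], trial_index = k)
      model <- out$model
      recs[[k]] <- out$record
    }
  }
  session <- new_motor_session(experiment, variant, model$kind,
                               do.call(rbind, recs))
  list(session = session, model = model)
}

#' Run the sequential battery of experiments
#'
#' Runs the listed experiments back to back on one learner with no reset in
#' between, so state (weights and, for model C, the plant model) carries over
#' — after experiment 1 the learner retains the +10 degree baseline field and
#' shows no learning curve at the start of experiments 2 and 3.
#'
#' @param model A pretrained [motor_model()].
#' @param experiments Integer vector of experiments to run in order
#'   (default `1:3`; experiment 4 is an alias of 3).
#' @param variant `"20deg"` or `"90deg"`.
#' @param noise_sd Measurement noise SD in degrees.
#' @param seed Optional integer seed for the measurement noise.
#' @return A list with `sessions` (named list of `"motor_session"` objects)
#'   and the final `model`.
#' @export
run_battery <- function(model, experiments = 1:3, variant = "20deg",
                        noise_sd = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sessions <- vector("list", length(experiments))
  names(sessions) <- paste0("exp", experiments)
  for (i in seq_along(experiments)) {
    out <- run_experiment(model, experiments[[i]], variant, noise_sd)
    sessions[[i]] <- out$session
    model <- out$model
  }
  list(sessions = sessions, model = model)
}

#' Simulate sessions from a pretrained motor model
#'
#' Standard `simulate()` interface: each replicate runs the full sequential
#' battery from the (unchanged) pretrained state with fresh measurement
#' noise. The learning loop is deterministic, so replicates differ only in
#' the noise added to the recorded initial directions.
#'
#' @param object A pretrained [motor_model()].
#' @param nsim Number of replicate batteries.
#' @param seed Optional seed, handled as in [stats::simulate()].
#' @param experiments,variant,noise_sd Passed to [run_battery()].
#' @param ... Unused.
#' @return A list of length `nsim`; each element is the named session list of
#'   one battery.
#' @export
simulate.motor_model <- function(object, nsim = 1, seed = NULL,
                                 experiments = 1:3, variant = "20deg",
                                 noise_sd = 1.5, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  for (s in seq_len(nsim))
    out[[s]] <- run_battery(object, experiments, variant, noise_sd)$sessions
  out
}

#' @export
print.motor_model <- function(x, ...) {
  label <- switch(x$kind,
    A = "single shared network",
    B = "one network per target",
    C = "per-target task networks + shared environment adapter")
  cat(sprintf("Motor learning model %s (%s)\n", x$kind, label))
  cat(sprintf("  targets: %s deg; pretrained: %s (%d trials/target)\n",
              paste(x$targets, collapse = ", "),
              if (x$pretrained) "yes" else "no", x$n_pretrain))
  cat(sprintf("  degree %d basis functions, lambda = %g, gamma = %g, delay = %d samples\n",
              x$control$degree, x$control$lambda, x$control$gamma,
              x$control$delay_samples))
  if (x$kind == "C")
    cat(sprintf("  plant model: implied rotation %+.2f deg (alpha_e = %g)\n",
                implied_rotation(x$plant), x$control$alpha_e))
  invisible(x)
}

#' Extract network weights from a motor model
#'
#' @param object A [motor_model()].
#' @param ... Unused.
#' @return For model A, a `(degree+1) x 2` matrix of weights (columns `Wx`,
#'   `Wy`); for models B and C, a named list of such matrices, one per
#'   stored target.
#' @export
coef.motor_model <- function(object, ...) {
  as_mat <- function(w) cbind(Wx = w$Wx, Wy = w$Wy)
  if (object$kind == "A") as_mat(object$shared)
  else lapply(object$nets, as_mat)
}

#' Planned trajectory for a target
#'
#' Evaluates the stored task network for `target_deg` on the model's time
#' grid (a never-practiced target uses a fresh least-squares-initialized
#' network, as in simulation).
#'
#' @param object A [motor_model()].
#' @param target_deg Target direction in degrees.
#' @param ... Unused.
#' @return An n x 2 matrix of planned positions.
#' @export
predict.motor_model <- function(object, target_deg = 20, ...) {
  ctl <- object$control
  des <- desired_trajectory(target_deg, ctl$target_dist, ctl$n_samples,
                            ctl$sigma_bell)
  w <- active_network(object, target_deg, des)
  eval_network(w, des$times)
}

#' Summarize a motor model
#'
#' Reports, per stored target, the initial direction and endpoint error of a
#' probe reach in the veridical environment (no learning, no noise), plus the
#' plant model's implied rotation for model C.
#'
#' @param object A [motor_model()].
#' @param ... Unused.
#' @return An object of class `"summary.motor_model"`.
#' @export
summary.motor_model <- function(object, ...) {
  ctl <- object$control
  tgts <- if (object$kind == "A") object$targets
          else as.numeric(names(object$nets))
  probe <- function(tgt) {
    des <- desired_trajectory(tgt, ctl$target_dist, ctl$n_samples, ctl$sigma_bell)
    w <- active_network(object, tgt, des)
    res <- closed_loop_trial(eval_network(w, des$times), des, rotation_env(0),
                             NULL, ctl)
    n <- nrow(res$sensed)
    c(initial_direction = initial_direction(res$sensed),
      endpoint_error = sqrt(sum((res$sensed[n, ] - des$xy[n, ])^2)))
  }
  tab <- t(vapply(tgts, probe, numeric(2L)))
  out <- list(kind = object$kind, targets = tgts, probe = tab,
              implied_rotation = if (object$kind == "C")
                implied_rotation(object$plant))
  class(out) <- "summary.motor_model"
  out
}

#' @export
print.summary.motor_model <- function(x, ...) {
  cat(sprintf("Model %s probe reaches (veridical environment):\n", x$kind))
  df <- data.frame(target_deg = x$targets,
                   initial_direction_deg = round(x$probe[, 1L], 3),
                   endpoint_error = signif(x$probe[, 2L], 3))
  print(df, row.names = FALSE)
  if (!is.null(x$implied_rotation))
    cat(sprintf("Plant model implied rotation: %+.3f deg\n", x$implied_rotation))
  invisible(x)
}

#' Plot a probe reach of a motor model
#'
#' Draws the desired and sensed on-screen paths of one probe trial (no
#' learning) for a target under a given rotation, the quickest way to see
#' the terminal "hook" produced by delayed online correction.
#'
#' @param x A [motor_model()].
#' @param target_deg Target direction (degrees).
#' @param theta_deg Plant rotation for the probe (degrees).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [closed_loop_trial()] result of the probe.
#' @export
plot.motor_model <- function(x, target_deg = 20, theta_deg = 0, ...) {
  ctl <- x$control
  des <- desired_trajectory(target_deg, ctl$target_dist, ctl$n_samples,
                            ctl$sigma_bell)
  w <- active_network(x, target_deg, des)
  res <- closed_loop_trial(eval_network(w, des$times), des,
                           rotation_env(theta_deg),
                           if (x$kind == "C") x$plant else NULL, ctl,
                           update_adapter = FALSE)
  rng <- range(des$xy, res$sensed)
  graphics::plot(des$xy, type = "l", lty = 2, col = "grey40", asp = 1,
                 xlim = rng, ylim = rng, xlab = "x (tablet units)",
                 ylab = "y (tablet units)", ...)
  graphics::lines(res$sensed, col = "black")
  graphics::points(des$xy[nrow(des$xy), 1L], des$xy[nrow(des$xy), 2L], pch = 4)
  graphics::legend("topleft", bty = "n", lty = c(2, 1),
                   col = c("grey40", "black"),
                   legend = c("desired", "sensed"))
  invisible(res)
}

#' Checkpoint a motor model's learnable state as plain text
#'
#' Writes (or restores) the network weights, the plant model and the key
#' configuration (`degree`, `lambda`, `n_samples`, `sigma_bell`, ...) as JSON,
#' so state can be carried between experiments or sessions.
#'
#' @param model A [motor_model()].
#' @param path File path.
#' @return `read_checkpoint()` returns a `"motor_model"`;
#'   `write_checkpoint()` returns `path` invisibly.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "motor_model"))
  payload <- list(
    kind = model$kind, targets = model$targets,
    control = unclass(model$control),
    pretrained = model$pretrained, n_pretrain = model$n_pretrain,
    shared = if (!is.null(model$shared)) model$shared[c("degree", "Wx", "Wy")],
    nets = if (!is.null(model$nets))
      lapply(model$nets, function(w) w[c("degree", "Wx", "Wy")]),
    Phat = if (!is.null(model$plant)) model$plant$Phat)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctl <- do.call(motor_control, x$control[setdiff(names(x$control), NULL)])
  model <- motor_model(x$kind, targets = x$targets, n_pretrain = 0,
                       control = ctl)
  if (length(x$shared))
    model$shared <- bf_network(x$shared$degree, x$shared$Wx, x$shared$Wy)
  if (length(x$nets))
    model$nets <- lapply(x$nets, function(w) bf_network(w$degree, w$Wx, w$Wy))
  if (length(x$Phat)) {
    Phat <- x$Phat
    if (!is.matrix(Phat)) Phat <- do.call(rbind, lapply(Phat, unlist))
    model$plant <- plant_model(Phat, ctl$alpha_e, ctl$cond_threshold)
  }
  model$pretrained <- isTRUE(x$pretrained)
  model$n_pretrain <- as.integer(x$n_pretrain)
  model
}
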
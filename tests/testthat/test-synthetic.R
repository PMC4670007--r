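test_that("generator parameters are validated and sessions are deterministic", {
  expect_error(synth_params(adaptation_rate = 0), "0, 1")
  expect_error(synth_params(noise_sd = -1), "non-negative")
  expect_error(synth_params(aftereffect_frac = 1.2), "\\[0, 1\\]")
  p <- synth_params(seed = 99)
  s1 <- synth_session(p, 1, participant = 3)
  s2 <- synth_session(p, 1, participant = 3)
  expect_identical(s1, s2)
  s3 <- synth_session(p, 1, participant = 4)
  expect_false(identical(s1$trials, s3$trials))
  # generating a session does not disturb the caller's RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(synth_session(p, 2)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("the noiseless instant-adaptation limit is on target from trial 2 onward", {
  # the first trial of a block always expresses the full on-screen
  # consequence of the block transition; with adaptation_rate = 1 it is
  # gone by the next trial
  p <- synth_params(adaptation_rate = 1, noise_sd = 0)
  for (e in 1:3) {
    s <- synth_session(p, e)
    sched <- make_schedule(e)
    keep <- setdiff(1:60, c(1, 21, 41))
    expect_equal(s$trials$initial_direction_deg[keep],
                 rep(sched$targets, each = 20)[keep], tolerance = 1e-12)
  }
  # experiment 2's baseline has no jump at all: the analysis reports the
  # degenerate (zero-variance) baseline explicitly instead of dividing
  r <- aftereffect(synth_session(p, 2))
  expect_true(r$degenerate)
  expect_false(r$significant)
})

test_that("injected aftereffects are recovered at the expected z magnitude", {
  # experiment 1, full aftereffect, noise sd 2: |z| ~ 20/2 = 10
  p <- synth_params(n_participants = 40, noise_sd = 2, aftereffect_frac = 1,
                    seed = 5)
  zz <- vapply(synth_experiment(p, 1), function(s) abs(aftereffect(s)$z), 0)
  expect_gt(mean(zz), 8)
  expect_lt(mean(zz), 12)
  # experiment 2 injects nothing: null calibration against the exact
  # closed form P(|sqrt(1.1) t_9| > 1.96) of the plugged-in-sd z test
  p0 <- synth_params(n_participants = 400, seed = 17)
  sig <- vapply(synth_experiment(p0, 2), function(s) aftereffect(s)$significant,
                TRUE)
  p_null <- 2 * pt(-qnorm(0.975) / sqrt(1 + 1 / 10), df = 9)
  mc_tol <- 3 * sqrt(p_null * (1 - p_null) / 400)
  expect_lt(abs(mean(sig) - p_null), mc_tol + 0.01)
})

test_that("detection power rises monotonically and crosses 50% where theory says", {
  sigma <- 3
  adapted <- 20 * (1 - 0.75^20)
  delta_star <- qnorm(0.975) * sigma * sqrt(1 + 1 / 10)
  power_at <- function(delta, n = 300) {
    p <- synth_params(n_participants = n, noise_sd = sigma,
                      aftereffect_frac = min(delta / adapted, 1), seed = 123)
    mean(vapply(synth_experiment(p, 1), function(s) aftereffect(s)$significant,
                TRUE))
  }
  grid <- c(0.5, 1, 1.6) * delta_star
  pw <- vapply(grid, power_at, 0)
  expect_true(all(diff(pw) > 0))
  expect_lt(pw[1], 0.45)
  expect_gt(pw[3], 0.80)
  expect_lt(abs(pw[2] - 0.5), 0.12)
  # closed form (noncentral t) agrees with the Monte-Carlo estimates
  closed <- vapply(grid, function(delta) {
    ncp <- delta / (sigma * sqrt(1.1))
    crit <- qnorm(0.975) / sqrt(1.1)
    pt(-crit, 9, ncp) + 1 - pt(crit, 9, ncp)
  }, 0)
  expect_lt(max(abs(pw - closed)), 0.1)
})

test_that("significance decisions track the generator's ground truth over a grid", {
  for (noise_sd in c(2, 4)) for (frac in c(0.7, 1)) {
    p <- synth_params(n_participants = 60, noise_sd = noise_sd,
                      aftereffect_frac = frac, seed = 7)
    delta <- frac * 20 * (1 - 0.75^20)
    power <- mean(vapply(synth_experiment(p, 1),
                         function(s) aftereffect(s)$significant, TRUE))
    if (delta > 4 * noise_sd) expect_gte(power, 0.95)
  }
})

test_that("the deposited CSV layout round-trips and reports parse errors precisely", {
  p <- synth_params(n_participants = 10, seed = 3)
  sessions <- synth_experiment(p, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions_csv(sessions, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_length(header, 11)                      # 10 participants + target
  expect_match(header[11], "target")
  back <- read_sessions_csv(path, experiment = 1)
  expect_length(back, 10)
  for (i in 1:10) {
    expect_identical(back[[i]]$trials$initial_direction_deg,
                     sessions[[i]]$trials$initial_direction_deg)
    expect_identical(back[[i]]$trials$target_deg, sessions[[i]]$trials$target_deg)
    expect_identical(nrow(back[[i]]$trials), 60L)
  }
  # a short / non-numeric column is reported with its name and row
  bad <- utils::read.csv(path, check.names = FALSE)
  bad[59, 2] <- NA
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_sessions_csv(path2), "participant_2.*59")
  bad2 <- utils::read.csv(path, check.names = FALSE)
  bad2[[4]] <- as.character(bad2[[4]]); bad2[7, 4] <- "oops"
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad2, path3, row.names = FALSE)
  expect_error(read_sessions_csv(path3), "participant_4.*7")
  # a file without a target column is rejected
  no_tgt <- utils::read.csv(path, check.names = FALSE)[, 1:10]
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(no_tgt, path4, row.names = FALSE)
  expect_error(read_sessions_csv(path4), "target")
})
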
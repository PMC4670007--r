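# Pretrained models are expensive; build each architecture once per test run.
.model_cache <- new.env(parent = emptyenv())

cached_model <- function(kind, n_pretrain = 100) {
  key <- paste0(kind, "_", n_pretrain)
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- motor_model(kind, n_pretrain = n_pretrain)
  .model_cache[[key]]
}

# A session table built directly from numbers, for analysis-only tests.
fake_session <- function(a, b = rep(20, 20), cc = rep(20, 20),
                         experiment = 1L, id = "s1", target = 20) {
  n <- length(a) + length(b) + length(cc)
  rotadapt:::new_motor_session(experiment, "20deg", id,
    data.frame(trial = seq_len(n),
               block = rep(c("A", "B", "C"), c(length(a), length(b), length(cc))),
               target_deg = target, theta_deg = 10,
               initial_direction_deg = c(a, b, cc),
               trial_cost = NA_real_, success = NA))
}
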
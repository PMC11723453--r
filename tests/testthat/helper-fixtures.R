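# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

small_ergo_session <- function(noise = 1) {
  memo(paste0("ergo_", noise), function() {
    su <- sample_subject("ergometer", 101)
    su$params$noise_sd <- noise
    simulate_ergo_session(su$profile, su$params, 8)
  })
}

small_boat_session <- function(noise = 1) {
  memo(paste0("boat_", noise), function() {
    su <- sample_subject("boat", 202)
    su$params$noise_sd <- noise
    simulate_boat_session(su$profile, su$params, 8)
  })
}

tiny_records <- function() {
  memo("tiny_records", function() {
    sessions <- simulate_cohort("ergometer", 3, 10, seed = 11)
    prepare_dataset(sessions, "ergometer")
  })
}

# The synthetic ergometer benchmark: 12 subjects x 80 cycles, seed 1.
# Problem sizes and epoch caps documented in the methods vignette. Trained
# once and shared by the learning-recovery and discrimination checks.
benchmark_records <- function() {
  memo("benchmark_records", function() {
    sessions <- simulate_cohort("ergometer", 12, 80, seed = 1)
    prepare_dataset(sessions, "ergometer")
  })
}

benchmark_fit <- function() {
  memo("benchmark_fit", function() {
    records <- benchmark_records()
    sp <- split_records(records, 0.8, seed = 1)
    # trained to early-stopping convergence (stops around epoch 85)
    tcfg <- train_config(max_epochs = 150, patience_epochs = 15, seed = 1)
    model <- train_network(build_network(network_config(16, 64, 0, seed = 1)),
                           records[sp$train], records[sp$val], tcfg)
    val <- records[sp$val]
    preds <- predict_cycles(model, val)
    list(records = records, split = sp, model = model, val = val,
         preds = preds, metrics = evaluate_predictions(val, preds))
  })
}

# Leave-one-subject-out on the same benchmark, with a reduced epoch cap so
# the twelve folds stay tractable; the like-for-like 80/20 model at the
# same cap is trained alongside for the generalization-gap comparison.
benchmark_loov <- function() {
  memo("benchmark_loov", function() {
    records <- benchmark_records()
    cfg <- network_config(16, 64, 0, seed = 1)
    tcfg <- train_config(max_epochs = 10, patience_epochs = 5, seed = 1)
    lo <- leave_one_out(records, cfg, tcfg)
    sp <- split_records(records, 0.8, seed = 1)
    m10 <- train_network(build_network(cfg), records[sp$train],
                         records[sp$val], tcfg)
    tab10 <- evaluate_predictions(records[sp$val],
                                  predict_cycles(m10, records[sp$val]))
    list(loov = lo, split10 = tab10)
  })
}
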
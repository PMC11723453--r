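test_that("LSTM parameter count matches a hand count of the weight arrays", {
  # enumerate the arrays for a 2-unit LSTM on 16 inputs: input weights
  # 4*2*16, recurrent 4*2*2, biases 4*2
  hand <- 4 * 2 * 16 + 4 * 2 * 2 + 4 * 2
  expect_equal(lstm_param_count(16, 2), hand)
  w <- rowkinetics:::lstm_init_cpp(16, 6, 2, 1)
  expect_equal(length(w$Wx) + length(w$Wh) + length(w$b), hand)
  expect_equal(lstm_param_count(16, 500), 1034000)
})

test_that("the network builds with the reference architectures", {
  m <- build_network(network_config(18, 53, 0.10, seed = 2))
  expect_identical(dim(m$weights$Wx), c(4L * 53L, 18L))
  expect_identical(dim(m$weights$W2), c(6L, 53L))
  expect_warning(network_config(12, 30), "standard condition")
  expect_error(network_config(16, 5))     # below search bounds
  expect_error(network_config(16, 64, dropout = 0.2))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(1)
  nI <- 3; nO <- 6; U <- 4; B <- 2; T <- 5
  w <- rowkinetics:::lstm_init_cpp(nI, nO, U, 42)
  X <- array(rnorm(nI * B * T), c(nI, B, T))
  Y <- array(rnorm(nO * B * T), c(nO, B, T))
  mask <- matrix(1, B, T); mask[2, 4:5] <- 0  # one padded tail
  lg <- rowkinetics:::lstm_loss_grads_cpp(w, X, Y, mask)
  for (nm in names(w)) {
    ks <- sample(length(w[[nm]]), min(10, length(w[[nm]])))
    for (k in ks) {
      e <- 1e-6
      wp <- w; wp[[nm]][k] <- wp[[nm]][k] + e
      wm <- w; wm[[nm]][k] <- wm[[nm]][k] - e
      fd <- (rowkinetics:::lstm_loss_cpp(wp, X, Y, mask) -
             rowkinetics:::lstm_loss_cpp(wm, X, Y, mask)) / (2 * e)
      expect_lt(abs(fd - lg$grads[[nm]][k]) /
                  max(1e-6, abs(fd) + abs(lg$grads[[nm]][k])), 1e-4)
    }
  }
})

test_that("padded frames carry no gradient", {
  set.seed(2)
  nI <- 3; U <- 4
  w <- rowkinetics:::lstm_init_cpp(nI, 6, U, 7)
  X <- array(rnorm(3 * 2 * 6), c(3, 2, 6))
  Y <- array(rnorm(6 * 2 * 6), c(6, 2, 6))
  mask <- matrix(1, 2, 6); mask[1, 5:6] <- 0
  l1 <- rowkinetics:::lstm_loss_cpp(w, X, Y, mask)
  Y[, 1, 5:6] <- 99  # changing masked targets must not change the loss
  expect_identical(rowkinetics:::lstm_loss_cpp(w, X, Y, mask), l1)
})

test_that("training reduces validation RMSE and is seed-reproducible", {
  recs <- tiny_records()
  sp <- split_records(recs, 0.8, seed = 4)
  tcfg <- train_config(max_epochs = 6, patience_epochs = 5, seed = 4)
  m1 <- train_network(build_network(network_config(16, 16, 0, seed = 4)),
                      recs[sp$train], recs[sp$val], tcfg)
  expect_lt(tail(m1$history$val_rmse, 1), m1$history$val_rmse[1])
  m2 <- train_network(build_network(network_config(16, 16, 0, seed = 4)),
                      recs[sp$train], recs[sp$val], tcfg)
  expect_identical(m1$history, m2$history)
  expect_error(train_network(build_network(network_config(16, 16, 0)),
                             recs, list(), tcfg), "empty validation")
})

test_that("early stopping halts when validation targets are unlearnable noise", {
  recs <- tiny_records()
  sp <- split_records(recs, 0.8, seed = 5)
  noise_val <- lapply(recs[sp$val], function(r) {
    r$y[] <- rnorm(length(r$y), 0, 2000)
    r
  })
  tcfg <- train_config(max_epochs = 200, patience_epochs = 4, seed = 5)
  m <- train_network(build_network(network_config(16, 12, 0, seed = 5)),
                     recs[sp$train], noise_val, tcfg)
  expect_lt(length(m$history$val_rmse), 60)
})

test_that("predictions have the per-cycle shape contract and dropout is inference-inert", {
  recs <- tiny_records()
  sp <- split_records(recs, 0.8, seed = 6)
  tcfg <- train_config(max_epochs = 2, patience_epochs = 1, seed = 6)
  m <- train_network(build_network(network_config(16, 12, 0.10, seed = 6)),
                     recs[sp$train], recs[sp$val], tcfg)
  p1 <- predict_cycles(m, recs[sp$val])
  p2 <- predict_cycles(m, recs[sp$val])
  expect_identical(p1, p2)  # no dropout at inference
  for (k in seq_along(p1)) {
    expect_identical(dim(p1[[k]]), c(nrow(recs[sp$val][[k]]$x), 6L))
    expect_identical(colnames(p1[[k]]), rowkinetics:::.rk_target_names)
  }
})

test_that("random-search sampling respects the log-uniform bounds", {
  cfgs <- sample_search_configs(10000, 16, seed = 9)
  units <- vapply(cfgs, `[[`, 0L, "lstm_units")
  dops <- vapply(cfgs, `[[`, 0, "dropout")
  expect_true(all(units >= 10 & units <= 500))
  expect_true(all(dops %in% c(0, 0.05, 0.10)))
  expect_gt(median(units), 60)
  expect_lt(median(units), 82)
})

test_that("random search returns the best-scoring trial", {
  recs <- tiny_records()
  tcfg <- train_config(max_epochs = 2, patience_epochs = 1, seed = 3)
  rs <- random_search(recs, n_trials = 2, nI = 16, tcfg = tcfg, seed = 3)
  expect_s3_class(rs$best, "network_config")
  expect_identical(nrow(rs$trials), 2L)
  expect_identical(rs$trials$units[which.min(rs$trials$score)],
                   rs$best$lstm_units)
  expect_error(random_search(recs, 0, 16), "n_trials")
})

test_that("leave-one-out validates every subject exactly once", {
  recs <- tiny_records()
  tcfg <- train_config(max_epochs = 2, patience_epochs = 1, seed = 8)
  lo <- leave_one_out(recs, network_config(16, 12, 0, seed = 8), tcfg)
  subj <- vapply(recs, `[[`, "", "subject_id")
  expect_identical(sort(names(lo$folds)), sort(unique(subj)))
  all_val <- sort(unname(unlist(lapply(lo$folds, `[[`, "val_ix"))))
  expect_identical(all_val, seq_along(recs))
  # aggregate is the arithmetic mean of fold tables
  mats <- lapply(lo$folds, function(f) as.matrix(f$metrics[, -1]))
  expect_equal(as.matrix(lo$aggregate[, -1]), Reduce(`+`, mats) / length(mats),
               tolerance = 1e-12)
})
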
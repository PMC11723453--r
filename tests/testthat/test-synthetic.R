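test_that("subject sampling is deterministic and tracks cohort statistics", {
  a <- sample_subject("ergometer", 7)
  b <- sample_subject("ergometer", 7)
  expect_identical(a, b)
  c <- sample_subject("ergometer", 8)
  expect_false(isTRUE(all.equal(a$params$force_peak_position,
                                c$params$force_peak_position)))

  hts <- vapply(1:1000, function(i) sample_subject("boat", i)$profile$height_m,
                numeric(1))
  se <- 0.05 / sqrt(1000)
  expect_lt(abs(mean(hts) - 1.85), 3 * se)
})

test_that("session duration follows stroke rate and cycle count", {
  su <- sample_subject("ergometer", 3)
  su$params$stroke_rate_spm <- 20
  ses <- simulate_ergo_session(su$profile, su$params, 10)
  dur <- nrow(ses$streams$sensors$values) / 150
  expect_lt(abs(dur - 30), 3.5)  # 10 x 3 s plus the sub-cycle padding
})

test_that("handle force is confined to the drive phase", {
  ses <- small_ergo_session()
  st <- ses$streams$sensors
  cycles <- segment_cycles(stream_channel(st, "X_handle"), 150, 1, 5)
  Fh <- stream_channel(st, "F_handle")
  for (cy in cycles) {
    seg <- cycle_slice(Fh, cy)
    rec <- seg[1:(cy$catch_idx - cy$start_idx)]  # recovery comes first
    expect_lte(max(rec), 0.05 * max(seg))
  }
})

test_that("ground truth is exactly self-consistent with target recomputation", {
  for (cond in c("ergometer", "boat")) {
    su <- sample_subject(cond, 31)
    su$params$noise_sd <- 0
    ses <- if (cond == "ergometer") {
      simulate_ergo_session(su$profile, su$params, 5)
    } else simulate_boat_session(su$profile, su$params, 5)
    fs <- if (cond == "ergometer") 150 else 100
    ref <- if (cond == "ergometer") {
      stream_channel(ses$streams$sensors, "X_handle")
    } else stream_channel(ses$streams$oars, "theta_starboard")
    cycles <- segment_cycles(ref, fs, 1, 5)
    tgs <- build_targets(ses$streams, cycles, cond)
    for (tg in tgs) {
      idx <- (tg$cycle$start_idx + 1):tg$cycle$end_idx
      for (nm in c("Ff_x", "Fh_x", "Ph_x", "Pa", "Pt", "Pl"))
        expect_lt(max(abs(tg[[nm]] - ses$truth[[nm]][idx])), 1e-9)
    }
  }
})

test_that("requested force peak position maps onto the measured T2P", {
  for (p in c(0.3, 0.4, 0.5)) {
    su <- sample_subject("ergometer", 17)
    su$params$noise_sd <- 0
    su$params$force_peak_position <- p
    ses <- simulate_ergo_session(su$profile, su$params, 6)
    st <- ses$streams$sensors
    cycles <- segment_cycles(stream_channel(st, "X_handle"), 150, 1, 5)
    Fh <- stream_channel(st, "F_handle")
    for (cy in cycles[2:4]) {
      win <- (cy$catch_idx + 1):cy$end_idx  # catch to finish, 0-based shift
      t2p <- determinants(Fh[win])$T2P
      expect_lt(abs(t2p - 100 * p), 3)
    }
  }
})

test_that("the arm-power technical fault produces a negative drive segment", {
  su <- sample_subject("ergometer", 23)
  su$params$noise_sd <- 0
  su$params$arm_negative_power_flag <- TRUE
  ses <- simulate_ergo_session(su$profile, su$params, 5)
  st <- ses$streams$sensors
  cycles <- segment_cycles(stream_channel(st, "X_handle"), 150, 1, 5)
  tg <- build_targets(ses$streams, cycles, "ergometer")[[2]]
  drive <- tg$Pa[(tg$cycle$catch_idx - tg$cycle$start_idx + 1):length(tg$Pa)]
  neg <- which(drive < -1)
  expect_gt(length(neg), 3)
  expect_true(all(diff(neg) == 1))  # one contiguous negative span
})

test_that("degenerate oar angular velocity yields zero gate power", {
  th <- list(port = rep(0.3, 50), starboard = rep(0.3, 50))
  thd <- list(port = rep(0, 50), starboard = rep(0, 50))
  Fx <- list(port = runif(50, 0, 300), starboard = runif(50, 0, 300))
  Fy <- list(port = runif(50, 0, 90), starboard = runif(50, 0, 90))
  expect_equal(boat_handle_power(th, thd, Fx, Fy)$Ph, rep(0, 50))
})
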
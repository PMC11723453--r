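test_that("integration with drift removal rejects DC and preserves band content", {
  fs <- 100
  # constant acceleration: pure drift, should be rejected
  v <- integrate_and_highpass(rep(0.2, 60 * fs), fs)
  expect_lt(abs(mean(v)), 0.01)
  # sinusoid at 0.5 Hz: amplitude a/(2*pi*f) survives the 0.1 Hz high-pass
  tt <- seq(0, 60, by = 1 / fs)
  v <- integrate_and_highpass(sin(2 * pi * 0.5 * tt), fs)
  mid <- v[(10 * fs):(50 * fs)]
  expect_lt(abs(max(abs(mid)) - 1 / (2 * pi * 0.5)) / (1 / (2 * pi * 0.5)), 0.05)
  # zero in, zero out
  expect_equal(integrate_and_highpass(rep(0, 30 * fs), fs), rep(0, 30 * fs))
  expect_error(integrate_and_highpass(rep(0, 100), fs), "too_short")
})

test_that("cross-correlation synchronization finds planted lags", {
  fs <- 100
  tt <- seq(0, 40, by = 1 / fs)
  x <- sin(2 * pi * 0.5 * tt) + 0.5 * sin(2 * pi * 1.3 * tt)
  sy <- synchronize(x, x, fs)
  expect_equal(sy$lag_s, 0)
  expect_equal(sy$correlation, 1, tolerance = 1e-12)

  shifted <- c(rep(0, 80), x[1:(length(x) - 80)])  # x delayed by 0.8 s
  sy <- synchronize(shifted, x, fs)
  expect_lt(abs(sy$lag_s - 0.8), 0.011)

  set.seed(42)
  fails <- 0
  for (i in 1:20) {
    a <- rnorm(10 * fs); b <- rnorm(10 * fs)
    fails <- fails + tryCatch({synchronize(a, b, fs, max_lag_s = 2); 0},
                              error = function(e) 1)
  }
  expect_gte(fails, 19)
})

test_that("resampling is exact on lines and accurate on band-limited signals", {
  fs <- 50
  tt <- seq(0, 10, by = 1 / fs)
  ramp <- sensor_stream(cbind(r = 3 + 2 * tt), fs, "r")
  same <- resample_stream(ramp, fs)
  expect_equal(same$values[, 1], ramp$values[, 1], tolerance = 1e-12)
  up <- resample_stream(ramp, 100)
  tt2 <- stream_time(up)
  expect_equal(up$values[, 1], 3 + 2 * tt2, tolerance = 1e-12)
  sine <- sensor_stream(cbind(s = sin(2 * pi * 2 * tt)), fs, "s")
  up2 <- resample_stream(sine, 100)
  expect_lt(max(abs(up2$values[, 1] - sin(2 * pi * 2 * stream_time(up2)))), 0.01)
})

test_that("differentiation is exact on polynomials of degree <= 2 and accurate on sinusoids", {
  fs <- 100
  tt <- seq(0, 5, by = 1 / fs)
  expect_equal(differentiate(2 * tt, fs), rep(2, length(tt)), tolerance = 1e-9)
  expect_equal(differentiate(rep(3.3, 100), fs), rep(0, 100))
  f <- 2  # well below fs / 20
  d <- differentiate(sin(2 * pi * f * tt), fs)
  mid <- 10:(length(tt) - 10)
  expect_lt(max(abs(d[mid] - 2 * pi * f * cos(2 * pi * f * tt[mid]))),
            0.01 * 2 * pi * f)
})

test_that("segmentation finds finish-to-finish cycles with catches at minima", {
  fs <- 100
  tt <- seq(0, 20, length.out = 20 * fs)  # 10 periods of a 0.5 Hz sinusoid
  x <- sin(2 * pi * 0.5 * tt)
  cycles <- segment_cycles(x, fs, 1, 5)
  expect_length(cycles, 9)
  for (cy in cycles) {
    seg <- x[(cy$start_idx + 1):cy$end_idx]
    expect_equal(cy$catch_idx - cy$start_idx, which.min(seg) - 1)
    expect_lt(abs(cy$stroke_rate_spm - 30), 1)
  }
  expect_identical(segment_cycles(rep(1, 1000), fs, 1, 5), list())
})

test_that("cycles with out-of-range duration are discarded", {
  fs <- 100
  # 6 unit-period cycles, with one stretched to 6 s in the middle
  phase <- cumsum(c(rep(1 / fs, 300), rep(1 / (6 * fs), 600), rep(1 / fs, 300)))
  x <- cos(2 * pi * phase)
  all_c <- segment_cycles(x, fs, min_cycle_s = 0.5, max_cycle_s = 10)
  kept <- segment_cycles(x, fs, min_cycle_s = 0.5, max_cycle_s = 5)
  expect_identical(length(kept), length(all_c) - 1L)
})

test_that("segmentation is idempotent on its own output", {
  ses <- small_ergo_session()
  x <- stream_channel(ses$streams$sensors, "X_handle")
  cycles <- segment_cycles(x, 150, 1, 5)
  lo <- cycles[[1]]$start_idx + 1
  hi <- cycles[[length(cycles)]]$end_idx
  again <- segment_cycles(x[lo:hi], 150, 1, 5)
  expect_length(again, length(cycles) - 2)
  for (k in seq_along(again))
    expect_identical(again[[k]]$start_idx + lo - 1,
                     cycles[[k + 1]]$start_idx)
})

test_that("drive-phase detection matches a linear-scan oracle", {
  tri <- c(seq(0, 300, length.out = 50), seq(300, 0, length.out = 50))
  got <- detect_drive_phase(tri)
  ora <- naive_drive_scan(tri)
  expect_identical(got$drive_start_idx, ora$drive_start_idx)
  expect_identical(got$drive_end_idx, ora$drive_end_idx)

  expect_error(detect_drive_phase(rep(50, 100)), "no_drive_detected")
  expect_warning(res <- detect_drive_phase(rep(250, 100)))
  expect_identical(res$drive_start_idx, 0)
  expect_identical(res$drive_end_idx, 100)
})

test_that("the effective drive phase sits inside the catch-to-finish span", {
  ses <- small_ergo_session(noise = 0)
  st <- ses$streams$sensors
  cycles <- segment_cycles(stream_channel(st, "X_handle"), 150, 1, 5)
  cycles <- annotate_cycles <- rowkinetics:::annotate_cycles(
    cycles, stream_channel(st, "F_handle"), 150)
  for (cy in cycles) {
    expect_gte(cy$drive_start_idx, cy$catch_idx)
    expect_lte(cy$drive_end_idx, cy$end_idx)
  }
})
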
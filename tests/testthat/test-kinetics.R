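test_that("ergometer segment kinematics satisfy their defining identities", {
  fs <- 150
  tt <- seq(0, 4, by = 1 / fs)
  Xc <- 0.4 + 0.2 * sin(2 * pi * 0.5 * tt)
  Xs <- 0.1 + 0.3 * sin(2 * pi * 0.5 * tt - 0.4)
  kin <- ergo_segment_kinematics(Xc, Xc, Xs, fs)   # handle == chest
  expect_equal(kin$Xa, rep(0, length(tt)))
  expect_equal(kin$Va, rep(0, length(tt)))
  kin2 <- ergo_segment_kinematics(Xc + 0.5, Xs, Xs, fs)  # chest == seat
  expect_equal(kin2$Xt, rep(0, length(tt)))
  # telescoping: Va + Vt + Vl = Vh
  Xh <- 0.9 + 0.5 * sin(2 * pi * 0.4 * tt + 0.2)
  kin3 <- ergo_segment_kinematics(Xh, Xc, Xs, fs)
  expect_equal(kin3$Va + kin3$Vt + kin3$Vl, kin3$Vh, tolerance = 1e-9)
})

test_that("ergometer powers follow the samplewise products and close the balance", {
  fs <- 150
  tt <- seq(0, 2, by = 1 / fs)
  Xh <- 0.9 + 0.5 * sin(2 * pi * 0.4 * tt)
  Xc <- 0.4 + 0.2 * sin(2 * pi * 0.4 * tt - 0.3)
  Xs <- 0.1 + 0.3 * sin(2 * pi * 0.4 * tt - 0.6)
  kin <- ergo_segment_kinematics(Xh, Xc, Xs, fs)
  z <- rep(0, length(tt))
  pw0 <- ergo_powers(kin, z, z)
  expect_equal(pw0$Ph_x, z); expect_equal(pw0$Pl, z)
  # direct product at a sample
  F1 <- rep(400, length(tt))
  pw1 <- ergo_powers(kin, F1, F1)
  k <- 100
  expect_equal(pw1$Ph_x[k], kin$Vh[k] * 400)
  # closure whenever handle and feet forces agree samplewise
  Fr <- abs(rnorm(length(tt), 300, 80))
  pw <- ergo_powers(kin, Fr, Fr)
  peak <- max(abs(pw$Ph_x))
  expect_lt(max(abs(pw$Pa + pw$Pt + pw$Pl - pw$Ph_x)), 1e-6 * peak)
  expect_error(ergo_powers(kin, Fr[-1], Fr), "mismatch")
})

test_that("gate power matches the direct samplewise oracle", {
  set.seed(5)
  n <- 200
  th <- list(port = runif(n, -1, 0.6), starboard = runif(n, -1, 0.6))
  thd <- list(port = rnorm(n), starboard = rnorm(n))
  Fx <- list(port = runif(n, 0, 400), starboard = runif(n, 0, 400))
  Fy <- list(port = runif(n, 0, 120), starboard = runif(n, 0, 120))
  got <- boat_handle_power(th, thd, Fx, Fy, li = 0.88)
  expect_equal(got$Ph, naive_gate_power(th, thd, Fx, Fy, 0.88), tolerance = 1e-12)
  expect_equal(got$Ph, got$Ph_x + got$Ph_y, tolerance = 1e-12)
  # theta = 0 kills the transverse term
  th0 <- list(port = rep(0, n), starboard = rep(0, n))
  g0 <- boat_handle_power(th0, thd, Fx, Fy, li = 0.88)
  expect_equal(g0$Ph, (Fx$port * thd$port + Fx$starboard * thd$starboard) * 0.88,
               tolerance = 1e-12)
})

test_that("IMU-derived segment velocities obey the pelvis correction", {
  n <- 100
  V <- rnorm(n); tilt <- runif(n, -0.3, 0.4); tdot <- rnorm(n)
  sv <- boat_segment_velocities(V, V, tilt, tdot)
  expect_equal(sv$Vt, rep(0, n))
  sv2 <- boat_segment_velocities(V + 1, V, tilt, rep(0, n))
  expect_equal(sv2$Vl, V)
  sv3 <- boat_segment_velocities(V, V, rep(pi / 2, n), tdot)
  expect_equal(sv3$Vl, V, tolerance = 1e-12)
})

test_that("trunk/leg powers and the arm-power closure hold to float precision", {
  set.seed(8)
  n <- 300
  Ff <- runif(n, 0, 600); Fh <- runif(n, 0, 500)
  Vt <- rnorm(n); Vl <- rnorm(n); Vb <- runif(n, 3, 5); Ph <- rnorm(n, 400, 150)
  sp <- boat_segment_powers(Ff, Fh, Vt, Vl)
  expect_equal(sp$Pl, Ff * Vl)
  expect_equal(sp$Pt, Fh * Vt)
  Pa <- boat_arm_power(Ph, Ff, Fh, Vb, sp$Pt, sp$Pl)
  resid <- Pa + sp$Pt + sp$Pl - Ph - (Ff - Fh) * Vb
  expect_lt(max(abs(resid)), 1e-9)
  # degenerate: equal forces and no segment power leaves Pa = Ph
  expect_equal(boat_arm_power(Ph, Fh, Fh, Vb, 0, 0), Ph)
})

test_that("build_targets emits one aligned target set per segmented cycle", {
  ses <- small_ergo_session()
  st <- ses$streams$sensors
  cycles <- segment_cycles(stream_channel(st, "X_handle"), 150, 1, 5)
  tgs <- build_targets(ses$streams, cycles, "ergometer")
  expect_length(tgs, length(cycles))
  for (tg in tgs) {
    len <- tg$cycle$end_idx - tg$cycle$start_idx
    for (nm in c("Ff_x", "Fh_x", "Ph_x", "Pa", "Pt", "Pl"))
      expect_length(tg[[nm]], len)
  }
})

test_that("recovery-phase powers are negligible on noise-free sessions", {
  ses <- small_ergo_session(noise = 0)
  st <- ses$streams$sensors
  cycles <- segment_cycles(stream_channel(st, "X_handle"), 150, 1, 5)
  tgs <- build_targets(ses$streams, cycles, "ergometer")
  for (tg in tgs) {
    rec <- 1:(tg$cycle$catch_idx - tg$cycle$start_idx)
    for (nm in c("Ph_x", "Pa", "Pt", "Pl"))
      expect_lt(max(abs(tg[[nm]][rec])), 0.02 * max(abs(tg[[nm]])))
  }
})
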
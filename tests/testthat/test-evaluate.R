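test_that("drive-grid interpolation is exact on constants and lines", {
  expect_equal(interp_drive_grid(rep(4.2, 17)), rep(4.2, 50))
  r <- interp_drive_grid(seq(2, 8, length.out = 31))
  expect_equal(r, seq(2, 8, length.out = 50), tolerance = 1e-12)
  x <- sin(seq(0, pi, length.out = 200))
  dense <- approx(seq_along(x), x, xout = seq(1, length(x), length.out = 50))$y
  expect_lt(max(abs(interp_drive_grid(x) - dense)), 1e-9)
  expect_error(interp_drive_grid(1), "fewer than 2")
})

test_that("MAE and cycle-averaged MAE follow their definitions", {
  M <- matrix(rnorm(200), 4, 50)
  expect_equal(mae_cmae(M, M), list(MAE = 0, cMAE = 0))
  e <- mae_cmae(M, M - 3.5)
  expect_equal(e$MAE, 3.5); expect_equal(e$cMAE, 3.5)
  # opposite residuals cancel in cMAE but not in MAE
  M2 <- rbind(rep(0, 50), rep(0, 50))
  E2 <- rbind(rep(2, 50), rep(-2, 50))
  e2 <- mae_cmae(M2, E2)
  expect_equal(e2$MAE, 2); expect_equal(e2$cMAE, 0)
  expect_error(mae_cmae(M[0, , drop = FALSE], M[0, , drop = FALSE]))
})

test_that("metrics match the naive reference on random curve pairs", {
  set.seed(14)
  for (i in 1:25) {
    C <- sample(2:6, 1)
    M <- matrix(rnorm(C * 50, 300, 120), C, 50)
    E <- M + matrix(rnorm(C * 50, 0, 30), C, 50)
    e <- mae_cmae(M, E)
    expect_lt(abs(e$MAE - naive_mae(M, E)) / naive_mae(M, E), 1e-9)
    expect_lt(abs(e$cMAE - naive_cmae(M, E)) / max(1e-12, naive_cmae(M, E)), 1e-9)
    expect_equal(normalize_error(e$MAE, M), 100 * e$MAE / mean(M),
                 tolerance = 1e-12)
  }
})

test_that("cMAE never exceeds MAE", {
  set.seed(15)
  for (i in 1:50) {
    M <- matrix(rnorm(300), 6, 50); E <- matrix(rnorm(300), 6, 50)
    e <- mae_cmae(M, E)
    expect_lte(e$cMAE, e$MAE + 1e-12)
  }
})

test_that("normalization to the mean curve behaves and rejects degenerate input", {
  expect_equal(normalize_error(5, matrix(100, 3, 50)), 5)
  expect_equal(normalize_error(0, matrix(7, 2, 50)), 0)
  expect_error(normalize_error(1, matrix(0, 2, 50)), "degenerate_normalizer")
})

test_that("technique determinants reproduce closed-form shapes", {
  tri <- c(seq(0, 1, length.out = 26), seq(1, 0, length.out = 26)[-1])
  d <- determinants(tri)
  expect_equal(d$T2P, 50); expect_lt(abs(d$WR - 50), 1)
  expect_equal(determinants(rep(3, 40))$M2P, 100)
  ramp <- determinants(seq(0, 5, length.out = 30))
  expect_equal(ramp$T2P, 100); expect_equal(ramp$WR, 100)
  expect_error(determinants(rep(0, 10)), "no_peak")
})

test_that("determinants are scale-free and match the naive reference", {
  set.seed(16)
  for (i in 1:30) {
    x <- abs(rnorm(60, 5, 2)) + 0.1
    d1 <- determinants(x); d2 <- determinants(3.7 * x)
    expect_equal(d1, d2, tolerance = 1e-12)
    ref <- naive_determinants(x)
    expect_equal(d1$T2P, ref$T2P); expect_equal(d1$M2P, ref$M2P)
    expect_equal(d1$WR, ref$WR, tolerance = 1e-9)
  }
})

test_that("intra-subject accuracy counts retained null hypotheses", {
  set.seed(17)
  meas <- lapply(setNames(1:6, paste0("S", 1:6)),
                 function(i) rnorm(20, 50, 3))
  expect_equal(intra_subject_accuracy(meas, meas)$As, 100)
  est <- meas
  for (s in names(est)[1:3]) est[[s]] <- est[[s]] + 30  # 10 SD bias
  expect_equal(intra_subject_accuracy(meas, est)$As, 50)
  one <- list(S1 = rnorm(10))
  expect_equal(intra_subject_accuracy(one, one)$As, 100)
})

test_that("inter-subject accuracy compares pairwise test decisions", {
  set.seed(18)
  meas <- lapply(setNames(seq(20, 70, by = 10), paste0("S", 1:6)),
                 function(mu) rnorm(25, mu, 1))
  expect_equal(inter_subject_accuracy(meas, meas)$Ap, 100)
  # a common within-subject shift preserves every pairwise decision
  shifted <- lapply(meas, function(x) x + 500)
  expect_equal(inter_subject_accuracy(meas, shifted)$Ap, 100)
  # collapsing all subjects onto one constant flips every decision
  flat <- lapply(meas, function(x) rnorm(25, 45, 1))
  expect_lt(inter_subject_accuracy(meas, flat)$Ap, 10)
})
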
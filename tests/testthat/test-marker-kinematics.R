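test_that("zero-phase low-pass preserves DC and halves power at cutoff", {
  rate <- 100
  x <- rep(3.7, 500)
  y <- lowpass_zero_phase(x, rate, list(cutoff = 5))
  expect_equal(y, x, tolerance = 1e-9)

  # 5 Hz sinusoid at 100 Hz sampling through a 5 Hz cutoff: two passes of a
  # 2nd-order Butterworth give (1/sqrt(2))^2 = 0.5 amplitude
  t <- seq(0, 20, by = 1 / rate)
  s <- sin(2 * pi * 5 * t)
  y <- lowpass_zero_phase(s, rate, list(cutoff = 5))
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_equal(max(abs(y[mid])), 0.5, tolerance = 1e-3)

  # zero-phase: no lag between a filtered band-limited signal and the input
  slow <- sin(2 * pi * 1 * t)
  yf <- lowpass_zero_phase(slow, rate, list(cutoff = 5))
  cc <- stats::ccf(yf[mid], slow[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(lowpass_zero_phase(s, rate, list(cutoff = 60)), "Nyquist")
  expect_error(lowpass_zero_phase(c(1, NA, 3), rate), "gap-fill")
})

test_that("marker gap filling respects the maximum gap length", {
  x <- c(1, 2, NA, NA, 5, 6, rep(NA, 30), 37:40)
  out <- fill_marker_gaps(x, rate = 100, max_gap_s = 0.1)
  expect_equal(out$x[3:4], c(3, 4))
  expect_true(all(is.na(out$x[7:36])))
  expect_true(all(out$unfilled[7:36]))
})

test_that("hip joint centre regression is affine, mirror-symmetric, and matches its transcription", {
  pw <- 0.24; pd <- 0.19; ll <- 0.85
  r <- harrington_hjc(pw, pd, ll, "right")
  l <- harrington_hjc(pw, pd, ll, "left")
  expect_equal(r[1:2], l[1:2])
  expect_equal(r[3], -l[3])

  # hand evaluation of the transcribed coefficients (mm in, mm out)
  expect_equal(r * 1000,
               c(-0.24 * 190 - 9.9,
                 -0.16 * 240 - 0.04 * 850 - 7.1,
                 0.28 * 190 + 0.16 * 240 + 7.9), tolerance = 1e-12)

  # affine structure: doubling inputs does NOT double the output; the
  # offset stays fixed
  r2 <- harrington_hjc(2 * pw, 2 * pd, 2 * ll, "right")
  offs <- c(-9.9, -7.1, 7.9) / 1000
  expect_equal(r2 - offs, 2 * (r - offs), tolerance = 1e-12)
  expect_error(harrington_hjc(-0.2, pd, ll), "> 0")
})

test_that("frame IK recovers exact postures and flags rank deficiency", {
  m <- shared_lowerlimb()
  set.seed(11)
  q_true <- c(rnorm(3, 0, 0.1) + c(0, 0, 0.92), rnorm(3, 0, 0.1),
              rnorm(5, 0, 0.3))
  mk <- virtual_markers(m, forward_kinematics(m, q_true))
  sol <- solve_frame_ik(m, mk, q_init = c(0, 0, 0.92, rep(0, 8)))
  expect_lt(max(abs(sol$q - q_true)), 1e-8)

  # far initial guess converges to the same optimum on this marker set
  sol2 <- solve_frame_ik(m, mk, q_init = c(0.3, -0.2, 0.5, 0.2, -0.2, 0.2,
                                           rep(0.3, 5)))
  expect_lt(max(abs(sol2$q - q_true)), 1e-6)

  few <- list(RASI = mk[, "RASI"], LASI = mk[, "LASI"])
  expect_error(solve_frame_ik(m, few), "underdetermined")
})

test_that("kinematic round trip holds and marker noise degrades it consistently", {
  m <- shared_lowerlimb()
  tr <- shared_trial()
  ik <- solve_ik_trial(m, tr$markers)
  expect_lt(max(abs(ik$qs - tr$truth$qs)), 1e-6)

  sigma <- 0.002
  noisy <- generate_gait_trial(m, gait_params(marker_noise_sd = sigma,
                                              seed = 5), reference = "none")
  ik_n <- solve_ik_trial(m, noisy$markers)
  err <- abs(ik_n$qs - noisy$truth$qs)
  # noise-consistent bound: angular error of order sigma / segment length
  expect_lt(max(err), 0.1)
  expect_gt(max(err), 1e-6)
})

test_that("doubling all marker weights leaves the IK optimum unchanged", {
  m <- shared_lowerlimb()
  set.seed(12)
  q_true <- c(0, 0, 0.92, rnorm(8, 0, 0.2))
  mk_mat <- virtual_markers(m, forward_kinematics(m, q_true))
  mk <- lapply(stats::setNames(seq_len(ncol(mk_mat)), colnames(mk_mat)),
               function(j) mk_mat[, j] + c(0.002, -0.001, 0.0015))
  sol1 <- solve_frame_ik(m, mk, q_init = c(0, 0, 0.92, rep(0, 8)))
  m2 <- m
  for (mn in names(m2$markers)) m2$markers[[mn]]$weight <- 2 * m2$markers[[mn]]$weight
  sol2 <- solve_frame_ik(m2, mk, q_init = c(0, 0, 0.92, rep(0, 8)))
  expect_equal(sol1$q, sol2$q, tolerance = 1e-7)
  expect_equal(sol2$objective, 2 * sol1$objective, tolerance = 1e-6)
})

test_that("raising a bony-landmark weight does not raise its residual", {
  m <- shared_lowerlimb()
  set.seed(13)
  q_true <- c(0, 0, 0.92, rnorm(8, 0, 0.2))
  mk_mat <- virtual_markers(m, forward_kinematics(m, q_true))
  mk <- lapply(stats::setNames(seq_len(ncol(mk_mat)), colnames(mk_mat)),
               function(j) mk_mat[, j] + stats::rnorm(3, 0, 0.004))
  base <- solve_frame_ik(m, mk, q_init = c(0, 0, 0.92, rep(0, 8)))
  for (wf in c(3, 10)) {
    m2 <- m
    m2$markers$RASI$weight <- m$markers$RASI$weight * wf
    up <- solve_frame_ik(m2, mk, q_init = c(0, 0, 0.92, rep(0, 8)))
    expect_lte(up$residuals["RASI"], base$residuals["RASI"] + 1e-10)
  }
})

test_that("calibration supports zero iterations and can pin the hip to the pelvis regression", {
  m <- shared_lowerlimb()
  tr <- shared_trial()
  sub <- lapply(tr$markers, function(x) x[seq(1, 101, by = 10), , drop = FALSE])

  # zero outer iterations: initial model back, residuals of the initial fit
  cal0 <- optimize_marker_params(m, sub, opts = list(max_iter = 0))
  expect_equal(cal0$factors, stats::setNames(rep(1, 4), unique(
    vapply(m$markers, `[[`, "", "segment"))))
  expect_lt(max(cal0$residual_report), 1e-6)

  # Harrington constraint pins the hip joint centre
  cal_h <- optimize_marker_params(m, sub, opts = list(
    max_iter = 0,
    constrain_hjc = list(hip_joint = "hip_r", leg_length = 0.85,
                         rasi = "RASI", lasi = "LASI",
                         rpsi = "RPSI", lpsi = "LPSI", side = "right")))
  hjc_cfg <- list(hip_joint = "hip_r", leg_length = 0.85,
                  rasi = "RASI", lasi = "LASI", rpsi = "RPSI", lpsi = "LPSI",
                  side = "right")
  expected <- hipforce:::apply_hjc_constraint(m, hjc_cfg)$joints$hip_r$location_in_parent
  expect_equal(cal_h$model$joints$hip_r$location_in_parent, expected,
               tolerance = 1e-12)
})
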
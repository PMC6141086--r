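test_that("with no muscles or motion the hip carries the limb weight", {
  m <- shared_lowerlimb()
  q <- c(0, 0, 0.92, rep(0, 8))
  poses <- forward_kinematics(m, q)
  fb <- limb_free_body(m, matrix(q, 1), matrix(0, 1, 11), matrix(0, 1, 11),
                       NULL, "hip_r")[[1]]
  f0 <- stats::setNames(rep(0, 12), names(m$muscles))
  jcf <- joint_contact_force(m, poses, f0, fb, "hip_r")
  expect_equal(jcf$hcf_world, -fb$F_gravity, tolerance = 1e-12)
  # femur frame: at the reference pose PD is world +z; the pelvis holds the
  # hanging limb up, a tensile force along +PD
  leg_w <- 9.81 * (7.8 + 3.627 + 1.131)
  expect_equal(unname(jcf$hcf_femur["PD"]), leg_w / body_weight(m),
               tolerance = 1e-12)
  expect_equal(jcf$total_bw, sqrt(sum(jcf$hcf_femur^2)))
})

test_that("the contact force is linear in each muscle force", {
  m <- shared_lowerlimb()
  q <- c(0, 0, 0.92, rep(0, 8))
  poses <- forward_kinematics(m, q)
  fb <- limb_free_body(m, matrix(q, 1), matrix(0, 1, 11), matrix(0, 1, 11),
                       NULL, "hip_r")[[1]]
  f0 <- stats::setNames(rep(0, 12), names(m$muscles))
  base <- joint_contact_force(m, poses, f0, fb, "hip_r")
  f1 <- f0; f1["glutmed1_r"] <- 321
  one <- joint_contact_force(m, poses, f1, fb, "hip_r")
  u <- line_of_action(m, poses, "glutmed1_r", "hip_r")$u
  expect_equal(one$hcf_world - base$hcf_world, -321 * u, tolerance = 1e-10)
})

test_that("free-body and joint-reaction paths give the same contact force", {
  res <- shared_result()
  m <- res$model
  bw <- body_weight(m)
  for (k in c(1, 25, 50, 75, 101)) {
    fr <- res$frames[[k]]
    # independent bookkeeping: Newton-Euler hip intersegmental force minus
    # the summed muscle pulls
    hip_force_id <- res$net_loads$frames[[k]]$joints$hip_r$force
    mf <- Reduce(`+`, lapply(fr$lines, function(l) l$f * l$u))
    hcf_jr <- hip_force_id - mf
    expect_lt(hipforce:::vnorm(hcf_jr - fr$hcf_world) / bw, 1e-9)
  }
})

test_that("element contributions reconstruct the summed muscle force", {
  res <- shared_result()
  contrib <- res$contrib
  for (k in c(1, 33, 66, 101)) {
    expect_equal(rowSums(contrib$elements[[k]]), contrib$mf_hip[k, ],
                 tolerance = 1e-12)
    expect_lt(hipforce:::vnorm(rowSums(contrib$elements[[k]]) -
                                 contrib$mf_hip[k, ]),
              1e-12 * max(1, hipforce:::vnorm(contrib$mf_hip[k, ])))
  }
  # per-element magnitude equals the recruited force
  k <- 50
  fmag <- apply(contrib$elements[[k]], 2, function(v) sqrt(sum(v^2)))
  crossing <- names(fmag)
  expect_equal(unname(fmag), unname(res$forces[k, crossing]),
               tolerance = 1e-9)
})

test_that("scaling one muscle force scales its contribution linearly", {
  res <- shared_result()
  fr <- res$frames[[50]]
  mn <- names(fr$lines)[which.max(vapply(fr$lines, `[[`, 0, "f"))]
  Fi <- fr$lines[[mn]]$f * fr$lines[[mn]]$u
  fr2 <- fr
  fr2$lines[[mn]]$f <- 2 * fr2$lines[[mn]]$f
  fr2$f[mn] <- 2 * fr2$f[mn]
  d1 <- decompose_hcf(res$model, list(fr))
  d2 <- decompose_hcf(res$model, list(fr2))
  expect_equal(d2$elements[[1]][, mn], 2 * d1$elements[[1]][, mn],
               tolerance = 1e-12)
  expect_equal(d2$mf_hip[1, ] - d1$mf_hip[1, ], Fi, tolerance = 1e-10)
})

test_that("group moment contributions close the net moment with residuals", {
  res <- shared_result()
  contrib <- res$contrib
  tot <- Reduce(`+`, contrib$group_moment)
  # the summed muscle moments must reproduce the net joint moments on the
  # constrained dofs up to the recruitment solver tolerance
  expect_lt(max(abs(tot - res$tau)), 1e-5 * max(1, max(abs(res$tau))))
})

test_that("criterion-b flags a constructed over-contributing group", {
  # one group supplies 120% of the extension moment over a fifth of swing,
  # an antagonist supplies -20%
  nfr <- 101L
  pct <- seq(0, 100, length.out = nfr)
  tau <- matrix(10, nfr, 1, dimnames = list(NULL, "hip_ext"))
  over <- pct >= 70 & pct <= 90
  gm_bad <- matrix(10, nfr, 1); gm_bad[over, 1] <- 12
  gm_ant <- matrix(0, nfr, 1); gm_ant[over, 1] <- -2
  contrib <- structure(list(
    n_frames = nfr, dofs = "hip_ext",
    hcf_norm = rep(1, nfr),
    group_force = list(bad = matrix(0.1, nfr, 3), ant = matrix(0.1, nfr, 3)),
    group_moment = list(bad = gm_bad, ant = gm_ant)),
    class = "muscle_contribution")
  events <- list(stance_pct = c(0, 60))
  rep1 <- flag_suspect_muscles(contrib, tau, events)
  expect_true(rep1$bad$flagged)
  expect_length(rep1$bad$criterion_b, 1L)
  ep <- rep1$bad$criterion_b[[1]]
  expect_equal(ep$phase, "swing")
  expect_equal(c(ep$start_pct, ep$end_pct), c(70, 90), tolerance = 1.1)
  expect_length(rep1$ant$criterion_b, 0L)

  # all groups at or below the net moment: nothing flagged under (b)
  gm_ok <- matrix(9, nfr, 1)
  contrib$group_moment <- list(bad = gm_ok, ant = gm_ant)
  rep2 <- flag_suspect_muscles(contrib, tau, events)
  expect_length(rep2$bad$criterion_b, 0L)
})

test_that("flagging is monotone in its thresholds", {
  res <- shared_result()
  tight <- flag_suspect_muscles(res$contrib, res$tau, res$events,
                                list(a_hcf_share = 0.3, a_moment_share = 0.02,
                                     b_min_duration = 0.10))
  loose <- flag_suspect_muscles(res$contrib, res$tau, res$events,
                                list(a_hcf_share = 0.05, a_moment_share = 0.2,
                                     b_min_duration = 0.02))
  for (g in names(tight)) {
    if (tight[[g]]$criterion_a) expect_true(loose[[g]]$criterion_a)
    expect_gte(length(loose[[g]]$criterion_b), length(tight[[g]]$criterion_b))
  }
})
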
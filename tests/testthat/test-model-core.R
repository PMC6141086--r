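test_that("dof counting follows the joint structure", {
  m <- minimal_hinge_model()
  expect_equal(n_dof(m), 7L)  # 6 floating base + 1 hinge

  ll <- make_toy_model("lowerlimb-12m")
  # 6 base + 3 (ball hip) + 1 (knee) + 1 (ankle); subtalar omitted in the toy
  expect_equal(n_dof(ll), 11L)
  expect_equal(length(ll$muscles), 12L)
})

test_that("model loading reports unresolved references and cycles", {
  cfg <- list(
    segments = list(list(name = "pelvis", mass = 1, length = 0.1),
                    list(name = "femur", mass = 1, length = 0.1)),
    joints = list(list(name = "hip", kind = "ball", parent = "pelvis",
                       child = "femur")),
    muscles = list(list(name = "bad", strength = 100,
                        nodes = list(list(segment = "pelvis", point = c(0, 0, 0)),
                                     list(segment = "femurX", point = c(0, 0, 0))))))
  expect_error(build_model(cfg), "femurX")

  cyc <- list(
    segments = list(list(name = "a", mass = 1, length = 0.1),
                    list(name = "b", mass = 1, length = 0.1)),
    joints = list(list(name = "j1", kind = "hinge", parent = "a", child = "b",
                       axis = c(0, 0, 1)),
                  list(name = "j2", kind = "hinge", parent = "b", child = "a",
                       axis = c(0, 0, 1))))
  expect_error(build_model(cyc), "parent joint|cycl|root")
})

test_that("forward kinematics honours reference pose and hinge rotations", {
  m <- minimal_hinge_model(axis = c(0, 0, 1))
  q0 <- rep(0, 7)
  poses <- forward_kinematics(m, q0)
  expect_equal(poses$base$R, diag(3))
  expect_equal(poses$arm$R, diag(3))
  expect_equal(poses$arm$p, c(0, 0, 0))

  q <- q0; q[7] <- pi / 2
  poses <- forward_kinematics(m, q)
  # child x-axis maps onto parent y-axis under a +90 deg z-hinge
  expect_equal(as.numeric(poses$arm$R %*% c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("chained and direct homogeneous-transform traversals agree", {
  m <- make_toy_model("lowerlimb-12m")
  # independent traversal: compose 4x4 homogeneous transforms per segment
  direct_pose <- function(model, q, target) {
    H <- function(R, p) rbind(cbind(R, p), c(0, 0, 0, 1))
    chain <- list()
    s <- target
    while (s != model$root) {
      jn <- model$segments[[s]]$parent_joint
      chain <- c(list(model$joints[[jn]]), chain)
      s <- model$joints[[jn]]$parent_segment
    }
    Hw <- H(hipforce:::euler_xyz(q[4:6]), q[1:3])
    for (j in chain) {
      qi <- model$dofs$joint_dofs[[j$name]]
      Rj <- if (j$kind == "ball") hipforce:::euler_xyz(q[qi]) else
        hipforce:::rot_axis(j$hinge_axis, q[qi])
      Hw <- Hw %*% H(diag(3), j$location_in_parent) %*% H(Rj, c(0, 0, 0)) %*%
        H(diag(3), -j$location_in_child)
    }
    Hw
  }
  set.seed(42)
  for (rep in 1:5) {
    q <- c(rnorm(3), rnorm(8, 0, 0.5))
    poses <- forward_kinematics(m, q)
    for (s in c("femur_r", "shank_r", "foot_r")) {
      Hw <- direct_pose(m, q, s)
      expect_equal(unname(Hw[1:3, 1:3]), poses[[s]]$R, tolerance = 1e-12)
      expect_equal(as.numeric(Hw[1:3, 4]), poses[[s]]$p, tolerance = 1e-12)
    }
  }
})

test_that("patella coupler interpolates within range and errors outside", {
  cfg <- list(
    segments = list(list(name = "femur", mass = 5, length = 0.4),
                    list(name = "tibia", mass = 3, length = 0.4),
                    list(name = "patella", mass = 0.1, length = 0.05)),
    joints = list(list(name = "knee", kind = "hinge", parent = "femur",
                       child = "tibia", axis = c(0, 1, 0),
                       location_in_parent = c(0, 0, -0.4))),
    couplers = list(list(knee_joint = "knee", segment = "patella",
                         table = list(c(0, 0.05, 0, -0.38, 0, 0, 0),
                                      c(1, 0.06, 0, -0.40, 0, 0.2, 0),
                                      c(2, 0.05, 0, -0.43, 0, 0.5, 0)))))
  m <- build_model(cfg)
  # root is femur: 6 base dofs + 1 knee; patella adds no dofs
  expect_equal(n_dof(m), 7L)
  q <- rep(0, 7); q[7] <- 0.5
  poses <- forward_kinematics(m, q)
  # linear interpolation midway between rows 1 and 2
  expect_equal(as.numeric(t(poses$femur$R) %*% (poses$patella$p - poses$femur$p)),
               c(0.055, 0, -0.39), tolerance = 1e-12)
  q[7] <- 2.5
  expect_error(forward_kinematics(m, q), "coupler table range")
})

test_that("identity scaling returns the model unchanged", {
  m <- make_toy_model("lowerlimb-12m")
  s <- scale_model(m, list(target_mass = m$subject_mass,
                           target_height = m$subject_height,
                           fat_fraction = 0.2, ref_fat_fraction = 0.2))
  expect_equal(s$segments, m$segments, tolerance = 1e-12)
  expect_equal(s$muscles, m$muscles, tolerance = 1e-12)
  expect_equal(s$markers, m$markers, tolerance = 1e-12)
})

test_that("per-segment scaling is linear in local geometry", {
  m <- make_toy_model("lowerlimb-12m")
  s <- scale_model(m, list(factors = list(femur_r = 2),
                           target_mass = m$subject_mass,
                           target_height = m$subject_height,
                           fat_fraction = 0.2, ref_fat_fraction = 0.2))
  expect_equal(s$segments$femur_r$length, 2 * m$segments$femur_r$length)
  for (mn in names(m$muscles)) {
    for (i in seq_along(m$muscles[[mn]]$nodes)) {
      nd0 <- m$muscles[[mn]]$nodes[[i]]
      nd1 <- s$muscles[[mn]]$nodes[[i]]
      fac <- if (nd0$segment == "femur_r") 2 else 1
      expect_equal(nd1$point, nd0$point * fac)
    }
  }
  expect_equal(s$joints$knee_r$location_in_parent,
               2 * m$joints$knee_r$location_in_parent)
  expect_equal(s$joints$hip_r$location_in_parent,
               m$joints$hip_r$location_in_parent)
})

test_that("scaled total mass matches the target and roundtrips invert", {
  m <- make_toy_model("lowerlimb-12m")
  sc <- list(factors = list(femur_r = 1.3, shank_r = 0.8),
             target_mass = 90, target_height = 1.80,
             fat_fraction = 0.25, ref_fat_fraction = 0.2)
  s <- scale_model(m, sc)
  expect_equal(total_mass(s), 90, tolerance = 1e-12)
  back <- scale_model(s, list(factors = list(femur_r = 1 / 1.3, shank_r = 1 / 0.8),
                              target_mass = m$subject_mass,
                              target_height = m$subject_height,
                              fat_fraction = 0.2, ref_fat_fraction = 0.25))
  for (seg in names(m$segments)) {
    expect_equal(back$segments[[seg]]$length, m$segments[[seg]]$length,
                 tolerance = 1e-10)
    expect_equal(back$segments[[seg]]$mass, m$segments[[seg]]$mass,
                 tolerance = 1e-10)
  }
  for (mn in names(m$muscles)) {
    expect_equal(back$muscles[[mn]]$strength, m$muscles[[mn]]$strength,
                 tolerance = 1e-10)
  }
  expect_error(scale_model(m, list(factors = list(femur_r = -1))), "> 0")
})

test_that("length-mass-fat strength factor matches its hand evaluation", {
  # 78 kg / 1.72 m target against a 75 kg / 1.75 m generic, femur scale 1.05
  f <- fat_fraction_from_bmi(78 / 1.72^2)
  f0 <- fat_fraction_from_bmi(75 / 1.75^2)
  got <- lmf_strength_factor(78 / 75, 1.05, f, f0)
  # hand evaluation of k = (1-f)/(1-f0) * k_m / k_l
  expect_equal(got, (1 - f) / (1 - f0) * (78 / 75) / 1.05, tolerance = 1e-14)
  # fat regression hand check: 1.28 * BMI - 10.13 percent
  bmi <- 78 / 1.72^2
  expect_equal(fat_fraction_from_bmi(bmi), (1.28 * bmi - 10.13) / 100,
               tolerance = 1e-14)
})
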
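# In-code fixtures used across the suite.

# Minimal two-segment, one-hinge, one-muscle model (7 dofs).
minimal_hinge_model <- function(n_muscles = 1L, axis = c(0, 1, 0)) {
  muscles <- list(
    list(name = "m1", group = "m1", strength = 1000,
         nodes = list(list(segment = "base", point = c(0, 0, 0.3)),
                      list(segment = "arm", point = c(0.3, 0, 0)))))
  if (n_muscles >= 2L) {
    muscles[[2]] <- list(name = "m2", group = "m2", strength = 1000,
                         nodes = list(list(segment = "base", point = c(0, 0, -0.3)),
                                      list(segment = "arm", point = c(0.3, 0, 0))))
  }
  build_model(list(
    name = "minimal",
    subject_mass = 7, subject_height = 1,
    segments = list(
      list(name = "base", mass = 5, com = c(0, 0, 0.1),
           inertia = c(0.05, 0.05, 0.05), length = 0.3),
      list(name = "arm", mass = 2, com = c(0.2, 0, 0),
           inertia = c(0.001, 0.03, 0.03), length = 0.4)),
    joints = list(
      list(name = "elbow", kind = "hinge", parent = "base", child = "arm",
           location_in_parent = c(0, 0, 0), location_in_child = c(0, 0, 0),
           axis = axis)),
    muscles = muscles))
}

# A hinge rig whose single muscle runs from a fixed base point to a point
# at radius rho on the rotating arm, with perpendicular geometry at q = 0:
# closed-form moment arm = rho.
perpendicular_arm_model <- function(rho = 0.1, reach = 0.5) {
  build_model(list(
    name = "perp",
    subject_mass = 3, subject_height = 1,
    segments = list(
      list(name = "base", mass = 2, com = c(0, 0, 0), inertia = c(0.01, 0.01, 0.01),
           length = 0.3),
      list(name = "arm", mass = 1, com = c(0.1, 0, 0), inertia = c(0.001, 0.01, 0.01),
           length = 0.3)),
    joints = list(
      list(name = "hinge", kind = "hinge", parent = "base", child = "arm",
           location_in_parent = c(0, 0, 0), location_in_child = c(0, 0, 0),
           axis = c(0, 0, 1))),
    muscles = list(
      # arm lies along +x; muscle pulls from far along -y on the base to a
      # point at radius rho on the arm: at q = 0 the muscle runs parallel
      # to -y, perpendicular to the radius vector
      list(name = "puller", group = "puller", strength = 1000,
           nodes = list(list(segment = "base", point = c(rho, -reach, 0)),
                        list(segment = "arm", point = c(rho, 0, 0)))))))
}

# Memoized shared lowerlimb pipeline run (reference generation included)
# so the acceptance tests reuse one solved trial.
shared_env <- new.env(parent = emptyenv())

shared_lowerlimb <- function() {
  if (is.null(shared_env$model)) {
    shared_env$model <- make_toy_model("lowerlimb-12m")
  }
  shared_env$model
}

shared_trial <- function() {
  if (is.null(shared_env$trial)) {
    shared_env$trial <- generate_gait_trial(shared_lowerlimb(), gait_params())
  }
  shared_env$trial
}

shared_result <- function() {
  if (is.null(shared_env$result)) {
    shared_env$result <- suppressMessages(
      run_pipeline(shared_lowerlimb(), shared_trial()))
  }
  shared_env$result
}
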
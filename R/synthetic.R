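#' Gait generator parameters
#'
#' Defaults emulate one steady gait cycle of an adult total-hip-replacement
#' patient (78 kg, 1.72 m class anthropometry): 1.0 s cycle sampled at
#' 100 Hz (101 frames, heel-strike to heel-strike), 60% stance, smooth
#' truncated-Fourier joint-angle profiles (up to 3 harmonics, closed-form
#' derivatives), a double-bump vertical GRF with moving centre of pressure
#' scaled so the cycle-average vertical force equals body weight, and
#' optional i.i.d. Gaussian marker noise.
#'
#' @param cycle_duration Cycle duration, s (default 1.0).
#' @param rate Sampling rate, Hz (>= 50; default 100).
#' @param stance_fraction Stance fraction of the cycle, in (0.3, 0.8)
#'   (default 0.6).
#' @param marker_noise_sd Marker noise standard deviation, m (default 0).
#' @param grf_peak_shape Relative amplitude of the third harmonic of the
#'   vertical GRF bump (controls the double-bump dip; default 0.4).
#' @param progression_speed Forward walking speed, m/s (default 1.25).
#' @param pelvis_height Mean pelvis origin height, m (default 0.92).
#' @param profiles Named list of joint-angle profiles: dof name ->
#'   `list(a0, a, b)` with angle(s) = a0 + sum_k a[k] cos(2 pi k s) +
#'   b[k] sin(2 pi k s), s in [0,1) cycle phase, rad.  `NULL` uses the
#'   built-in right-leg gait set.
#' @param seed Random seed for the marker noise (default 1).
#' @return List of class `gait_params`.
#' @export
gait_params <- function(cycle_duration = 1.0, rate = 100,
                        stance_fraction = 0.6, marker_noise_sd = 0,
                        grf_peak_shape = 0.4, progression_speed = 1.25,
                        pelvis_height = 0.92, profiles = NULL, seed = 1L) {
  if (rate < 50) stop("sampling rate must be >= 50 Hz", call. = FALSE)
  if (stance_fraction <= 0.3 || stance_fraction >= 0.8) {
    stop("stance fraction must lie in (0.3, 0.8)", call. = FALSE)
  }
  structure(list(cycle_duration = cycle_duration, rate = rate,
                 stance_fraction = stance_fraction,
                 marker_noise_sd = marker_noise_sd,
                 grf_peak_shape = grf_peak_shape,
                 progression_speed = progression_speed,
                 pelvis_height = pelvis_height,
                 profiles = profiles, seed = as.integer(seed)),
            class = "gait_params")
}

# Built-in right-leg joint-angle profiles (rad), phrased in the toy model's
# dof conventions (hip_r_ry > 0 = extension, knee_r_angle > 0 = flexion,
# ankle_r_angle > 0 = plantarflexion).
default_gait_profiles <- function(pelvis_height) {
  d <- pi / 180
  list(
    hip_r_rx = list(a0 = -0.02, a = c(0.02, 0, 0), b = c(0.04, 0, 0)),
    hip_r_ry = list(a0 = -7 * d, a = c(-20 * d, 0, 0), b = c(-5 * d, 0, 0)),
    hip_r_rz = list(a0 = 0, a = c(0.02, 0, 0), b = c(0.03, 0, 0)),
    knee_r_angle = list(a0 = 25 * d, a = c(-15 * d, 3 * d, 0),
                        b = c(-18 * d, 9 * d, 0)),
    ankle_r_angle = list(a0 = 0, a = c(-0.03, -0.04, 0), b = c(0.10, 0, 0)),
    pelvis_rx = list(a0 = 0, a = c(0.015, 0, 0), b = c(0.015, 0, 0)),
    pelvis_ry = list(a0 = 0, a = c(0, 0.01, 0), b = c(0.02, 0, 0)),
    pelvis_rz = list(a0 = 0, a = c(0.03, 0, 0), b = c(0.02, 0, 0)),
    pelvis_ty = list(a0 = 0, a = c(0, 0.01, 0), b = c(0.02, 0, 0)),
    pelvis_tz = list(a0 = pelvis_height, a = c(0, 0.012, 0), b = c(0, 0.008, 0))
  )
}

eval_profile <- function(pr, s) {
  out <- rep(pr$a0, length(s))
  for (k in seq_along(pr$a)) {
    out <- out + pr$a[k] * cos(2 * pi * k * s) + pr$b[k] * sin(2 * pi * k * s)
  }
  out
}

#' Generate a synthetic gait trial with known ground truth
#'
#' Builds one gait cycle: generalized coordinates from smooth periodic
#' profiles (plus linear forward progression of the pelvis), marker
#' trajectories by forward kinematics (plus optional Gaussian noise), a
#' double-bump vertical GRF with moving centre of pressure scaled so the
#' cycle-average vertical force equals body weight, and a reference hip
#' contact force computed by running the full analysis pipeline on the
#' noise-free trial with the uncorrupted model (self-consistent ground
#' truth, stored as the trial's `measured_hcf`).
#'
#' @param model A `skeletal_model` (e.g. `make_toy_model("lowerlimb-12m")`).
#' @param params A [gait_params()].
#' @param reference `"pipeline"` (default) computes the reference HCF by the
#'   full pipeline on the clean trial; `"none"` skips it (used internally).
#' @return List of class `gait_trial`: `time`, `rate`, `markers` (name ->
#'   frames x 3, m), `grf` (per-plate `segment`, `force`, `cop`, `moment`
#'   matrices), `measured_hcf` (frames x 3 AP/ML/PD, BW, or NULL),
#'   `events`, and `truth` (`qs`, `qd`, `qdd`, `hcf`, `params`).
#' @export
generate_gait_trial <- function(model, params = gait_params(),
                                reference = c("pipeline", "none")) {
  stopifnot(inherits(params, "gait_params"))
  reference <- match.arg(reference)
  rate <- params$rate
  nfr <- round(params$cycle_duration * rate) + 1L
  time <- seq(0, params$cycle_duration, length.out = nfr)
  s <- (time / params$cycle_duration) %% 1
  s[nfr] <- 1 - 1e-12  # closing sample of the cycle

  profiles <- params$profiles %||% default_gait_profiles(params$pelvis_height)
  nd <- n_dof(model)
  qs <- matrix(0, nfr, nd, dimnames = list(NULL, dof_names(model)))
  root <- model$root
  base_map <- c(paste0(root, "_tx"), paste0(root, "_ty"), paste0(root, "_tz"),
                paste0(root, "_rx"), paste0(root, "_ry"), paste0(root, "_rz"))
  alias <- stats::setNames(base_map,
                           c("pelvis_tx", "pelvis_ty", "pelvis_tz",
                             "pelvis_rx", "pelvis_ry", "pelvis_rz"))
  for (nm in names(profiles)) {
    dof <- if (nm %in% names(alias)) alias[[nm]] else nm
    di <- match(dof, dof_names(model))
    if (is.na(di)) next
    qs[, di] <- eval_profile(profiles[[nm]], s)
  }
  qs[, base_map[1]] <- qs[, base_map[1]] +
    params$progression_speed * time
  if (!(paste0(root, "_tz") %in% names(profiles)) &&
      !("pelvis_tz" %in% names(profiles))) {
    qs[, base_map[3]] <- params$pelvis_height
  }

  # markers by forward kinematics (+ optional noise)
  set.seed(params$seed)
  markers <- stats::setNames(
    vector("list", length(model$markers)), names(model$markers))
  poses_per_frame <- vector("list", nfr)
  for (k in seq_len(nfr)) poses_per_frame[[k]] <- forward_kinematics(model, qs[k, ])
  for (mn in names(model$markers)) {
    mk <- model$markers[[mn]]
    tr <- t(vapply(seq_len(nfr), function(k)
      world_point(poses_per_frame[[k]], mk$segment, mk$point), numeric(3)))
    if (params$marker_noise_sd > 0) {
      tr <- tr + matrix(stats::rnorm(length(tr), sd = params$marker_noise_sd),
                        nrow = nfr)
    }
    markers[[mn]] <- tr
  }

  # double-bump vertical GRF, scaled so the cycle-average vertical force
  # equals body weight; fore-aft braking/propulsion and small ML shear
  bw <- body_weight(model)
  fst <- params$stance_fraction
  stance <- s < fst
  u <- ifelse(stance, s / fst, 0)
  bump <- ifelse(stance, pmax(0, sin(pi * u) +
                                params$grf_peak_shape * sin(3 * pi * u)), 0)
  scale_c <- bw / mean(bump)
  fz <- scale_c * bump
  fx <- ifelse(stance, -0.15 * bw * sin(2 * pi * u), 0)
  fy <- ifelse(stance, 0.03 * bw * sin(pi * u), 0)
  foot_seg <- grep("foot", names(model$segments), value = TRUE)[1]
  foot_xy <- t(vapply(seq_len(nfr), function(k)
    poses_per_frame[[k]][[foot_seg]]$p, numeric(3)))
  cop <- cbind(foot_xy[, 1] + (-0.04 + 0.22 * u), foot_xy[, 2], 0)
  cop[!stance, ] <- 0
  grf <- list(list(segment = foot_seg,
                   force = cbind(fx, fy, fz, deparse.level = 0),
                   cop = cop,
                   moment = matrix(0, nfr, 3)))

  trial <- structure(list(time = time, rate = rate, markers = markers,
                          grf = grf, measured_hcf = NULL, events = NULL,
                          truth = list(qs = qs, params = params)),
                     class = "gait_trial")

  if (reference == "pipeline") {
    clean <- trial
    if (params$marker_noise_sd > 0) {
      # reference is defined on the noise-free trial
      clean_params <- params
      clean_params$marker_noise_sd <- 0
      clean <- generate_gait_trial(model, clean_params, reference = "none")
    }
    res <- pipeline_core(model, clean, pipeline_config())
    trial$measured_hcf <- res$hcf_femur
    trial$truth$hcf <- res$hcf_femur
    trial$truth$qs_ik <- res$qs
  }
  trial
}

#' Toy model catalogue
#'
#' Shipped, fully documented fixtures: `"planar-2seg"` (ground + one link on
#' a hinge, two antagonist muscles; closed-form testable), `"hip-abductor-rig"`
#' (pelvis + femur on a ball hip, three abductor elements each wrapping a
#' pelvis-fixed cylinder), `"lowerlimb-12m"` (3D pelvis-femur-shank-foot leg,
#' 12 muscle elements spanning hip and knee including two biarticular
#' hamstring-like elements with femoral-condyle wrap cylinders).  All numbers
#' live in the fixture YAML files under `extdata/`.
#'
#' @param name Catalogue entry name.
#' @return A `skeletal_model`.
#' @export
make_toy_model <- function(name) {
  catalogue <- c("planar-2seg", "hip-abductor-rig", "lowerlimb-12m")
  if (!name %in% catalogue) {
    stop("unknown toy model '", name, "'; catalogue: ",
         paste(catalogue, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".yaml"), package = "hipforce")
  if (path == "") {
    stop("fixture file for '", name, "' not found", call. = FALSE)
  }
  build_model(path)
}

#' Perturb a model's muscle geometry
#'
#' Creates a modified copy for defect studies: remove wrap cylinders, shift
#' muscle origins (first path node), or shift via points (interior nodes).
#'
#' @param model A `skeletal_model`.
#' @param perturbation List with `type` (`"remove-wrap"`, `"shift-origin"`,
#'   `"shift-via"`), `muscles` (character vector of element names, or a
#'   regular expression in `pattern`), and for shifts `delta` (local
#'   3-vector, m).
#' @return Modified model; attribute `"diff"` lists the changed entities.
#' @export
perturb_model <- function(model, perturbation) {
  type <- match.arg(perturbation$type,
                    c("remove-wrap", "shift-origin", "shift-via"))
  targets <- perturbation$muscles %||%
    grep(perturbation$pattern, names(model$muscles), value = TRUE)
  missing <- setdiff(targets, names(model$muscles))
  if (length(missing) > 0 || length(targets) == 0L) {
    stop("perturbation targets not found: ",
         paste(if (length(missing)) missing else "(none matched)",
               collapse = ", "), call. = FALSE)
  }
  diff <- list()
  for (mn in targets) {
    m <- model$muscles[[mn]]
    if (type == "remove-wrap") {
      if (length(m$wraps) > 0) diff[[mn]] <- "wraps removed"
      m$wraps <- list()
    } else if (type == "shift-origin") {
      delta <- as.numeric(perturbation$delta)
      m$nodes[[1]]$point <- m$nodes[[1]]$point + delta
      if (any(delta != 0)) diff[[mn]] <- "origin shifted"
    } else {
      delta <- as.numeric(perturbation$delta)
      if (length(m$nodes) > 2L) {
        for (i in 2:(length(m$nodes) - 1L)) {
          m$nodes[[i]]$point <- m$nodes[[i]]$point + delta
        }
        if (any(delta != 0)) diff[[mn]] <- "via points shifted"
      }
    }
    model$muscles[[mn]] <- m
  }
  attr(model, "diff") <- diff
  model
}

#' Place n muscle-element origins evenly along an attachment polyline
#'
#' Helper for redistributing element origins over the span of an attachment
#' area described as a polyline in the owner segment's frame.
#'
#' @param polyline k x 3 matrix of local polyline vertices (m).
#' @param n Number of origins to place.
#' @return n x 3 matrix of local points, evenly spaced by arc length.
#' @export
distribute_origins <- function(polyline, n) {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 3L, nrow(polyline) >= 2L, n >= 1L)
  seg_len <- sqrt(rowSums(diff(polyline)^2))
  cum <- c(0, cumsum(seg_len))
  targets <- seq(0, cum[length(cum)], length.out = n)
  t(vapply(targets, function(d) {
    i <- max(1L, min(nrow(polyline) - 1L, findInterval(d, cum)))
    w <- (d - cum[i]) / max(seg_len[i], 1e-300)
    polyline[i, ] + w * (polyline[i + 1L, ] - polyline[i, ])
  }, numeric(3)))
}
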
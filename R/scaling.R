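#' Anthropometric scaling of a skeletal model
#'
#' Linearly scales each segment's geometry (length, centre of mass, joint
#' attachment points, muscle path nodes, wrap-cylinder placement and radius,
#' marker positions) by a per-segment factor; redistributes segment masses so
#' the total equals `target_mass` while preserving the generic model's mass
#' fractions; rescales rotational inertia by mass x length-scale^2; and
#' multiplies every muscle strength by the length-mass-fat factor (see
#' [lmf_strength_factor()]).  The input model is not modified.
#'
#' @param model A `skeletal_model`.
#' @param scaling A list with `factors` (named per-segment length scale
#'   factors; segments not named keep factor 1), `target_mass` (kg),
#'   `target_height` (m), and optionally `fat_fraction` (in `[0,1)`; defaults
#'   to [fat_fraction_from_bmi()] of the target) and `ref_fat_fraction`
#'   (defaults to the generic model's BMI-derived value).
#' @return A new, scaled `skeletal_model`.
#' @export
scale_model <- function(model, scaling) {
  factors <- scaling$factors %||% list()
  fac <- rep(1, length(model$segments))
  names(fac) <- names(model$segments)
  for (nmf in names(factors)) {
    if (is.null(model$segments[[nmf]])) {
      stop("scaling factor for unknown segment '", nmf, "'", call. = FALSE)
    }
    fac[nmf] <- as.numeric(factors[[nmf]])
  }
  if (any(fac <= 0)) {
    stop("scale factors must be > 0 (offenders: ",
         paste(names(fac)[fac <= 0], collapse = ", "), ")", call. = FALSE)
  }
  target_mass <- scaling$target_mass %||% model$subject_mass
  target_height <- scaling$target_height %||% model$subject_height
  if (target_mass <= 0) stop("target_mass must be > 0", call. = FALSE)

  generic_mass <- total_mass(model)
  fractions <- vapply(model$segments, function(s)
    s$mass_fraction %||% (s$mass / generic_mass), 0)
  fractions <- fractions / sum(fractions)

  ref_fat <- scaling$ref_fat_fraction %||%
    fat_fraction_from_bmi(model$subject_mass / model$subject_height^2)
  fat <- scaling$fat_fraction %||%
    fat_fraction_from_bmi(target_mass / target_height^2)
  if (fat < 0 || fat >= 1) stop("fat_fraction must lie in [0, 1)", call. = FALSE)

  out <- model
  for (s in names(out$segments)) {
    k <- unname(fac[s])
    seg <- out$segments[[s]]
    new_mass <- unname(fractions[s] * target_mass)
    mass_ratio <- if (seg$mass > 0) new_mass / seg$mass else 1
    seg$com_local <- seg$com_local * k
    seg$length <- seg$length * k
    seg$inertia_local <- seg$inertia_local * mass_ratio * k^2
    seg$mass <- new_mass
    out$segments[[s]] <- seg
  }
  for (jn in names(out$joints)) {
    j <- out$joints[[jn]]
    j$location_in_parent <- j$location_in_parent * unname(fac[j$parent_segment])
    j$location_in_child <- j$location_in_child * unname(fac[j$child_segment])
    out$joints[[jn]] <- j
  }
  for (cn in names(out$couplers)) {
    cp <- out$couplers[[cn]]
    fem <- out$joints[[cp$knee_joint]]$parent_segment
    cp$table[, 2:4] <- cp$table[, 2:4] * unname(fac[fem])
    out$couplers[[cn]] <- cp
  }
  for (mn in names(out$muscles)) {
    m <- out$muscles[[mn]]
    m$nodes <- lapply(m$nodes, function(nd) {
      nd$point <- nd$point * unname(fac[nd$segment])
      nd
    })
    m$wraps <- lapply(m$wraps, function(w) {
      w$center <- w$center * unname(fac[w$segment])
      w$radius <- w$radius * unname(fac[w$segment])
      w
    })
    seg_of_origin <- m$nodes[[1]]$segment
    m$strength <- m$strength * lmf_strength_factor(
      mass_ratio = target_mass / generic_mass,
      length_scale = unname(fac[seg_of_origin]),
      fat_fraction = fat, ref_fat_fraction = ref_fat)
    out$muscles[[mn]] <- m
  }
  for (kn in names(out$markers)) {
    mk <- out$markers[[kn]]
    mk$point <- mk$point * unname(fac[mk$segment])
    out$markers[[kn]] <- mk
  }
  if (!is.null(out$femur_frame)) {
    k <- unname(fac[out$femur_frame$segment])
    out$femur_frame$hip_point <- as.numeric(out$femur_frame$hip_point) * k
    out$femur_frame$knee_point <- as.numeric(out$femur_frame$knee_point) * k
  }
  out$subject_mass <- target_mass
  out$subject_height <- target_height
  out
}

#' Length-mass-fat muscle strength scaling factor
#'
#' Strength of a constant-strength actuator is taken proportional to its
#' physiological cross-sectional area, i.e. to lean muscle mass divided by
#' muscle length.  Scaling body mass by `mass_ratio`, the owning segment's
#' length by `length_scale`, and the body-fat fraction from
#' `ref_fat_fraction` to `fat_fraction` therefore multiplies strength by
#'
#' \deqn{k_S = \frac{(1-f)\,k_m}{(1-f_0)\,k_l}}
#'
#' where `k_m` is the mass ratio, `k_l` the length scale, and `f`, `f_0` the
#' target and generic fat fractions.
#'
#' @param mass_ratio Target body mass / generic body mass.
#' @param length_scale Length scale factor of the segment the muscle
#'   originates on.
#' @param fat_fraction Target body-fat fraction in `[0, 1)`.
#' @param ref_fat_fraction Generic-model body-fat fraction in `[0, 1)`.
#' @return Dimensionless strength multiplier.
#' @export
lmf_strength_factor <- function(mass_ratio, length_scale,
                                fat_fraction, ref_fat_fraction) {
  stopifnot(mass_ratio > 0, length_scale > 0,
            fat_fraction >= 0, fat_fraction < 1,
            ref_fat_fraction >= 0, ref_fat_fraction < 1)
  (1 - fat_fraction) / (1 - ref_fat_fraction) * mass_ratio / length_scale
}

#' Body-fat fraction estimated from body mass index
#'
#' A linear BMI regression of percent body fat, kept in this one function so
#' the constants can be swapped for any preferred published regression.  The
#' default constants are a Frankenfield-type adult-male fit,
#' fat% = 1.28 * BMI - 10.13, clamped to `[0.05, 0.6]`.
#'
#' @param bmi Body mass index, kg/m^2.
#' @return Fat fraction (dimensionless).
#' @export
fat_fraction_from_bmi <- function(bmi) {
  stopifnot(bmi > 0)
  f <- (1.28 * bmi - 10.13) / 100
  min(max(f, 0.05), 0.60)
}

#' Hip joint centre location from pelvis anthropometry
#'
#' Affine regression of the hip joint centre in the pelvis frame from pelvis
#' width (inter-ASIS distance), pelvis depth (ASIS-midpoint to PSIS-midpoint)
#' and leg length, after Harrington et al.'s three-predictor equations.  The
#' pelvis frame here is: origin at the mid-ASIS point, x anterior, y
#' superior, z to the subject's right.  Inputs and output in meters.
#'
#' @param pelvis_width Inter-ASIS distance, m (> 0).
#' @param pelvis_depth ASIS-midpoint to PSIS-midpoint distance, m (> 0).
#' @param leg_length Leg length, m (> 0).
#' @param side `"right"` or `"left"`; the two are mirror-symmetric about the
#'   sagittal (z = 0) plane.
#' @return 3-vector (x, y, z) in the pelvis frame, m.
#' @export
harrington_hjc <- function(pelvis_width, pelvis_depth, leg_length,
                           side = c("right", "left")) {
  side <- match.arg(side)
  if (pelvis_width <= 0 || pelvis_depth <= 0 || leg_length <= 0) {
    stop("pelvis dimensions and leg length must be > 0", call. = FALSE)
  }
  pw <- pelvis_width * 1000
  pd <- pelvis_depth * 1000
  ll <- leg_length * 1000
  x <- -0.24 * pd - 9.9
  y <- -0.16 * pw - 0.04 * ll - 7.1
  z <- 0.28 * pd + 0.16 * pw + 7.9
  if (side == "left") z <- -z
  c(x, y, z) / 1000
}
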
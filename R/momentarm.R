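#' Muscle moment arm about a generalized coordinate (tendon excursion)
#'
#' The moment arm is defined by the tendon-excursion method,
#' `-dL/dq`, evaluated by Richardson-extrapolated central differences of the
#' muscle-tendon length.  Positive arm means positive muscle tension makes a
#' positive generalized force on that dof.
#'
#' @param model A `skeletal_model`.
#' @param q Generalized coordinates.
#' @param muscle Muscle element (or name).
#' @param dof Dof name (see [dof_names()]) or index.
#' @param h Base finite-difference step, rad (default 1e-5).
#' @return Signed moment arm in m, with attribute `spans` — `FALSE` (and
#'   value 0) when the muscle does not span the joint owning the dof.
#' @export
moment_arm <- function(model, q, muscle, dof, h = 1e-5) {
  di <- dof_index(model, dof)
  jn <- model$dofs$joint_of[di]
  if (is.na(jn) || !muscle_spans_joint(model, muscle, jn)) {
    return(structure(0, spans = FALSE))
  }
  lenq <- function(qq) muscle_length(model, forward_kinematics(model, qq), muscle)
  qp <- q
  f <- function(step) { qp[di] <- q[di] + step; lenq(qp) }
  d1 <- (f(h) - f(-h)) / (2 * h)
  d2 <- (f(2 * h) - f(-2 * h)) / (4 * h)
  structure(-(4 * d1 - d2) / 3, spans = TRUE)
}

dof_index <- function(model, dof) {
  if (is.numeric(dof)) return(as.integer(dof))
  di <- match(dof, model$dofs$names)
  if (is.na(di)) stop("unknown dof '", dof, "'", call. = FALSE)
  di
}

#' Moment-arm matrix for a set of muscles and dofs
#'
#' Rows are dofs, columns muscle elements; entries are tendon-excursion
#' moment arms (m).  Entries for muscles not spanning a dof's joint are 0.
#'
#' @param model A `skeletal_model`.
#' @param q Generalized coordinates.
#' @param dofs Character vector of dof names (default: all joint dofs).
#' @param muscles Character vector of muscle names (default: all).
#' @param h Finite-difference step, rad.
#' @return `length(dofs)` x `length(muscles)` numeric matrix.
#' @export
moment_arm_matrix <- function(model, q,
                              dofs = joint_dof_names(model),
                              muscles = names(model$muscles), h = 1e-5) {
  nm <- length(muscles)
  spans <- matrix(FALSE, length(dofs), nm, dimnames = list(dofs, muscles))
  for (d in seq_along(dofs)) {
    jn <- model$dofs$joint_of[dof_index(model, dofs[d])]
    if (is.na(jn)) next
    for (m in seq_len(nm)) {
      spans[d, m] <- muscle_spans_joint(model, muscles[m], jn)
    }
  }
  lengths_at <- function(qq) {
    poses <- forward_kinematics(model, qq)
    vapply(muscles, function(mn) muscle_length(model, poses, mn), 0)
  }
  R <- matrix(0, length(dofs), nm, dimnames = list(dofs, muscles))
  for (d in seq_along(dofs)) {
    if (!any(spans[d, ])) next
    di <- dof_index(model, dofs[d])
    qp <- q
    ls <- lapply(c(h, -h, 2 * h, -2 * h), function(st) {
      qp[di] <- q[di] + st
      lengths_at(qp)
    })
    d1 <- (ls[[1]] - ls[[2]]) / (2 * h)
    d2 <- (ls[[3]] - ls[[4]]) / (4 * h)
    R[d, ] <- -(4 * d1 - d2) / 3 * spans[d, ]
  }
  R
}

#' All joint (non-floating-base) dof names
#' @param model A `skeletal_model`.
#' @return Character vector.
#' @export
joint_dof_names <- function(model) {
  model$dofs$names[!is.na(model$dofs$joint_of)]
}

#' Moment-arm sweep over a joint-angle grid
#'
#' Evaluates the moment arm of one muscle about one dof over a grid of that
#' dof's angles (all other coordinates held at `q_base`), records wrap
#' engagement, and flags discontinuities: adjacent-gridpoint arm jumps larger
#' than `jump_threshold`, the signature of a muscle path snapping on or off
#' a wrapping surface or sliding past an attachment.
#'
#' @param model A `skeletal_model`.
#' @param muscle Muscle element name.
#' @param dof Dof name.
#' @param angles Numeric grid of angles, rad (may be empty).
#' @param q_base Baseline posture (default all-zero).
#' @param jump_threshold Arm jump (m) between adjacent grid points flagged
#'   as a discontinuity (default 0.01).
#' @return Data frame with columns `angle_rad`, `arm_m`, `engaged`,
#'   `discontinuity`.
#' @export
moment_arm_sweep <- function(model, muscle, dof, angles,
                             q_base = rep(0, n_dof(model)),
                             jump_threshold = 0.01) {
  if (length(angles) == 0L) {
    return(data.frame(angle_rad = numeric(0), arm_m = numeric(0),
                      engaged = logical(0), discontinuity = logical(0)))
  }
  di <- dof_index(model, dof)
  rows <- lapply(angles, function(a) {
    qq <- q_base
    qq[di] <- a
    arm <- moment_arm(model, qq, muscle, dof)
    eng <- compute_path(model, forward_kinematics(model, qq), muscle)$engaged
    list(arm = as.numeric(arm), engaged = length(eng) > 0 && any(eng))
  })
  arm <- vapply(rows, `[[`, 0, "arm")
  engaged <- vapply(rows, `[[`, TRUE, "engaged")
  disc <- c(FALSE, abs(diff(arm)) > jump_threshold)
  data.frame(angle_rad = angles, arm_m = arm, engaged = engaged,
             discontinuity = disc)
}

#' Write a moment-arm sweep table to CSV
#'
#' Columns `angle_deg`, `arm_mm`, `engaged` (plus the discontinuity flag).
#'
#' @param sweep Output of [moment_arm_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  out <- data.frame(angle_deg = sweep$angle_rad * 180 / pi,
                    arm_mm = sweep$arm_m * 1000,
                    engaged = sweep$engaged,
                    discontinuity = sweep$discontinuity)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
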
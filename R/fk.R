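#' Forward kinematics: world pose of every segment
#'
#' Propagates poses from the floating base through the joint tree.  Ball
#' joints use an intrinsic XYZ Euler parameterization, hinges rotate about
#' their stored axis.  Patella-coupler segments get their pose from the knee
#' flexion angle via the coupler table (no dofs added).
#'
#' @param model A `skeletal_model`.
#' @param q Numeric vector of generalized coordinates, length `n_dof(model)`:
#'   world translation of the root (3), root XYZ Euler angles (3), then joint
#'   dofs in tree order (rad).
#' @return Named list (one entry per segment) of lists with `R` (3x3 world
#'   rotation) and `p` (3-vector world position of the segment frame origin).
#' @export
forward_kinematics <- function(model, q) {
  kin_state(model, q)$poses
}

# Full kinematic state: poses plus (if qd/qdd given) world angular velocity
# `om`, angular acceleration `al`, frame-origin velocity `v` and acceleration
# `a` per segment.
kin_state <- function(model, q, qd = NULL, qdd = NULL) {
  nd <- model$dofs$n
  if (length(q) != nd) {
    stop("q has length ", length(q), " but model has ", nd, " dofs", call. = FALSE)
  }
  with_vel <- !is.null(qd)
  if (with_vel && is.null(qdd)) qdd <- rep(0, nd)
  if (!with_vel) { qd <- rep(0, nd); qdd <- rep(0, nd) }

  st <- list()
  abc <- q[4:6]
  E <- euler_rate_map(abc)
  Ed <- euler_rate_map_dot(abc, qd[4:6])
  st[[model$root]] <- list(
    R = euler_xyz(abc), p = q[1:3],
    om = as.numeric(E %*% qd[4:6]),
    al = as.numeric(E %*% qdd[4:6] + Ed %*% qd[4:6]),
    v = qd[1:3], a = qdd[1:3])

  for (s in model$order) {
    if (s == model$root) next
    cp <- model$couplers[[s]]
    if (!is.null(cp)) {
      st[[s]] <- coupler_state(model, st, cp, q, qd, qdd)
      next
    }
    jn <- model$segments[[s]]$parent_joint
    j <- model$joints[[jn]]
    par <- st[[j$parent_segment]]
    qi <- model$dofs$joint_dofs[[jn]]
    if (j$kind == "ball") {
      ang <- q[qi]
      Rj <- euler_xyz(ang)
      Ej <- euler_rate_map(ang)
      Edj <- euler_rate_map_dot(ang, qd[qi])
      w_rel_l <- as.numeric(Ej %*% qd[qi])
      wd_rel_l <- as.numeric(Ej %*% qdd[qi] + Edj %*% qd[qi])
    } else {
      Rj <- rot_axis(j$hinge_axis, q[qi])
      w_rel_l <- j$hinge_axis * qd[qi]
      wd_rel_l <- j$hinge_axis * qdd[qi]
    }
    w_rel <- as.numeric(par$R %*% w_rel_l)
    wd_rel <- as.numeric(par$R %*% wd_rel_l) + cross3(par$om, w_rel)
    Rc <- par$R %*% Rj
    om <- par$om + w_rel
    al <- par$al + wd_rel
    rp <- as.numeric(par$R %*% j$location_in_parent)
    rc <- as.numeric(Rc %*% j$location_in_child)
    p <- par$p + rp - rc
    v <- par$v + cross3(par$om, rp) - cross3(om, rc)
    a <- par$a + cross3(par$al, rp) + cross3(par$om, cross3(par$om, rp)) -
      cross3(al, rc) - cross3(om, cross3(om, rc))
    st[[s]] <- list(R = Rc, p = p, om = om, al = al, v = v, a = a)
  }
  list(poses = lapply(st, function(x) x[c("R", "p")]), states = st,
       q = q, qd = qd, qdd = qdd)
}

# Pose and derivatives of a coupled (patella) segment from the knee angle.
coupler_state <- function(model, st, cp, q, qd, qdd) {
  jn <- cp$knee_joint
  qi <- model$dofs$joint_dofs[[jn]]
  theta <- q[qi]; thd <- qd[qi]; thdd <- qdd[qi]
  ev <- coupler_eval(cp$table, theta)
  tr <- ev$val[1:3]; rr <- ev$val[4:6]
  dtr <- ev$dval[1:3] * thd; drr <- ev$dval[4:6] * thd
  ddtr <- ev$dval[1:3] * thdd; ddrr <- ev$dval[4:6] * thdd
  fem <- st[[model$joints[[jn]]$parent_segment]]
  Rf <- fem$R
  Rrel <- euler_xyz(rr)
  E <- euler_rate_map(rr)
  Ed <- euler_rate_map_dot(rr, drr)
  w_rel <- as.numeric(Rf %*% (E %*% drr))
  wd_rel <- as.numeric(Rf %*% (E %*% ddrr + Ed %*% drr)) + cross3(fem$om, w_rel)
  om <- fem$om + w_rel
  al <- fem$al + wd_rel
  rt <- as.numeric(Rf %*% tr)
  p <- fem$p + rt
  v <- fem$v + cross3(fem$om, rt) + as.numeric(Rf %*% dtr)
  a <- fem$a + cross3(fem$al, rt) + cross3(fem$om, cross3(fem$om, rt)) +
    2 * cross3(fem$om, as.numeric(Rf %*% dtr)) + as.numeric(Rf %*% ddtr)
  list(R = Rf %*% Rrel, p = p, om = om, al = al, v = v, a = a)
}

# Piecewise-linear interpolation of the coupler pose table; errors outside
# the tabulated knee-angle range.
coupler_eval <- function(table, theta) {
  ang <- table[, 1]
  if (theta < ang[1] - 1e-12 || theta > ang[length(ang)] + 1e-12) {
    stop("knee angle ", signif(theta, 6), " rad outside coupler table range [",
         signif(ang[1], 6), ", ", signif(ang[length(ang)], 6), "]", call. = FALSE)
  }
  theta <- min(max(theta, ang[1]), ang[length(ang)])
  i <- max(1L, min(length(ang) - 1L, findInterval(theta, ang)))
  w <- (theta - ang[i]) / (ang[i + 1] - ang[i])
  lo <- table[i, -1]; hi <- table[i + 1, -1]
  list(val = lo + w * (hi - lo), dval = (hi - lo) / (ang[i + 1] - ang[i]))
}

# World position of a point given in a segment's local frame.
world_point <- function(poses, segment, local) {
  ps <- poses[[segment]]
  as.numeric(ps$p + ps$R %*% local)
}

#' Model ("virtual") marker positions for a posture
#'
#' @param model A `skeletal_model` with a marker protocol.
#' @param poses Output of [forward_kinematics()].
#' @return 3 x n matrix of world marker positions, columns named by marker.
#' @export
virtual_markers <- function(model, poses) {
  out <- vapply(model$markers, function(mk)
    world_point(poses, mk$segment, mk$point), numeric(3))
  out
}
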
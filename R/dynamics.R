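#' Recursive Newton-Euler inverse dynamics
#'
#' Computes, per frame, the net force and moment that all structures crossing
#' each joint must supply, by a leaf-to-root recursion over the segment tree:
#' each segment's Newton and Euler balances (gravity, external loads,
#' inertial terms from the segment's world acceleration and angular motion)
#' are closed by the joint wrench from its parent.  The floating-base residual
#' wrench at the root (what the environment or upper body must apply to the
#' pelvis) is reported alongside.
#'
#' @param model A `skeletal_model`.
#' @param qs,qds,qdds Numeric matrices, frames x dofs (velocities and
#'   accelerations from differentiating the filtered coordinate series, see
#'   [differentiate_q()]).
#' @param loads External load set: a list of length `nrow(qs)`; each element
#'   a list of loads `list(segment, force, point, moment)` (world N, world m,
#'   world N m free moment).  Use [grf_to_loads()] to build one from force
#'   plate records.
#' @return Object of class `net_joint_loads`: list with `frames` (per frame:
#'   per-joint `force`, `moment` (world, about the joint centre),
#'   `moment_child` (child-frame), `hinge_moment` (scalar, hinges),
#'   `base_residual` (6-vector force/moment at the root origin), `tau`
#'   (named generalized torques over joint dofs)) and `model` dof metadata.
#' @export
inverse_dynamics <- function(model, qs, qds, qdds, loads = NULL) {
  nfr <- nrow(qs)
  if (is.null(loads)) loads <- rep(list(list()), nfr)
  if (length(loads) != nfr) {
    stop("external loads (", length(loads), " frames) are not synchronized ",
         "with the posture series (", nfr, " frames)", call. = FALSE)
  }
  frames <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    frames[[k]] <- id_frame(model, qs[k, ], qds[k, ], qdds[k, ], loads[[k]])
  }
  structure(list(frames = frames, n_frames = nfr,
                 joint_names = names(model$joints)),
            class = "net_joint_loads")
}

# Single-frame Newton-Euler pass.
id_frame <- function(model, q, qd, qdd, frame_loads) {
  ks <- kin_state(model, q, qd, qdd)
  st <- ks$states
  g <- model$gravity

  loads_by_seg <- split(frame_loads,
                        vapply(frame_loads, `[[`, "", "segment"))

  # children (including coupled patellae) and the world joint point
  # connecting each non-root segment to its parent
  parent_of <- list(); joint_pt <- list(); joint_name <- list()
  for (j in model$joints) {
    parent_of[[j$child_segment]] <- j$parent_segment
    joint_pt[[j$child_segment]] <-
      world_point(ks$poses, j$parent_segment, j$location_in_parent)
    joint_name[[j$child_segment]] <- j$name
  }
  for (cp in model$couplers) {
    fem <- model$joints[[cp$knee_joint]]$parent_segment
    parent_of[[cp$segment]] <- fem
    joint_pt[[cp$segment]] <- st[[cp$segment]]$p
    joint_name[[cp$segment]] <- NA_character_
  }

  f_joint <- list(); m_joint <- list()
  for (s in rev(model$order)) {
    seg <- model$segments[[s]]
    ss <- st[[s]]
    r_com <- ss$p + as.numeric(ss$R %*% seg$com_local)
    a_com <- ss$a + cross3(ss$al, as.numeric(ss$R %*% seg$com_local)) +
      cross3(ss$om, cross3(ss$om, as.numeric(ss$R %*% seg$com_local)))
    Iw <- ss$R %*% seg$inertia_local %*% t(ss$R)
    f <- seg$mass * a_com - seg$mass * g
    m <- as.numeric(Iw %*% ss$al) + cross3(ss$om, as.numeric(Iw %*% ss$om))
    for (ld in loads_by_seg[[s]] %||% list()) {
      f <- f - ld$force
      m <- m - cross3(ld$point - r_com, ld$force) - (ld$moment %||% c(0, 0, 0))
    }
    for (ch in names(parent_of)) {
      if (parent_of[[ch]] != s) next
      f <- f + f_joint[[ch]]
      m <- m + m_joint[[ch]] + cross3(joint_pt[[ch]] - r_com, f_joint[[ch]])
    }
    jp <- if (s == model$root) ss$p else joint_pt[[s]]
    f_joint[[s]] <- f
    m_joint[[s]] <- m - cross3(jp - r_com, f)
  }

  out <- list()
  for (j in model$joints) {
    ch <- j$child_segment
    Rp <- st[[j$parent_segment]]$R
    Mw <- m_joint[[ch]]
    res <- list(force = f_joint[[ch]], moment = Mw,
                moment_child = as.numeric(t(st[[ch]]$R) %*% Mw))
    if (j$kind == "hinge") {
      res$hinge_moment <- sum(as.numeric(Rp %*% j$hinge_axis) * Mw)
    }
    out[[j$name]] <- res
  }

  tau <- numeric(0)
  for (jn in names(model$dofs$joint_dofs)) {
    j <- model$joints[[jn]]
    qi <- model$dofs$joint_dofs[[jn]]
    Rp <- st[[j$parent_segment]]$R
    Mw <- m_joint[[j$child_segment]]
    tj <- if (j$kind == "ball") {
      as.numeric(t(euler_rate_map(q[qi])) %*% t(Rp) %*% Mw)
    } else {
      sum(as.numeric(Rp %*% j$hinge_axis) * Mw)
    }
    names(tj) <- model$dofs$names[qi]
    tau <- c(tau, tj)
  }

  list(joints = out, tau = tau,
       base_residual = c(f_joint[[model$root]], m_joint[[model$root]]))
}

#' Free-body force terms of the limb distal to a joint
#'
#' For the set of segments distal to `cut_joint` (for the hip: the whole
#' leg), computes per frame the inertial force `F_inertial = -sum m_s a_s`
#' (d'Alembert sign: a force that, added to the applied forces, closes
#' Newton's balance), the gravity force `F_gravity = sum m_s g`, and the sum
#' of external (ground reaction) forces applied to distal segments.
#'
#' @inheritParams inverse_dynamics
#' @param cut_joint Joint name defining the cut (e.g. the hip).
#' @return List of per-frame lists with `F_inertial`, `F_gravity`, `GRF_sum`
#'   (world N).
#' @export
limb_free_body <- function(model, qs, qds, qdds, loads = NULL, cut_joint) {
  j <- model$joints[[cut_joint]]
  if (is.null(j)) stop("unknown joint '", cut_joint, "'", call. = FALSE)
  distal <- distal_segments(model, cut_joint)
  nfr <- nrow(qs)
  if (is.null(loads)) loads <- rep(list(list()), nfr)
  g <- model$gravity
  lapply(seq_len(nfr), function(k) {
    ks <- kin_state(model, qs[k, ], qds[k, ], qdds[k, ])
    Fi <- c(0, 0, 0); Fg <- c(0, 0, 0)
    for (s in distal) {
      seg <- model$segments[[s]]
      ss <- ks$states[[s]]
      rc <- as.numeric(ss$R %*% seg$com_local)
      a_com <- ss$a + cross3(ss$al, rc) + cross3(ss$om, cross3(ss$om, rc))
      Fi <- Fi - seg$mass * a_com
      Fg <- Fg + seg$mass * g
    }
    Fgrf <- c(0, 0, 0)
    for (ld in loads[[k]]) if (ld$segment %in% distal) Fgrf <- Fgrf + ld$force
    list(F_inertial = Fi, F_gravity = Fg, GRF_sum = Fgrf)
  })
}

#' Assign force-plate records to foot segments as external loads
#'
#' A plate's wrench is applied to its foot segment, at the centre of
#' pressure, on frames where the vertical force exceeds `threshold`
#' (stance); below threshold nothing is applied.
#'
#' @param grf List of per-plate records: `list(segment, force, cop, moment)`
#'   where `force`, `cop`, `moment` are frames x 3 matrices (world N / m /
#'   N m).
#' @param threshold Vertical-force stance threshold, N (default 20).
#' @param up_axis Index of the vertical world axis (default 3).
#' @return Per-frame external load list for [inverse_dynamics()].
#' @export
grf_to_loads <- function(grf, threshold = 20, up_axis = 3) {
  nfr <- nrow(grf[[1]]$force)
  lapply(seq_len(nfr), function(k) {
    out <- list()
    for (pl in grf) {
      if (pl$force[k, up_axis] > threshold) {
        out[[length(out) + 1L]] <- list(
          segment = pl$segment,
          force = pl$force[k, ],
          point = pl$cop[k, ],
          moment = if (!is.null(pl$moment)) pl$moment[k, ] else c(0, 0, 0))
      }
    }
    out
  })
}

#' Differentiate a coordinate series in time
#'
#' Central finite differences on interior samples, one-sided (first-order)
#' differences at the endpoints.
#'
#' @param qs Frames x dofs matrix.
#' @param rate Sampling rate, Hz.
#' @return List with `qd` and `qdd` matrices of the same shape.
#' @export
differentiate_q <- function(qs, rate) {
  dt <- 1 / rate
  n <- nrow(qs)
  d1 <- function(x) {
    out <- x
    if (n >= 3) out[2:(n - 1), ] <- (x[3:n, , drop = FALSE] -
                                       x[1:(n - 2), , drop = FALSE]) / (2 * dt)
    out[1, ] <- (x[2, ] - x[1, ]) / dt
    out[n, ] <- (x[n, ] - x[n - 1, ]) / dt
    out
  }
  qd <- d1(qs)
  qdd <- d1(qd)
  list(qd = qd, qdd = qdd)
}

#' Export net joint loads to a long-format data frame
#'
#' @param nl A `net_joint_loads` object.
#' @param times Optional frame times (s).
#' @return Data frame with columns `time_s`, `frame`, `joint`, `axis`,
#'   `moment_Nm`, `force_N`.
#' @export
net_loads_table <- function(nl, times = NULL) {
  rows <- list()
  for (k in seq_len(nl$n_frames)) {
    for (jn in nl$joint_names) {
      jl <- nl$frames[[k]]$joints[[jn]]
      for (ax in 1:3) {
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = if (is.null(times)) NA_real_ else times[k],
          frame = k, joint = jn, axis = c("x", "y", "z")[ax],
          moment_Nm = jl$moment[ax], force_N = jl$force[ax])
      }
    }
  }
  do.call(rbind, rows)
}
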
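# Independent oracles, kept free of the implementation paths they check.

# Generalized inertial/gravity/external forces by the d'Alembert
# virtual-work principle with Richardson-extrapolated finite-difference
# Jacobians.  Independent of the recursive Newton-Euler bookkeeping.
virtual_work_tau <- function(model, q, qd, qdd, frame_loads = list(),
                             h = 1e-4) {
  nd <- n_dof(model)
  ks <- hipforce:::kin_state(model, q, qd, qdd)
  g <- model$gravity
  segs <- names(model$segments)
  poses0 <- ks$poses
  cross3 <- hipforce:::cross3

  fd4 <- function(fun, d) {
    # Richardson: (8 f(h) - 8 f(-h) - f(2h) + f(-2h)) / (12 h)
    qa <- q; qa[d] <- q[d] + h
    qb <- q; qb[d] <- q[d] - h
    qc <- q; qc[d] <- q[d] + 2 * h
    qe <- q; qe[d] <- q[d] - 2 * h
    (8 * fun(qa) - 8 * fun(qb) - fun(qc) + fun(qe)) / (12 * h)
  }

  tau <- numeric(nd)
  for (d in seq_len(nd)) {
    for (s in segs) {
      seg <- model$segments[[s]]
      ss <- ks$states[[s]]
      Jc <- fd4(function(qq) hipforce:::world_point(
        forward_kinematics(model, qq), s, seg$com_local), d)
      dR <- fd4(function(qq) forward_kinematics(model, qq)[[s]]$R, d)
      W <- matrix(dR, 3, 3) %*% t(poses0[[s]]$R)
      Jr <- c(W[3, 2], W[1, 3], W[2, 1])
      rc <- as.numeric(ss$R %*% seg$com_local)
      a_com <- ss$a + cross3(ss$al, rc) + cross3(ss$om, cross3(ss$om, rc))
      Iw <- ss$R %*% seg$inertia_local %*% t(ss$R)
      Fin <- seg$mass * a_com - seg$mass * g
      Min <- as.numeric(Iw %*% ss$al) + cross3(ss$om, as.numeric(Iw %*% ss$om))
      tau[d] <- tau[d] + sum(Fin * Jc) + sum(Min * Jr)
      for (ld in frame_loads) {
        if (ld$segment != s) next
        loc <- as.numeric(t(poses0[[s]]$R) %*% (ld$point - poses0[[s]]$p))
        Jp <- fd4(function(qq) hipforce:::world_point(
          forward_kinematics(model, qq), s, loc), d)
        tau[d] <- tau[d] - sum(ld$force * Jp) -
          sum((ld$moment %||% c(0, 0, 0)) * Jr)
      }
    }
  }
  stats::setNames(tau, dof_names(model))
}

`%||%` <- hipforce:::`%||%`

# Newton-Euler output mapped onto the same generalized-force coordinates.
newton_euler_tau <- function(model, q, qd, qdd, frame_loads = list()) {
  fr <- hipforce:::id_frame(model, q, qd, qdd, frame_loads)
  E <- hipforce:::euler_rate_map(q[4:6])
  stats::setNames(c(fr$base_residual[1:3],
                    as.numeric(t(E) %*% fr$base_residual[4:6]), fr$tau),
                  dof_names(model))
}

# Brute-force shortest path around a cylinder (canonical frame: axis z,
# centre at origin): grid over entry/exit surface angles with unrolled z
# distribution, then Nelder-Mead refinement over (phi1, z1, phi2, z2).
# Direction of the surface geodesic follows `side`.
brute_wrap_length <- function(p, q, r, side, n_grid = 60) {
  helix <- function(phi1, z1, phi2, z2) {
    dphi <- (side * (phi2 - phi1)) %% (2 * pi)
    sqrt((r * dphi)^2 + (z2 - z1)^2)
  }
  seg_axis_dist <- function(a, b) {
    ab <- b[1:2] - a[1:2]
    den <- sum(ab^2)
    t <- if (den < 1e-30) 0 else min(1, max(0, -sum(a[1:2] * ab) / den))
    sqrt(sum((a[1:2] + t * ab)^2))
  }
  total <- function(par) {
    s1 <- c(r * cos(par[1]), r * sin(par[1]), par[2])
    s2 <- c(r * cos(par[3]), r * sin(par[3]), par[4])
    # straight pieces must stay outside the cylinder
    pen <- 1e3 * (max(0, r - seg_axis_dist(p, s1))^2 +
                    max(0, r - seg_axis_dist(s2, q))^2)
    sqrt(sum((p - s1)^2)) + helix(par[1], par[2], par[3], par[4]) +
      sqrt(sum((s2 - q)^2)) + pen
  }
  phis <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  best <- Inf; best_par <- NULL
  for (f1 in phis) for (f2 in phis) {
    dphi <- (side * (f2 - f1)) %% (2 * pi)
    # distribute z linearly over the projected path length
    l1 <- sqrt(max(sum(p[1:2]^2) - r^2, 0))
    l2 <- sqrt(max(sum(q[1:2]^2) - r^2, 0))
    D <- l1 + r * dphi + l2
    z1 <- p[3] + (q[3] - p[3]) * l1 / D
    z2 <- p[3] + (q[3] - p[3]) * (l1 + r * dphi) / D
    v <- total(c(f1, z1, f2, z2))
    if (v < best) { best <- v; best_par <- c(f1, z1, f2, z2) }
  }
  opt <- stats::optim(best_par, total, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# Dense grid-search oracle for the two-muscle recruitment problem:
# minimize (f1/N1)^p + (f2/N2)^p subject to r1 f1 + r2 f2 = tau, f >= 0.
grid_recruitment_2m <- function(tau, r1, r2, N1, N2, p = 3, n = 400001L) {
  f2_max <- tau / r2
  if (f2_max < 0) stop("oracle assumes positive arms and positive tau")
  f2 <- seq(0, f2_max, length.out = n)
  f1 <- (tau - r2 * f2) / r1
  ok <- f1 >= 0
  obj <- (f1[ok] / N1)^p + (f2[ok] / N2)^p
  i <- which.min(obj)
  c(f1 = f1[ok][i], f2 = f2[ok][i])
}

# Geometric moment arm for a straight joint-crossing path piece:
# ((anchor - joint_centre) x u) projected on the dof's instantaneous axis.
geometric_moment_arm <- function(model, q, muscle, joint, dof) {
  poses <- forward_kinematics(model, q)
  j <- model$joints[[joint]]
  loa <- line_of_action(model, poses, muscle, joint)
  jc <- hipforce:::world_point(poses, j$parent_segment, j$location_in_parent)
  qi <- model$dofs$joint_dofs[[joint]]
  di <- match(dof, dof_names(model))
  Rp <- poses[[j$parent_segment]]$R
  ax <- if (j$kind == "hinge") {
    as.numeric(Rp %*% j$hinge_axis)
  } else {
    E <- hipforce:::euler_rate_map(q[qi])
    as.numeric(Rp %*% E[, match(di, qi)])
  }
  sum(ax * hipforce:::cross3(loa$anchor - jc, loa$u))
}
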
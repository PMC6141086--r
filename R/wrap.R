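#' Shortest muscle path over a wrapping cylinder
#'
#' Computes the shortest path from `p_start` to `p_end` around an infinite
#' cylinder, on the side selected by the cylinder's `side` convention.  If
#' the straight segment clears the cylinder the path is straight
#' (`engaged = FALSE`); otherwise it is the C1 tangent-geodesic-tangent
#' path: two straight 3D segments touching the surface tangentially, joined
#' by a helical geodesic, with total length
#' `sqrt((l1 + r*dphi + l2)^2 + dz^2)` on the unrolled cylinder.
#'
#' @param p_start,p_end World 3-vectors, both strictly outside the cylinder.
#' @param cylinder List with `center` (3-vector), `axis` (unit 3-vector),
#'   `radius` (> 0), `side` (+1 or -1: sense of the wrap about `axis`,
#'   right-hand rule), all in the owner segment's local frame.
#' @param pose Owner segment world pose (`list(R, p)`); defaults to identity
#'   (cylinder given directly in world coordinates).
#' @return List with `engaged` (logical), `length` (m), `t1`, `t2` (world
#'   tangent points, `NULL` when not engaged), `arc_angle` (rad), and
#'   `arc_points(n)` (function sampling the wrapped surface arc).
#' @export
wrap_over_cylinder <- function(p_start, p_end, cylinder,
                               pose = list(R = diag(3), p = c(0, 0, 0))) {
  ax_w <- as.numeric(pose$R %*% cylinder$axis)
  c_w <- as.numeric(pose$p + pose$R %*% cylinder$center)
  r <- cylinder$radius
  s <- sign(cylinder$side %||% 1)
  if (s == 0) s <- 1

  # orthonormal cylinder frame (z along axis)
  ref <- if (abs(ax_w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- unitv(cross3(ref, ax_w))
  ey <- cross3(ax_w, ex)
  Rc <- cbind(ex, ey, ax_w, deparse.level = 0)

  P <- as.numeric(t(Rc) %*% (p_start - c_w))
  Q <- as.numeric(t(Rc) %*% (p_end - c_w))
  dP <- sqrt(P[1]^2 + P[2]^2)
  dQ <- sqrt(Q[1]^2 + Q[2]^2)
  straight <- vnorm(p_end - p_start)
  if (dP < 1e-9 || dQ < 1e-9) {
    stop("wrap endpoint lies on the cylinder axis (degenerate configuration)",
         call. = FALSE)
  }
  if (dP < r || dQ < r) {
    stop("wrap endpoint lies inside the cylinder (radius ", signif(r, 4),
         " m)", call. = FALSE)
  }

  # engage test: does the projected straight segment come closer to the
  # axis than the radius?
  d2 <- seg_point_dist2d(P[1:2], Q[1:2])
  if (d2 >= r) {
    return(list(engaged = FALSE, length = straight, t1 = NULL, t2 = NULL,
                arc_angle = 0, arc_points = function(n) NULL))
  }

  phiP <- atan2(P[2], P[1])
  phiQ <- atan2(Q[2], Q[1])
  aP <- acos(min(1, r / dP))
  aQ <- acos(min(1, r / dQ))
  tP <- phiP + s * aP
  tQ <- phiQ - s * aQ
  dphi <- (s * (tQ - tP)) %% (2 * pi)

  l1 <- sqrt(max(dP^2 - r^2, 0))
  l2 <- sqrt(max(dQ^2 - r^2, 0))
  larc <- r * dphi
  D <- l1 + larc + l2
  dz <- Q[3] - P[3]
  len <- sqrt(D^2 + dz^2)

  zT1 <- P[3] + dz * l1 / D
  zT2 <- P[3] + dz * (l1 + larc) / D
  t1 <- c_w + as.numeric(Rc %*% c(r * cos(tP), r * sin(tP), zT1))
  t2 <- c_w + as.numeric(Rc %*% c(r * cos(tQ), r * sin(tQ), zT2))

  arc_points <- function(n) {
    tt <- seq(0, 1, length.out = n)
    ang <- tP + s * dphi * tt
    zz <- zT1 + (zT2 - zT1) * tt
    t(sapply(seq_along(tt), function(i)
      c_w + as.numeric(Rc %*% c(r * cos(ang[i]), r * sin(ang[i]), zz[i]))))
  }
  list(engaged = TRUE, length = len, t1 = t1, t2 = t2,
       arc_angle = dphi, arc_points = arc_points)
}

# Minimum distance from the origin to the 2D segment a-b.
seg_point_dist2d <- function(a, b) {
  ab <- b - a
  den <- sum(ab^2)
  t <- if (den < 1e-30) 0 else min(1, max(0, -sum(a * ab) / den))
  sqrt(sum((a + t * ab)^2))
}
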
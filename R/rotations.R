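# Small rotation / vector algebra kernel shared by kinematics and dynamics.
# All rotations are active, right-handed, applied to column 3-vectors.

rot_x <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
}

rot_y <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
}

rot_z <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

# Intrinsic X-Y-Z Euler sequence: R = Rx(a) Ry(b) Rz(c).
euler_xyz <- function(abc) rot_x(abc[1]) %*% rot_y(abc[2]) %*% rot_z(abc[3])

# Map from XYZ Euler-angle rates to angular velocity (same frame as R is
# expressed in): omega = E(abc) %*% abc_dot.
euler_rate_map <- function(abc) {
  ex <- c(1, 0, 0)
  e2 <- rot_x(abc[1]) %*% c(0, 1, 0)
  e3 <- rot_x(abc[1]) %*% rot_y(abc[2]) %*% c(0, 0, 1)
  cbind(ex, e2, e3, deparse.level = 0)
}

# Time derivative of euler_rate_map along rates abc_dot (analytic).
euler_rate_map_dot <- function(abc, abc_dot) {
  a <- abc[1]; b <- abc[2]
  ad <- abc_dot[1]; bd <- abc_dot[2]
  dRx <- matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3, 3)
  dRy <- matrix(c(-sin(b), 0, -cos(b), 0, 0, 0, cos(b), 0, -sin(b)), 3, 3)
  col2 <- ad * (dRx %*% c(0, 1, 0))
  col3 <- ad * (dRx %*% rot_y(b) %*% c(0, 0, 1)) +
    bd * (rot_x(a) %*% dRy %*% c(0, 0, 1))
  cbind(c(0, 0, 0), col2, col3, deparse.level = 0)
}

# Rotation about an arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, a) {
  k <- skew3(axis)
  diag(3) + sin(a) * k + (1 - cos(a)) * (k %*% k)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 10) {
    stop("cannot normalize a (near-)zero vector", call. = FALSE)
  }
  v / n
}
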
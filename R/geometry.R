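# Internal 3D geometry helpers shared by the backbone builder and featurizer.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) return(NULL)
  a / n
}

# Signed dihedral angle (radians, in (-pi, pi]) of four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# NeRF atom placement: position D with |C-D| = bond, angle(B,C,D) = theta,
# dihedral(A,B,C,D) = phi. Angles in radians.
place_atom <- function(A, B, C, bond, theta, phi) {
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  p <- vcross(n, bc)
  d <- bond * (-cos(theta) * bc + sin(theta) * (cos(phi) * p - sin(phi) * n))
  C + d
}

# Rotation matrix for angle (radians) about unit axis.
rotation_about_axis <- function(axis, angle) {
  u <- vunit(axis)
  c_ <- cos(angle); s <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_),        ux * uy * (1 - c_) - uz * s, ux * uz * (1 - c_) + uy * s,
    uy * ux * (1 - c_) + uz * s, c_ + uy^2 * (1 - c_),        uy * uz * (1 - c_) - ux * s,
    uz * ux * (1 - c_) - uy * s, uz * uy * (1 - c_) + ux * s, c_ + uz^2 * (1 - c_)
  ), nrow = 3, byrow = TRUE)
}

# Random proper rotation (uniform via QR of Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply rigid motion to an n x 3 coordinate matrix.
apply_rigid <- function(xyz, R, t) {
  sweep(xyz %*% t(R), 2, t, "+")
}

# Unit quaternion (w,x,y,z) with nonnegative scalar part from a rotation matrix.
quat_from_rotation <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q <- q / vnorm(q)
  if (q[1] < 0) q <- -q  # double-cover ambiguity fixed by nonnegative scalar
  q
}
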
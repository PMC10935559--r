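# Quaternion and rotation helpers shared by the dynamics, marker and
# kinematics code. Quaternions are length-4 numeric vectors (w, x, y, z),
# unit norm, mapping body coordinates into world coordinates.

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q Numeric length-4 quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix mapping body to world coordinates.
#' @export
#' @keywords internal
quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#' @param R 3x3 rotation matrix.
#' @return quaternion `(w, x, y, z)` with non-negative scalar part.
#' @export
#' @keywords internal
mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q * q))
}

#' Hamilton product of two quaternions
#' @keywords internal
quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion exponential of half a rotation vector
#'
#' `quat_exp(theta)` returns the unit quaternion rotating by the rotation
#' vector `theta` (radians, axis * angle).
#' @keywords internal
quat_exp <- function(theta) {
  a <- sqrt(sum(theta * theta))
  if (a < 1e-14) {
    q <- c(1, theta / 2)
  } else {
    q <- c(cos(a / 2), sin(a / 2) * theta / a)
  }
  q / sqrt(sum(q * q))
}

#' Normalize a quaternion to unit length
#' @export
#' @keywords internal
quat_normalize <- function(q) q / sqrt(sum(q * q))

#' Rotation about a principal axis
#' @param axis 1, 2 or 3 (x, y, z).
#' @param angle radians.
#' @export
#' @keywords internal
rot_axis <- function(axis, angle) {
  c0 <- cos(angle); s0 <- sin(angle)
  R <- diag(3)
  i <- switch(axis, c(2, 3), c(3, 1), c(1, 2))
  R[i[1], i[1]] <- c0; R[i[2], i[2]] <- c0
  R[i[1], i[2]] <- -s0; R[i[2], i[1]] <- s0
  R
}

#' Skew-symmetric cross-product matrix
#' @keywords internal
skew <- function(v) {
  matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < 1e-300) stop("cannot normalize zero vector")
  v / n
}

#' Angle between two rotations
#'
#' Geodesic distance (radians) between rotation matrices `Ra` and `Rb`.
#' @export
#' @keywords internal
rotation_angle_between <- function(Ra, Rb) {
  R <- crossprod(Ra, Rb)
  # atan2 form: accurate near zero where acos((tr-1)/2) loses ~sqrt(eps)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  atan2(sqrt(sum(v * v)), (sum(diag(R)) - 1) / 2)
}
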
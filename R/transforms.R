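#' @title Homogeneous transform utilities
#' @description Internal helpers for 4x4 rigid transforms in the column-vector
#'   convention: `p_world = R %*% p_local + t`, stored as `rbind(cbind(R, t), c(0,0,0,1))`.
#'   All lengths are cm, all angles radians unless a function says otherwise.
#' @name transforms
#' @keywords internal
NULL

#' Build a 4x4 rigid transform from rotation and translation
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (cm).
#' @return 4x4 homogeneous transform.
#' @keywords internal
make_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

#' @keywords internal
transform_rotation <- function(T) T[1:3, 1:3, drop = FALSE]

#' @keywords internal
transform_translation <- function(T) T[1:3, 4]

#' Invert a rigid transform
#' @param T 4x4 rigid transform.
#' @keywords internal
invert_transform <- function(T) {
  R <- T[1:3, 1:3]
  make_transform(t(R), -crossprod(R, T[1:3, 4])[, 1])
}

#' Apply a rigid transform to points
#' @param T 4x4 transform.
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @return n x 3 matrix of transformed points.
#' @keywords internal
apply_transform <- function(T, pts) {
  pts <- rbind3(pts)
  out <- pts %*% t(T[1:3, 1:3])
  out[, 1] <- out[, 1] + T[1, 4]
  out[, 2] <- out[, 2] + T[2, 4]
  out[, 3] <- out[, 3] + T[3, 4]
  out
}

# coerce a 3-vector or n x 3 matrix to n x 3 matrix
#' @keywords internal
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Rotation about an arbitrary unit axis (Rodrigues)
#' @param axis unit 3-vector.
#' @param theta angle in radians, right-hand rule.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' @keywords internal
rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3)

#' @keywords internal
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a),
                              0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3)

#' @keywords internal
rot_z <- function(a) matrix(c(cos(a), sin(a), 0,
                              -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)

#' Check a matrix is a proper rotation
#' @keywords internal
is_rotation_matrix <- function(R, tol = 1e-9) {
  all(abs(crossprod(R) - diag(3)) < tol) && abs(det(R) - 1) < tol
}

#' Normalize a vector, erroring on (near) zero length
#' @keywords internal
unitize <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop(what, " has (near) zero length", call. = FALSE)
  v / n
}

#' Cross product of two 3-vectors
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
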
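#' Intrinsic ZYZ Euler angles to a rotation matrix
#'
#' Orientations are stored as intrinsic ZYZ Euler angles `(rot, tilt, psi)` in
#' degrees, the convention used by Relion particle tables. The matrix form
#' `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)` maps particle-local coordinates into
#' tomogram coordinates.
#'
#' @param rot,tilt,psi Euler angles in degrees. `rot` may also be a numeric
#'   vector of length 3 holding all three angles.
#' @return A 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
euler_to_matrix <- function(rot, tilt = NULL, psi = NULL) {
  if (is.null(tilt)) {
    stopifnot(length(rot) == 3L)
    tilt <- rot[2L]; psi <- rot[3L]; rot <- rot[1L]
  }
  rot_z(rot) %*% rot_y(tilt) %*% rot_z(psi)
}

#' Rotation matrix to intrinsic ZYZ Euler angles
#'
#' Inverse of [euler_to_matrix()]. At the gimbal degeneracy
#' (`tilt` of 0 or 180 degrees) `rot` is set to 0 and the full in-plane spin
#' goes into `psi`.
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  ct <- max(-1, min(1, R[3L, 3L]))
  tilt <- acos(ct)
  if (sin(tilt) > 1e-9) {
    rot <- atan2(R[2L, 3L], R[1L, 3L])
    psi <- atan2(R[3L, 2L], -R[3L, 1L])
  } else if (ct > 0) {       # tilt ~ 0: R ~ Rz(rot + psi)
    rot <- 0
    psi <- atan2(R[2L, 1L], R[1L, 1L])
  } else {                   # tilt ~ 180: R ~ Rz(rot) diag(-1,1,-1) Rz(psi)
    rot <- 0
    psi <- atan2(R[2L, 1L], -R[1L, 1L])
  }
  c(rot = rot, tilt = tilt, psi = psi) * 180 / pi
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
}

as_rotmat <- function(o) {
  if (is.matrix(o)) o else euler_to_matrix(o)
}

#' Apply an orientation to a local-frame vector
#'
#' Maps a particle-local vector into tomogram coordinates, `R(o) %*% v`. This
#' is how transition-list displacements are carried from a seed's frame into
#' the tomogram.
#'
#' @param o An orientation: either Euler angles `c(rot, tilt, psi)` in degrees
#'   or a 3x3 rotation matrix.
#' @param v Numeric vector of length 3.
#' @return The rotated vector (length 3).
#' @export
orient_vector <- function(o, v) {
  stopifnot(length(v) == 3L)
  drop(as_rotmat(o) %*% as.numeric(v))
}

#' Rotation-vector (axis-angle) form of a rotation matrix
#'
#' Returns the rotation vector in degrees: axis times angle. Used to measure
#' angular error between an estimated and a true frame.
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric vector of length 3; its norm is the rotation angle in
#'   degrees.
#' @export
rotation_vector <- function(R) {
  ca <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  ang <- acos(ca)
  if (ang < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  if (sin(ang) > 1e-6) {
    ax <- ax / (2 * sin(ang))
  } else {
    # angle ~ 180 deg: take axis from the dominant diagonal term
    d <- diag(R)
    k <- which.max(d)
    ax <- R[, k] + diag(3)[, k]
    ax <- ax / sqrt(sum(ax^2))
  }
  ax * ang * 180 / pi
}

#' Angular distance between two orientations
#'
#' Axis-angle magnitude of the relative rotation, in degrees.
#'
#' @param a,b Orientations (Euler triples in degrees or 3x3 matrices).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angular_distance <- function(a, b) {
  sqrt(sum(rotation_vector(crossprod(as_rotmat(a), as_rotmat(b)))^2))
}
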
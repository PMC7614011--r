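#' Rigid transform (proper rotation + translation)
#'
#' World-to-world rigid map `w -> R w + t` with `R` a proper rotation
#' (orthogonal, det = +1) and `t` a translation in mm.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- unclass(as.matrix(R))
  t <- as.numeric(t)
  if (!all(dim(R) == c(3L, 3L)) || length(t) != 3L) {
    abort("rigid_transform needs a 3x3 R and length-3 t")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    abort("R is not a proper rotation (R'R = I, det R = +1)",
          class = "fetalrecon_invalid_transform")
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation %.3f mm\n",
              rotation_angle_deg(x$R), sqrt(sum(x$t^2))))
  invisible(x)
}

#' Identity rigid transform
#' @return the identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform()

#' Compose rigid transforms (`a` after `b`)
#' @param a,b `rigid_transform`s.
#' @return the `rigid_transform` `w -> a(b(w))`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, drop(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tr a `rigid_transform`.
#' @return its inverse.
#' @export
rt_invert <- function(tr) {
  rigid_transform(t(tr$R), drop(-t(tr$R) %*% tr$t))
}

#' Apply a rigid transform to points
#' @param tr a `rigid_transform`.
#' @param pts n x 3 matrix (or length-3 vector) of world mm points.
#' @return transformed points, same shape convention (n x 3 matrix).
#' @export
rt_apply <- function(tr, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  out <- pts %*% t(tr$R)
  sweep(out, 2, tr$t, "+")
}

#' Rigid transform as a 4x4 homogeneous matrix
#' @param tr a `rigid_transform`.
#' @return 4x4 matrix.
#' @export
rt_as_affine <- function(tr) {
  m <- diag(4)
  m[1:3, 1:3] <- tr$R
  m[1:3, 4] <- tr$t
  m
}

#' Rigid transform from a 4x4 homogeneous matrix
#' @param m 4x4 matrix with a proper-rotation linear part.
#' @return a `rigid_transform`.
#' @export
rt_from_affine <- function(m) {
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Rotation (optionally with translation) about a centre point
#'
#' Builds the rigid map `w -> R (w - c) + c + t`, i.e. rotation about `center`
#' followed by translation `t`.
#'
#' @param R 3x3 rotation.
#' @param t length-3 translation (mm).
#' @param center length-3 centre of rotation (mm).
#' @return a `rigid_transform`.
#' @export
rt_about_center <- function(R, t = c(0, 0, 0), center = c(0, 0, 0)) {
  center <- as.numeric(center)
  rigid_transform(R, as.numeric(t) + center - drop(as.matrix(R) %*% center))
}

#' Rotation matrix from Euler angles in degrees (Rz Ry Rx convention)
#' @param deg length-3 rotations about x, y, z in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_deg <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotation about a single axis in degrees
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_rotation_deg <- function(axis, deg) {
  v <- c(0, 0, 0)
  v[axis] <- deg
  euler_deg(v)
}

#' Geodesic rotation angle of a rotation matrix, in degrees
#' @param R 3x3 rotation matrix.
#' @return angle in `[0, 180]` degrees.
#' @export
rotation_angle_deg <- function(R) {
  # atan2 of the skew part against the trace is well conditioned at both
  # ends of [0, 180], unlike acos((tr - 1) / 2)
  ctheta <- (sum(diag(R)) - 1) / 2
  s <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  atan2(sqrt(sum(s^2)), ctheta) * 180 / pi
}

#' Pose error between an estimated and a true transform
#'
#' For an estimate `est` of the inverse of a simulated pose `pose` (i.e.
#' `est` should map scanner world back to atlas world), reports the residual
#' rotation angle and the residual displacement of a reference point.
#'
#' @param est estimated `rigid_transform` (scanner -> atlas).
#' @param pose true simulated `rigid_transform` (atlas -> scanner).
#' @param point reference world point (default origin, the trunk centre).
#' @return tibble with `rot_err_deg` and `trans_err_mm`.
#' @export
pose_error <- function(est, pose, point = c(0, 0, 0)) {
  res <- rt_compose(est, pose)          # should be identity
  tibble::tibble(
    rot_err_deg = rotation_angle_deg(res$R),
    trans_err_mm = sqrt(sum((drop(rt_apply(res, point)) - point)^2))
  )
}

#' Draw a uniformly random proper rotation
#' @param n number of rotations.
#' @return a list of 3x3 rotation matrices (uses the current RNG stream).
#' @export
random_rotations <- function(n = 1L) {
  lapply(seq_len(n), function(i) {
    # random unit quaternion
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3)
  })
}

#' Write a rigid transform as a 4x4 text matrix
#' @param tr a `rigid_transform`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transform <- function(tr, path) {
  utils::write.table(rt_as_affine(tr), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a rigid transform from a 4x4 text matrix
#' @param path file written by [write_transform()].
#' @return a `rigid_transform`.
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  rt_from_affine(m)
}
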
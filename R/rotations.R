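#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula. The axis is normalised internally.
#'
#' @param axis numeric length-3 axis of rotation.
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rot_axis_angle <- function(axis, angle) {
  u <- unitize(axis)
  c_ <- cos(angle); s_ <- sin(angle); v <- 1 - c_
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(c_ + ux * ux * v, uy * ux * v + uz * s_, uz * ux * v - uy * s_,
           ux * uy * v - uz * s_, c_ + uy * uy * v, uz * uy * v + ux * s_,
           ux * uz * v + uy * s_, uy * uz * v - ux * s_, c_ + uz * uz * v),
         3, 3)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Cardan (sequential) angle decomposition of a relative rotation
#'
#' Decomposes the rotation of a child frame relative to a parent frame as an
#' ordered sequence of three rotations about the given (mutually
#' perpendicular) axes: `t(parent_R) %*% child_R = R(a1, q1) R(a2, q2) R(a3, q3)`.
#' This is the standard way joint angles are reported in clinical gait
#' analysis, where the axes are the joint's flexion, ab/adduction and
#' internal-external rotation axes.
#'
#' Axes may form a left-handed triad (as happens for one body side of a
#' mirror-symmetric axis convention); this is handled by flipping the third
#' axis and negating its angle.
#'
#' @param parent_R,child_R 3x3 orthonormal rotation matrices (columns = frame
#'   axes expressed in a common frame).
#' @param axes 3x3 matrix whose columns are the ordered unit rotation axes of
#'   the sequence, expressed in the parent frame. Default: the identity, i.e.
#'   an X-Y-Z Cardan sequence.
#' @return numeric length-3 vector of angles in degrees, with attribute
#'   `gimbal` set to `TRUE` when the middle angle lies within 0.5 degrees of
#'   +/-90 degrees (decomposition ill-conditioned).
#' @seealso [compose_cardan()] for the inverse operation.
#' @export
#' @examples
#' R <- rot_axis_angle(c(0, 1, 0), pi / 6)
#' cardan_angles(diag(3), R, axes = cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)))
cardan_angles <- function(parent_R, child_R, axes = diag(3)) {
  if (!is_rotation_matrix(parent_R) || !is_rotation_matrix(child_R)) {
    stop("parent_R and child_R must be orthonormal rotation matrices", call. = FALSE)
  }
  rel <- crossprod(parent_R, child_R)  # t(parent) %*% child
  ang <- .cardan_from_rel(rel, axes)
  ang
}

# Internal: decompose a relative rotation already expressed in the parent
# frame. Shared by cardan_angles() and the vectorised waveform extractor.
.cardan_from_rel <- function(rel, axes) {
  a1 <- unitize(axes[, 1]); a2 <- unitize(axes[, 2]); a3 <- unitize(axes[, 3])
  s3 <- 1
  B <- cbind(a1, a2, a3)
  if (det(B) < 0) {  # left-handed triad: flip third axis, negate its angle
    a3 <- -a3
    s3 <- -1
    B <- cbind(a1, a2, a3)
  }
  M <- crossprod(B, rel %*% B)  # decompose as Rx(q1) Ry(q2) Rz(q3)
  q2 <- asin(clamp(M[1, 3], -1, 1))
  q1 <- atan2(-M[2, 3], M[3, 3])
  q3 <- atan2(-M[1, 2], M[1, 1])
  out <- rad2deg(c(q1, q2, q3 * s3))
  attr(out, "gimbal") <- abs(abs(out[2]) - 90) < 0.5
  out
}

#' Recompose a rotation from Cardan angles
#'
#' Inverse of [cardan_angles()]: builds
#' `R(a1, q1) %*% R(a2, q2) %*% R(a3, q3)` from angles in degrees.
#'
#' @param angles_deg numeric length-3 angles in degrees.
#' @param axes 3x3 matrix of ordered unit axes (columns).
#' @return a 3x3 rotation matrix.
#' @export
compose_cardan <- function(angles_deg, axes = diag(3)) {
  q <- deg2rad(angles_deg)
  rot_axis_angle(axes[, 1], q[1]) %*%
    rot_axis_angle(axes[, 2], q[2]) %*%
    rot_axis_angle(axes[, 3], q[3])
}

#' Clinical Cardan axis conventions per joint and side
#'
#' The ordered rotation axes used for joint-angle decomposition, expressed
#' in the proximal (parent) frame at the neutral pose. Laboratory frame:
#' X = walking direction, Y = left, Z = up (right-handed). Signs are chosen
#' so that positive angles are the clinical positives: flexion +,
#' adduction +, internal rotation +, dorsiflexion +, anterior pelvic
#' tilt +; the left side's transverse/frontal axes are mirrored.
#'
#' @param joint one of `"pelvis"`, `"hip"`, `"knee"`, `"ankle"`.
#' @param side `"left"` or `"right"`.
#' @return 3x3 matrix whose columns are the ordered unit rotation axes.
#' @export
clinical_axes <- function(joint, side = "right") {
  s <- if (side == "right") 1 else -1
  switch(joint,
    pelvis = cbind(c(0, 1, 0),        # anterior tilt +
                   c(s, 0, 0),        # obliquity, mirrored for the left side
                   c(0, 0, s)),       # rotation, mirrored for the left side
    hip    = cbind(c(0, -1, 0),       # flexion +
                   c(s, 0, 0),        # adduction +
                   c(0, 0, s)),       # internal rotation +
    knee   = cbind(c(0, 1, 0),        # flexion +
                   c(s, 0, 0),
                   c(0, 0, s)),
    ankle  = cbind(c(0, -1, 0),       # dorsiflexion +
                   c(s, 0, 0),
                   c(0, 0, s)),
    stop("unknown joint: ", joint)
  )
}
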
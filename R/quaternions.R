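# Unit quaternion helpers. Quaternions are stored row-wise as (w, x, y, z)
# and rotate head-frame vectors into the world frame (v' = q v q*).

#' Rotate vectors by unit quaternions
#'
#' Applies the rotation encoded by each quaternion row to the corresponding
#' vector row. With the package's left-handed, y-up, z-forward convention a
#' quaternion with axis (0, 1, 0) and angle +90 degrees maps the forward
#' vector (0, 0, 1) onto (1, 0, 0).
#'
#' @param q numeric matrix (n x 4) of unit quaternions (w, x, y, z), or a
#'   length-4 vector.
#' @param v numeric matrix (n x 3) of vectors, or a length-3 vector.
#' @return matrix (n x 3) of rotated vectors.
#' @examples
#' quat_rotate(quat_from_axis_angle(c(0, 1, 0), 90), c(0, 0, 1))
#' @export
quat_rotate <- function(q, v) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (nrow(q) == 1 && nrow(v) > 1) q <- q[rep(1, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1 && nrow(q) > 1) v <- v[rep(1, nrow(q)), , drop = FALSE]
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # t = 2 * (q_vec x v); v' = v + w*t + q_vec x t
  tx <- 2 * (y * v[, 3] - z * v[, 2])
  ty <- 2 * (z * v[, 1] - x * v[, 3])
  tz <- 2 * (x * v[, 2] - y * v[, 1])
  cbind(
    v[, 1] + w * tx + y * tz - z * ty,
    v[, 2] + w * ty + z * tx - x * tz,
    v[, 3] + w * tz + x * ty - y * tx
  )
}

#' Quaternion from rotation axis and angle
#'
#' @param axis length-3 axis (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return length-4 quaternion (w, x, y, z).
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * axis)
}

#' Quaternion from yaw and pitch
#'
#' Yaw is rotation about the +y (up) axis, turning the forward (+z) axis
#' toward +x for positive angles; pitch is rotation about the +x axis
#' applied after yaw, turning +z toward -y for positive angles (i.e.
#' positive elevation uses negative pitch).
#'
#' @param yaw_deg,pitch_deg angles in degrees (vectors recycle).
#' @return matrix (n x 4) of unit quaternions.
#' @export
quat_from_yaw_pitch <- function(yaw_deg, pitch_deg = 0) {
  n <- max(length(yaw_deg), length(pitch_deg))
  yaw <- rep_len(yaw_deg, n) * pi / 360
  pit <- rep_len(pitch_deg, n) * pi / 360
  # q = q_yaw(y axis) * q_pitch(x axis)
  cy <- cos(yaw); sy <- sin(yaw); cp <- cos(pit); sp <- sin(pit)
  cbind(cy * cp, cy * sp, sy * cp, -sy * sp)
}

#' Geodesic angle between successive quaternions, in degrees
#'
#' Handles the double cover: q and -q encode the same rotation, so the
#' angle between adjacent rows is computed from |<q_i, q_{i+1}>|.
#'
#' @param q matrix (n x 4) of unit quaternions.
#' @return length n-1 vector of rotation angles in degrees.
#' @export
quat_step_angle <- function(q) {
  if (nrow(q) < 2) return(numeric(0))
  d <- abs(rowSums(q[-nrow(q), , drop = FALSE] * q[-1, , drop = FALSE]))
  2 * acos(clamp1(d)) * 180 / pi
}

#' Quaternion conjugate (inverse rotation for unit quaternions)
#' @param q matrix (n x 4) or length-4 quaternion.
#' @return matrix (n x 4) of conjugated quaternions.
#' @export
quat_conjugate <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}
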
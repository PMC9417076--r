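# Quaternion algebra and the intrinsic z-x-y Euler decomposition used for
# sensor-to-earth orientations. Quaternions are stored as n x 4 matrices in
# (w, x, y, z) order; Euler angles as n x 3 matrices in (z, x, y) order,
# degrees. The decomposition satisfies R(q) = Rz(z) %*% Rx(x) %*% Ry(y)
# (active rotations, column vectors), with the middle (x) angle in
# (-90, 90) degrees.

quat_norms <- function(q) sqrt(rowSums(q^2))

quat_normalize <- function(q) q / quat_norms(q)

#' Hamilton product of quaternions
#'
#' @param q1,q2 n x 4 matrices (w, x, y, z) or length-4 vectors; one may have
#'   a single row, which is recycled.
#' @return n x 4 matrix of products `q1 * q2`.
#' @export
quat_multiply <- function(q1, q2) {
  q1 <- rbind(q1); q2 <- rbind(q2)
  if (nrow(q1) == 1L && nrow(q2) > 1L) q1 <- q1[rep(1L, nrow(q2)), , drop = FALSE]
  if (nrow(q2) == 1L && nrow(q1) > 1L) q2 <- q2[rep(1L, nrow(q1)), , drop = FALSE]
  w1 <- q1[, 1]; x1 <- q1[, 2]; y1 <- q1[, 3]; z1 <- q1[, 4]
  w2 <- q2[, 1]; x2 <- q2[, 2]; y2 <- q2[, 3]; z2 <- q2[, 4]
  cbind(
    w = w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    x = w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    y = w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    z = w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
}

#' Rotation matrix of a single unit quaternion
#'
#' @param q length-4 numeric (w, x, y, z), unit norm.
#' @return 3 x 3 rotation matrix (active rotation of column vectors).
#' @export
quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unwrap an angle sequence in degrees
#'
#' Removes artificial jumps larger than 180 degrees between adjacent samples
#' by adding multiples of 360.
#'
#' @param x numeric vector of angles in degrees.
#' @return unwrapped vector, same length.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  adj <- cumsum(-round(d / 360) * 360)
  c(x[1], x[-1] + adj)
}

#' Convert unit quaternions to intrinsic z-x-y Euler angles
#'
#' Decomposes each orientation quaternion into successive rotations about the
#' z, then x, then y axis (the order used for segment orientations in lower
#' limb analyses), in degrees. Each angle stream is unwrapped so adjacent
#' samples never differ by an artificial +/-360-degree jump.
#'
#' @param quat n x 4 matrix (w, x, y, z) of unit quaternions (norm within
#'   1e-6 of 1).
#' @param unwrap unwrap each output angle stream (default `TRUE`).
#' @return n x 3 matrix with columns `z`, `x`, `y` (degrees). The middle (x)
#'   angle lies in (-90, 90) by construction; samples within 1e-6 degree of
#'   gimbal lock (|x| = 90) trigger a warning but are still returned.
#' @export
quat_to_euler_zxy <- function(quat, unwrap = TRUE) {
  quat <- rbind(quat)
  stopifnot(ncol(quat) == 4L)
  assert_finite(quat, "quaternion series")
  nrm <- quat_norms(quat)
  if (any(abs(nrm - 1) > 1e-6)) {
    stop_named("imuagree_integrity",
               "non-unit quaternion (max |norm-1| = %.3g, tolerance 1e-6)",
               max(abs(nrm - 1)))
  }
  q <- quat / nrm
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # elements of R(q) needed for the zxy decomposition
  r32 <- 2 * (y * z + w * x)                       # sin(ex)
  sx <- pmin(1, pmax(-1, r32))
  ex <- asin(sx)
  ez <- atan2(-2 * (x * y - w * z), 1 - 2 * (x^2 + z^2))
  ey <- atan2(-2 * (x * z - w * y), 1 - 2 * (x^2 + y^2))
  deg <- cbind(z = ez, x = ex, y = ey) * 180 / pi
  if (any(abs(abs(deg[, "x"]) - 90) < 1e-6)) {
    warning("gimbal proximity: |x| within 1e-6 degree of 90; z and y angles ill-conditioned")
  }
  if (unwrap && nrow(deg) > 1L) {
    deg[, "z"] <- unwrap_deg(deg[, "z"])
    deg[, "y"] <- unwrap_deg(deg[, "y"])
  }
  deg
}

#' Convert intrinsic z-x-y Euler angles to unit quaternions
#'
#' Inverse of [quat_to_euler_zxy()]: composes q = qz * qx * qy.
#'
#' @param euler n x 3 matrix (z, x, y) in degrees, or length-3 vector.
#' @return n x 4 matrix of unit quaternions (w, x, y, z).
#' @export
euler_zxy_to_quat <- function(euler) {
  euler <- rbind(euler)
  stopifnot(ncol(euler) == 3L)
  h <- euler * pi / 360  # half-angles in radians
  cz <- cos(h[, 1]); sz <- sin(h[, 1])
  cx <- cos(h[, 2]); sx <- sin(h[, 2])
  cy <- cos(h[, 3]); sy <- sin(h[, 3])
  qz <- cbind(cz, 0, 0, sz)
  qx <- cbind(cx, sx, 0, 0)
  qy <- cbind(cy, 0, sy, 0)
  q <- quat_multiply(quat_multiply(qz, qx), qy)
  colnames(q) <- c("w", "x", "y", "z")
  q
}

# fixed-rotation quaternion from (z, x, y) misalignment angles in degrees
misalignment_quat <- function(zxy_deg) {
  euler_zxy_to_quat(matrix(zxy_deg, nrow = 1))[1, ]
}
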
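# Helix-axis extraction and the quaternion description of a reorientation.
#
# A reorientation of a helix axis from unit vector a to unit vector b is
# carried by the unit quaternion
#   Q = (cos(theta/2), sin(theta/2) u1, sin(theta/2) u2, sin(theta/2) u3)
# where (u1,u2,u3) is the normalized cross product a x b and theta the planar
# angle between a and b. The scalar part is kept non-negative so that
# theta lies in [0, 180] degrees.

vnorm <- function(v) sqrt(sum(v * v))
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Axis of an ordered C-alpha trace
#'
#' Uses the bisector construction: for each interior residue the bisector
#' `b_i = (p_{i-1} - p_i) + (p_{i+1} - p_i)` points radially from the helix
#' surface toward the axis, so the cross products of successive bisectors
#' are parallel to the axis (exactly so for an ideal helix, for which a raw
#' principal-component fit carries a partial-turn phase bias of up to a
#' degree or two). The averaged cross product is normalized and its sign
#' chosen so the axis points from the N-terminal half toward the C-terminal
#' half (positive projection of the difference of half centroids).
#'
#' @param coords numeric n x 3 matrix of C-alpha coordinates ordered N to C,
#'   n >= 5.
#' @return unit length-3 numeric vector.
#' @export
helix_axis <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 5L) stop("helix axis needs at least 5 C-alpha positions, got ", n)
  b <- coords[1:(n - 2), ] + coords[3:n, ] - 2 * coords[2:(n - 1), ]
  acc <- c(0, 0, 0)
  for (i in seq_len(nrow(b) - 1)) {
    cr <- vcross(b[i, ], b[i + 1, ])
    nc <- vnorm(cr)
    if (nc > 1e-12) {
      if (sum(cr * acc) < 0) cr <- -cr
      acc <- acc + cr / nc
    }
  }
  if (vnorm(acc) < 1e-9)
    stop("degenerate point set: no helix axis (collinear or coincident points)")
  ax <- acc / vnorm(acc)
  half <- n %/% 2
  dir <- colMeans(coords[(n - half + 1):n, , drop = FALSE]) -
         colMeans(coords[1:half, , drop = FALSE])
  if (sum(ax * dir) < 0) ax <- -ax
  ax
}

#' Construct / validate a unit quaternion
#'
#' @param q numeric length 4 `(q0, q1, q2, q3)`: scalar then vector part.
#'   Must be unit norm to 1e-6; it is renormalized exactly.
#' @return object of class `unit_quaternion` (numeric length 4).
#' @export
unit_quaternion <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L || anyNA(q)) stop("a quaternion has four numeric components")
  n <- vnorm(q)
  if (abs(n - 1) > 1e-6) stop("not a unit quaternion: norm = ", format(n))
  structure(q / n, class = "unit_quaternion")
}

#' @export
print.unit_quaternion <- function(x, ...) {
  cat(sprintf("<unit_quaternion> (%.6f, %.6f, %.6f, %.6f)  theta = %.3f deg\n",
              x[1], x[2], x[3], x[4], quaternion_angle(x)))
  invisible(x)
}

quat_identity <- function() unit_quaternion(c(1, 0, 0, 0))

#' Hamilton product of two unit quaternions
#'
#' @param p,q [unit_quaternion()]s; the result rotates by `q` first, then
#'   `p`.
#' @return a [unit_quaternion()].
#' @export
quat_multiply <- function(p, q) {
  unit_quaternion(c(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]))
}

#' Conjugate (inverse rotation) of a unit quaternion
#'
#' @param q a [unit_quaternion()].
#' @return a [unit_quaternion()].
#' @export
quat_conjugate <- function(q) unit_quaternion(c(q[1], -q[2], -q[3], -q[4]))

#' Quaternion describing the rotation taking one axis onto another
#'
#' Rotation axis: normalized cross product of the two input vectors; rotation
#' angle: atan2(|a x b|, a . b). Parallel inputs give the identity; exactly
#' antiparallel inputs give a 180-degree rotation about a deterministic
#' perpendicular axis (the lowest-index canonical basis vector not parallel
#' to the input, orthogonalized).
#'
#' @param axis_before,axis_after unit length-3 vectors (N-to-C helix axes).
#' @return a [unit_quaternion()] with non-negative scalar part.
#' @export
rotation_quaternion <- function(axis_before, axis_after) {
  a <- axis_before / vnorm(axis_before)
  b <- axis_after / vnorm(axis_after)
  cr <- vcross(a, b)
  s <- vnorm(cr)
  d <- sum(a * b)
  if (s < 1e-9) {
    if (d > 0) return(quat_identity())
    # antiparallel: pick a reproducible perpendicular axis
    basis <- diag(3)
    k <- which(abs(a) < 0.9)[1]
    u <- basis[, k] - sum(basis[, k] * a) * a
    u <- u / vnorm(u)
    return(unit_quaternion(c(0, u)))
  }
  theta <- atan2(s, d)
  u <- cr / s
  unit_quaternion(c(cos(theta / 2), sin(theta / 2) * u))
}

#' Rotation angle of a unit quaternion, in degrees
#'
#' @param q a [unit_quaternion()] or numeric length 4 of unit norm.
#' @return angle `2 arccos(|q0|)` in degrees, in \[0, 180\].
#' @export
quaternion_angle <- function(q) {
  q <- unit_quaternion(q)
  2 * acos(min(1, abs(q[1]))) * 180 / pi
}

#' Rotation axis of a unit quaternion
#'
#' @param q a [unit_quaternion()].
#' @return unit length-3 vector; `(0, 0, 1)` by convention for the identity.
#' @export
quaternion_axis <- function(q) {
  q <- unit_quaternion(q)
  v <- q[2:4]
  n <- vnorm(v)
  if (n < 1e-12) return(c(0, 0, 1))
  v / n
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Standard conjugation v' = q v q*; norm-preserving.
#'
#' @param q a [unit_quaternion()].
#' @param v numeric length-3 vector.
#' @return rotated length-3 vector.
#' @export
apply_rotation <- function(q, v) {
  q <- unit_quaternion(q)
  w <- q[1]; u <- q[2:4]
  2 * sum(u * v) * u + (w * w - sum(u * u)) * v + 2 * w * vcross(u, v)
}

#' Spherical interpolation from the identity toward a target orientation
#'
#' The rotation angle scales linearly with `fraction` along the geodesic, so
#' half of a 35-degree reorientation is a 17.5-degree rotation about the same
#' axis.
#'
#' @param q_target a [unit_quaternion()].
#' @param fraction number in \[0, 1\].
#' @return a [unit_quaternion()].
#' @export
interpolate_orientation <- function(q_target, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a single number in [0, 1]")
  q_target <- unit_quaternion(q_target)
  theta <- quaternion_angle(q_target) * pi / 180
  if (theta < 1e-12) return(quat_identity())
  u <- quaternion_axis(q_target)
  h <- fraction * theta / 2
  unit_quaternion(c(cos(h), sin(h) * u))
}

#' Quaternion for a rotation of a given angle about a given axis
#'
#' @param angle_deg rotation angle in degrees.
#' @param axis length-3 axis vector (normalized internally).
#' @return a [unit_quaternion()].
#' @export
axis_angle_quaternion <- function(angle_deg, axis) {
  axis <- axis / vnorm(axis)
  h <- angle_deg * pi / 360
  unit_quaternion(c(cos(h), sin(h) * axis))
}
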
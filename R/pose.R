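#' Rigid-body pose
#'
#' The planner's state: a translation in millimetres plus a unit quaternion
#' `(w, x, y, z)` giving the orientation of the bearing.
#'
#' @param t length-3 translation (mm).
#' @param q length-4 quaternion `(w, x, y, z)`; normalised on construction.
#' @return an object of class `pose`.
#' @export
pose <- function(t = c(0, 0, 0), q = c(1, 0, 0, 0)) {
  t <- as.numeric(t)
  q <- as.numeric(q)
  if (length(t) != 3L) stop("t must have length 3")
  if (length(q) != 4L) stop("q must have length 4")
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion")
  structure(list(t = t, q = q / n), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose t = (%.4f, %.4f, %.4f) mm, q = (%.4f, %.4f, %.4f, %.4f)\n",
              x$t[1], x$t[2], x$t[3], x$q[1], x$q[2], x$q[3], x$q[4]))
  invisible(x)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_rotation_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Angular distance between two orientations (radians)
#'
#' @param qa,qb unit quaternions `(w, x, y, z)`.
#' @export
quat_angle <- function(qa, qb) {
  2 * acos(min(1, abs(sum(qa * qb))))
}

#' Compose two poses
#'
#' `pose_compose(a, b)` applies `b` first, then `a` (matrix convention).
#' @param a,b [pose()] objects.
#' @export
pose_compose <- function(a, b) {
  R <- quat_rotation_matrix(a$q)
  pose(t = as.numeric(R %*% b$t) + a$t, q = quat_multiply(a$q, b$q))
}

#' Invert a pose
#'
#' @param p a [pose()].
#' @export
pose_inverse <- function(p) {
  qi <- quat_conjugate(p$q)
  R <- quat_rotation_matrix(qi)
  pose(t = -as.numeric(R %*% p$t), q = qi)
}

#' Interpolate between two poses
#'
#' Linear in translation, spherical-linear (shortest arc) in rotation; this is
#' the interpolation the swept-motion validity check samples along.
#' @param a,b [pose()] objects.
#' @param s interpolation fraction in `[0, 1]`.
#' @export
pose_interp <- function(a, b, s) {
  qa <- a$q
  qb <- b$q
  d <- sum(qa * qb)
  if (d < 0) {
    qb <- -qb
    d <- -d
  }
  if (d > 0.9995) {
    q <- qa + s * (qb - qa)
  } else {
    th <- acos(min(1, d))
    q <- (sin((1 - s) * th) * qa + sin(s * th) * qb) / sin(th)
  }
  pose(t = a$t + s * (b$t - a$t), q = q)
}

#' Apply a pose to points
#'
#' @param p a [pose()].
#' @param pts `n x 3` matrix (or length-3 vector) of points in mm.
#' @return transformed points, same shape as the input.
#' @export
transform_points <- function(p, pts) {
  R <- quat_rotation_matrix(p$q)
  if (is.null(dim(pts))) {
    return(as.numeric(R %*% pts) + p$t)
  }
  sweep(pts %*% t(R), 2, p$t, "+")
}
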
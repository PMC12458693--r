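# quaternion conventions: q = (w, x, y, z), unit norm, proper rotation

#' Identity quaternion
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Quaternion product
#' @param a,b quaternions as length-4 numerics (w, x, y, z)
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix from a unit quaternion
#' @param q quaternion (w, x, y, z)
#' @return 3x3 proper rotation matrix
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Quaternion from an axis-angle rotation
#' @param axis length-3 axis (need not be normalised)
#' @param angle rotation angle in radians
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Deterministic low-discrepancy rotation set (Super-Fibonacci spiral)
#'
#' Quasi-uniform cover of SO(3) used for the orientation quadrature of the
#' grid grand-partition oracle and for well-depth scans of synthetic hosts.
#' The set is deterministic in \code{n}, so refinement checks (doubling
#' \code{n}) are reproducible.
#'
#' @param n number of rotations
#' @return an \code{n x 4} matrix of unit quaternions (w, x, y, z)
#' @export
super_fibonacci_rotations <- function(n) {
  stopifnot(n >= 1)
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041
  i <- seq_len(n) - 1
  s <- i + 0.5
  t <- s / n
  d <- 2 * pi * s
  r <- sqrt(t)
  bigR <- sqrt(1 - t)
  alpha <- d / phi
  beta <- d / psi
  cbind(r * sin(alpha), r * cos(alpha), bigR * sin(beta), bigR * cos(beta))[, c(1, 2, 3, 4), drop = FALSE]
}

#' Uniform random unit quaternions (Shoemake's method)
#' @param n how many
#' @return an \code{n x 4} matrix of quaternions
#' @export
random_rotations <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  a <- sqrt(1 - u1); b <- sqrt(u1)
  cbind(b * cos(2 * pi * u3), a * sin(2 * pi * u2),
        a * cos(2 * pi * u2), b * sin(2 * pi * u3))
}
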
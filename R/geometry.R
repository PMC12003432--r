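#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula. The axis is normalized internally.
#'
#' @param axis numeric length-3 rotation axis.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero length")
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Build an orthonormal frame whose z axis is a given direction
#'
#' Deterministic completion: picks the world axis least aligned with z.
#'
#' @param z numeric length-3 direction (normalized internally).
#' @return 3x3 rotation matrix with columns x, y, z.
#' @keywords internal
frame_from_z <- function(z) {
  z <- z / sqrt(sum(z^2))
  ref <- c(1, 0, 0)
  if (abs(z[1]) > 0.9) ref <- c(0, 1, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  R <- cbind(x, cross3(z, x), z)
  colnames(R) <- NULL
  R
}

#' Cross product of two 3-vectors
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Degrees to radians
#' @param x angle(s) in degrees.
#' @return angle(s) in radians.
#' @export
deg2rad <- function(x) x * pi / 180

#' Radians to degrees
#' @param x angle(s) in radians.
#' @return angle(s) in degrees.
#' @export
rad2deg <- function(x) x * 180 / pi
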
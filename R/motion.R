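#' Prescribed kinematic time history for a functional motion
#'
#' Three motions mirroring the strength-test postures are shipped:
#' \describe{
#'   \item{rotation}{elbow flexed 90 deg, humerus slightly elevated (8 deg in
#'     a 30-deg anterior plane, clearing the thorax as in dynamometry with a
#'     towel roll under the arm); axial rotation ramps 0 -> +45 deg (external),
#'     pauses, then -> -30 deg (internal).}
#'   \item{scapular_elevation}{elevation in a 30-deg anterior (scapular)
#'     plane: 45 -> 90 deg, pause, back to 45 deg; elbow extended.}
#'   \item{horizontal_abd_add}{model supine (gravity along -x), humerus
#'     elevated 90 deg and internally rotated 90 deg; the elevation-plane
#'     coordinate ramps 0 -> -45 deg (horizontal abduction), pauses, then ->
#'     +30 deg past the start (adduction).}
#' }
#' Segments are cosine ramps: velocity is zero at every waypoint and during
#' the pause, and the trajectory is C1-continuous.
#'
#' @param name motion name (see above).
#' @param phase_duration duration of each moving phase (s), default 4.
#' @param pause pause duration at the mid-motion waypoint (s), default 1.
#' @param dt time step (s), default 0.01.
#' @return object of class `kinematic_time_history`: list with `time`,
#'   matrices `q`, `qd`, `qdd` (columns = coordinates, radians), `gravity`
#'   vector, and `name`.
#' @export
generate_motion <- function(name = c("rotation", "scapular_elevation",
                                     "horizontal_abd_add"),
                            phase_duration = 4, pause = 1, dt = 0.01) {
  name <- match.arg(name)
  if (phase_duration <= 0) stop("phase duration must be > 0")
  cfg <- switch(name,
    rotation = list(
      base = c(elv_plane = deg2rad(30), elv_angle = deg2rad(8),
               axial_rotation = 0, elbow_flexion = pi / 2),
      coord = "axial_rotation",
      waypoints = deg2rad(c(0, 45, -30)),
      gravity = c(0, -9.80665, 0)),
    scapular_elevation = list(
      base = c(elv_plane = deg2rad(30), elv_angle = deg2rad(45),
               axial_rotation = 0, elbow_flexion = 0),
      coord = "elv_angle",
      waypoints = deg2rad(c(45, 90, 45)),
      gravity = c(0, -9.80665, 0)),
    horizontal_abd_add = list(
      base = c(elv_plane = 0, elv_angle = pi / 2,
               axial_rotation = -pi / 2, elbow_flexion = 0),
      coord = "elv_plane",
      waypoints = deg2rad(c(0, -45, 30)),
      gravity = c(-9.80665, 0, 0)))

  wp <- cfg$waypoints
  t_end <- 2 * phase_duration + pause
  time <- seq(0, t_end, by = dt)
  nt <- length(time)
  coords <- names(cfg$base)
  q <- matrix(rep(cfg$base, each = nt), nt, length(coords),
              dimnames = list(NULL, coords))
  qd <- matrix(0, nt, length(coords), dimnames = list(NULL, coords))
  qdd <- matrix(0, nt, length(coords), dimnames = list(NULL, coords))

  # cosine ramp from a to b over duration d, evaluated at local time s
  ramp <- function(s, a, b, d) {
    s <- pmin(pmax(s / d, 0), 1)
    list(q = a + (b - a) * (1 - cos(pi * s)) / 2,
         qd = (b - a) * pi * sin(pi * s) / (2 * d),
         qdd = (b - a) * pi^2 * cos(pi * s) / (2 * d^2) *
           as.numeric(s > 0 & s < 1))
  }
  seg1 <- time <= phase_duration
  seg2 <- time >= phase_duration + pause
  r1 <- ramp(time[seg1], wp[1], wp[2], phase_duration)
  r2 <- ramp(time[seg2] - phase_duration - pause, wp[2], wp[3],
             phase_duration)
  ci <- cfg$coord
  q[, ci] <- wp[2]  # pause value fills the middle
  q[seg1, ci] <- r1$q;  qd[seg1, ci] <- r1$qd;  qdd[seg1, ci] <- r1$qdd
  q[seg2, ci] <- r2$q;  qd[seg2, ci] <- r2$qd;  qdd[seg2, ci] <- r2$qdd

  structure(list(name = name, time = time, q = q, qd = qd, qdd = qdd,
                 coord = ci, gravity = cfg$gravity, dt = dt),
            class = "kinematic_time_history")
}

#' Active muscle tension under the rigid-tendon force model
#'
#' F = a * Fmax * fL(lnorm), with a Gaussian active force-length curve
#' fL(l) = exp(-(l - 1)^2 / 0.45). The tendon is rigid: the normalized fiber
#' length is (path length - tendon slack) / lopt, with the slack length fixed
#' so that the fiber sits at optimal length in the neutral posture.
#'
#' @param model a [model_variant()].
#' @param activation numeric vector in [0, 1], one value per muscle (recycled
#'   if scalar).
#' @param q posture.
#' @return named numeric vector of tensions (N).
#' @export
muscle_force <- function(model, activation, q) {
  m <- length(model$muscles)
  activation <- rep_len(activation, m)
  if (any(activation < 0 | activation > 1)) {
    stop("activation must lie in [0, 1]")
  }
  L <- all_path_lengths(model, q)
  L0 <- reference_lengths(model)
  lnorm <- 1 + (L - L0) / vapply(model$muscles, `[[`, numeric(1), "lopt")
  fl <- exp(-(lnorm - 1)^2 / 0.45)
  fmax <- vapply(model$muscles, `[[`, numeric(1), "fmax")
  stats::setNames(activation * fmax * fl, names(model$muscles))
}

# Path lengths at the neutral posture, cached on first use per model variant.
reference_lengths <- function(model) {
  cache <- attr(model, "ref_lengths")
  if (!is.null(cache)) return(cache)
  q0 <- stats::setNames(numeric(n_coords(model)), model$coords)
  all_path_lengths(model, q0)
}

# fL factors for all muscles at a posture (vector), plus tensions at a = 1.
unit_tensions <- function(model, q, lengths = NULL) {
  if (is.null(lengths)) lengths <- all_path_lengths(model, q)
  L0 <- reference_lengths(model)
  lopt <- vapply(model$muscles, `[[`, numeric(1), "lopt")
  fl <- exp(-((lengths - L0) / lopt)^2 / 0.45)
  fmax <- vapply(model$muscles, `[[`, numeric(1), "fmax")
  fmax * fl
}
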
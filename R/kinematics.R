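#' Forward kinematics
#'
#' Composes the fixed joint offsets and intrinsic rotation sequences down the
#' chain. The root (thorax) is welded to ground with its origin at the
#' suprasternal notch: x anterior, y superior, z to the model's right.
#'
#' @param model a [model_variant()].
#' @param q a [posture()] or named numeric vector of angles (rad) covering all
#'   coordinates.
#' @return list with `bodies` (per body: 3x3 rotation `R`, origin `p` in
#'   ground frame), `coord_axes` (3 x n world-frame rotation axes),
#'   `coord_origins` (3 x n world-frame joint centres) and `ancestors`
#'   (per body, indices of coordinates that move it).
#' @export
forward_kinematics <- function(model, q) {
  v <- posture_vector(model, q)
  n <- n_coords(model)
  frames <- vector("list", length(model$bodies))
  names(frames) <- names(model$bodies)
  axes <- matrix(0, 3, n); origins <- matrix(0, 3, n)
  anc <- vector("list", length(model$bodies))
  names(anc) <- names(model$bodies)
  k <- 0L
  for (b in model$bodies) {
    if (is.null(b$parent)) {
      frames[[b$name]] <- list(R = diag(3), p = c(0, 0, 0))
      anc[[b$name]] <- integer(0)
      next
    }
    pf <- frames[[b$parent]]
    if (is.null(pf)) stop("bodies must be in root-first order")
    j <- b$joint
    Rj <- pf$R %*% j$offset_R
    p <- pf$p + pf$R %*% j$offset_p
    own <- integer(0)
    for (i in seq_along(j$axes)) {
      k <- k + 1L
      axes[, k] <- Rj %*% j$axes[[i]]
      origins[, k] <- p
      Rj <- Rj %*% rot_axis_angle(j$axes[[i]], v[k])
      own <- c(own, k)
    }
    frames[[b$name]] <- list(R = Rj, p = as.numeric(p))
    anc[[b$name]] <- c(anc[[b$parent]], own)
  }
  list(bodies = frames, coord_axes = axes, coord_origins = origins,
       ancestors = anc)
}

# Ground-frame position of a point given in a body frame.
point_in_ground <- function(fk, body, point) {
  f <- fk$bodies[[body]]
  if (is.null(f)) stop("unknown body: ", body)
  as.numeric(f$p + f$R %*% point)
}

#' Translational Jacobian of a body-fixed point
#'
#' Column k is the partial derivative of the ground-frame point position with
#' respect to coordinate k (m/rad). Points on the root give a zero matrix.
#'
#' @param model a [model_variant()].
#' @param q posture (or a precomputed [forward_kinematics()] result via `fk`).
#' @param body body carrying the point.
#' @param point 3-vector in the body frame (m).
#' @param fk optional precomputed forward kinematics.
#' @return 3 x n_coords numeric matrix.
#' @export
point_jacobian <- function(model, q, body, point, fk = NULL) {
  if (is.null(fk)) fk <- forward_kinematics(model, q)
  n <- n_coords(model)
  J <- matrix(0, 3, n)
  pw <- point_in_ground(fk, body, point)
  for (k in fk$ancestors[[body]]) {
    J[, k] <- cross3(fk$coord_axes[, k], pw - fk$coord_origins[, k])
  }
  colnames(J) <- model$coords
  J
}

# Angular Jacobian of a body: column k = world rotation axis of coordinate k
# if it is an ancestor of the body, else zero.
body_angular_jacobian <- function(model, fk, body) {
  n <- n_coords(model)
  Jw <- matrix(0, 3, n)
  for (k in fk$ancestors[[body]]) Jw[, k] <- fk$coord_axes[, k]
  Jw
}

#' Generalized gravity forces
#'
#' Returns the generalized force of gravity per coordinate,
#' sum over bodies of t(J_com) %*% (m g). Equals -dV/dq for potential
#' V = -sum m g.com.
#'
#' @param model a [model_variant()].
#' @param q posture.
#' @param g gravity vector in the ground frame (m/s^2), default standard
#'   gravity pointing along -y (thorax upright).
#' @return named numeric vector (N m) per coordinate.
#' @export
gravity_generalized_forces <- function(model, q, g = c(0, -9.80665, 0)) {
  fk <- forward_kinematics(model, q)
  n <- n_coords(model)
  G <- numeric(n)
  for (b in model$bodies) {
    if (b$mass == 0 || is.null(b$parent)) next
    J <- point_jacobian(model, q, b$name, b$com, fk = fk)
    G <- G + as.numeric(t(J) %*% (b$mass * g))
  }
  names(G) <- model$coords
  G
}
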
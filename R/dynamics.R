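#' Joint-space mass matrix
#'
#' Assembled from per-body translational and angular Jacobians:
#' M = sum_b m_b Jv' Jv + Jw' I_w Jw, with inertia rotated to the ground
#' frame. Symmetric positive definite away from singular configurations.
#'
#' @param model a [model_variant()].
#' @param q posture.
#' @return n x n symmetric matrix (kg m^2).
#' @export
mass_matrix <- function(model, q) {
  fk <- forward_kinematics(model, q)
  n <- n_coords(model)
  M <- matrix(0, n, n)
  for (b in model$bodies) {
    if (is.null(b$parent) || !length(fk$ancestors[[b$name]])) next
    Jv <- point_jacobian(model, q, b$name, b$com, fk = fk)
    Jw <- body_angular_jacobian(model, fk, b$name)
    R <- fk$bodies[[b$name]]$R
    Iw <- R %*% b$inertia %*% t(R)
    M <- M + b$mass * crossprod(Jv) + t(Jw) %*% Iw %*% Jw
  }
  M <- (M + t(M)) / 2
  dimnames(M) <- list(model$coords, model$coords)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warning("mass matrix is near-singular at this posture")
  }
  M
}

# Velocity-dependent bias forces b(q, qdot) = C(q, qdot) qdot, from
# finite-difference Christoffel assembly: b = Mdot qdot - dT/dq with
# T = qdot' M qdot / 2. Gravity is not included.
bias_forces <- function(model, q, qd, h = 1e-6) {
  v <- posture_vector(model, q)
  n <- n_coords(model)
  if (all(qd == 0)) return(numeric(n))
  dM <- vector("list", n)
  for (k in seq_len(n)) {
    vp <- v; vp[k] <- vp[k] + h
    vm <- v; vm[k] <- vm[k] - h
    dM[[k]] <- (mass_matrix(model, stats::setNames(vp, model$coords)) -
                  mass_matrix(model, stats::setNames(vm, model$coords))) / (2 * h)
  }
  Mdot <- Reduce(`+`, Map(function(D, qk) D * qk, dM, as.list(qd)))
  dTdq <- vapply(seq_len(n), function(k) 0.5 * sum(qd * (dM[[k]] %*% qd)),
                 numeric(1))
  as.numeric(Mdot %*% qd - dTdq)
}

# Hand-point velocity-product acceleration Jdot qdot, by central difference
# of J(q) along the direction qdot.
hand_jdot_qd <- function(model, q, qd, h = 1e-6) {
  v <- posture_vector(model, q)
  hp <- model$hand_point
  Jp <- point_jacobian(model, stats::setNames(v + h * qd, model$coords),
                       hp$body, hp$location)
  Jm <- point_jacobian(model, stats::setNames(v - h * qd, model$coords),
                       hp$body, hp$location)
  as.numeric(((Jp - Jm) / (2 * h)) %*% qd)
}

# One forward-dynamics acceleration evaluation:
# qddot = M^-1 (tau + G - bias). tau is the total applied generalized force.
forward_accel <- function(model, q, qd, tau, g = c(0, -9.80665, 0)) {
  M <- mass_matrix(model, q)
  G <- gravity_generalized_forces(model, q, g)
  b <- bias_forces(model, q, qd)
  as.numeric(solve(M, tau + G - b))
}
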
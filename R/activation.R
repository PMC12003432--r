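# Box-constrained ridge QP by an exact active-set method:
#   min_a  sum(a^2) + w * || tau - B a ||^2,  a_min <= a <= 1
# B is n_coords x n_muscles. Strictly convex; the free subproblem is solved
# directly ((I + w B'B) a = w B' tau), violated bounds are clamped and
# KKT-inconsistent clamps released one at a time. Deterministic.
solve_activation_qp <- function(B, tau, w = 1e4, a_min = 0, tol = 1e-9,
                                max_iter = 200) {
  m <- ncol(B)
  A <- diag(m) + w * crossprod(B)
  rhs <- w * as.numeric(crossprod(B, tau))
  lo <- rep(a_min, m); hi <- rep(1, m)
  at_lo <- rep(FALSE, m); at_hi <- rep(FALSE, m)
  a <- numeric(m)
  for (iter in seq_len(max_iter)) {
    free <- !(at_lo | at_hi)
    a[at_lo] <- lo[at_lo]; a[at_hi] <- hi[at_hi]
    if (any(free)) {
      b_f <- rhs[free] - A[free, !free, drop = FALSE] %*% a[!free]
      a[free] <- solve(A[free, free, drop = FALSE], b_f)
    }
    viol_lo <- free & (a < lo - tol)
    viol_hi <- free & (a > hi + tol)
    if (any(viol_lo) || any(viol_hi)) {
      at_lo <- at_lo | viol_lo
      at_hi <- at_hi | viol_hi
      next
    }
    # KKT: at lower bound gradient must be >= 0, at upper <= 0
    g <- 2 * a - 2 * w * as.numeric(crossprod(B, tau - B %*% a))
    rel_lo <- which(at_lo & g < -tol)
    rel_hi <- which(at_hi & g > tol)
    if (!length(rel_lo) && !length(rel_hi)) break
    worst <- c(rel_lo, rel_hi)[which.max(abs(g[c(rel_lo, rel_hi)]))]
    at_lo[worst] <- FALSE; at_hi[worst] <- FALSE
  }
  a <- pmin(hi, pmax(lo, a))
  list(activation = a, reserve = as.numeric(tau - B %*% a))
}

# Generalized-force basis of the muscle set at a posture: column j is the
# generalized force produced by muscle j at full activation (moment arms
# times unit tension), n_coords x n_muscles.
muscle_torque_basis <- function(model, q) {
  R <- moment_arm_matrix(model, q)
  f <- unit_tensions(model, q)
  t(R * f)
}

#' Solve muscle activations tracking a kinematic time history
#'
#' A simplified computed-muscle-control stage: the model is integrated
#' forward (semi-implicit Euler at the history time step); at every step the
#' desired acceleration is the trajectory feedforward plus PD feedback on the
#' tracking error, and the activation-squared cost is minimized subject to
#' the equations of motion with bounds 0 <= a <= 1 and heavily penalized
#' per-coordinate reserve actuators. Re-integrating with the returned
#' controls and the same integrator reproduces the realized trajectory
#' exactly; the realized trajectory tracks the input within the reported RMS
#' error.
#'
#' @param model a [model_variant()].
#' @param history a [generate_motion()] result.
#' @param weights reserve penalty weight w in sum(a^2) + w * sum(reserve^2);
#'   default 1e4 (reserve "price" 0.01 N m).
#' @param a_min lower control bound. The reference tracking algorithm this
#'   stage emulates constrains muscle excitations to a small positive floor
#'   rather than zero; the default 0.02 mirrors that, so every muscle
#'   transmits a small force and the induced-acceleration stage sees the
#'   full muscle set. Set to 0 for a strict minimum-effort solution.
#' @param kp,kv PD tracking gains (1/s^2, 1/s).
#' @return object of class `activation_solution`: time, activation matrix
#'   (steps x muscles), reserve matrix (steps x coords), realized `q`, `qd`,
#'   applied accelerations `qdd`, per-coordinate tracking RMS error (rad).
#' @export
solve_activations <- function(model, history, weights = 1e4, a_min = 0.02,
                              kp = 400, kv = 40) {
  time <- history$time
  nt <- length(time)
  coords <- model$coords
  qdes <- history$q[, coords, drop = FALSE]
  qddes <- history$qd[, coords, drop = FALSE]
  qdddes <- history$qdd[, coords, drop = FALSE]
  dt <- history$dt
  g <- history$gravity
  m <- length(model$muscles)
  n <- length(coords)

  act <- matrix(0, nt, m, dimnames = list(NULL, names(model$muscles)))
  res <- matrix(0, nt, n, dimnames = list(NULL, coords))
  qs <- matrix(0, nt, n, dimnames = list(NULL, coords))
  qds <- matrix(0, nt, n, dimnames = list(NULL, coords))
  qdds <- matrix(0, nt, n, dimnames = list(NULL, coords))

  q <- qdes[1, ]; qd <- qddes[1, ]
  for (i in seq_len(nt)) {
    qs[i, ] <- q; qds[i, ] <- qd
    qn <- stats::setNames(q, coords)
    M <- mass_matrix(model, qn)
    G <- gravity_generalized_forces(model, qn, g)
    b <- bias_forces(model, qn, qd)
    qdd_cmd <- qdddes[i, ] + kp * (qdes[i, ] - q) + kv * (qddes[i, ] - qd)
    tau_req <- as.numeric(M %*% qdd_cmd) + b - G
    B <- muscle_torque_basis(model, qn)
    sol <- solve_activation_qp(B, tau_req, w = weights, a_min = a_min)
    act[i, ] <- sol$activation
    res[i, ] <- sol$reserve
    tau <- as.numeric(B %*% sol$activation) + sol$reserve
    qdd <- as.numeric(solve(M, tau + G - b))
    qdds[i, ] <- qdd
    if (i < nt) {
      qd <- qd + qdd * dt
      q <- q + qd * dt
    }
  }
  err <- qs - qdes
  rms <- sqrt(colMeans(err^2))
  structure(list(time = time, activation = act, reserve = res,
                 q = qs, qd = qds, qdd = qdds,
                 tracking_rms_rad = rms, history = history,
                 weights = weights, a_min = a_min, kp = kp, kv = kv),
            class = "activation_solution")
}

#' Open-loop re-simulation with a solved control history
#'
#' Integrates the forward dynamics driven only by the stored activations and
#' reserve moments (no feedback), with the same integrator and step as the
#' solver, and returns the trajectory. Used for round-trip verification.
#'
#' @param model a [model_variant()].
#' @param solution an [solve_activations()] result.
#' @return matrix of re-simulated angles (steps x coords).
#' @export
resimulate_activations <- function(model, solution) {
  coords <- model$coords
  time <- solution$time
  nt <- length(time)
  dt <- solution$history$dt
  g <- solution$history$gravity
  qs <- matrix(0, nt, length(coords), dimnames = list(NULL, coords))
  q <- solution$q[1, ]; qd <- solution$qd[1, ]
  for (i in seq_len(nt)) {
    qs[i, ] <- q
    qn <- stats::setNames(q, coords)
    M <- mass_matrix(model, qn)
    G <- gravity_generalized_forces(model, qn, g)
    b <- bias_forces(model, qn, qd)
    B <- muscle_torque_basis(model, qn)
    tau <- as.numeric(B %*% solution$activation[i, ]) + solution$reserve[i, ]
    qdd <- as.numeric(solve(M, tau + G - b))
    if (i < nt) {
      qd <- qd + qdd * dt
      q <- q + qd * dt
    }
  }
  qs
}
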
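#' Hand acceleration induced by a single force source
#'
#' Applies one source's generalized force alone through the equations of
#' motion and reports the resulting hand-point acceleration along the thorax
#' axes (x anterior, y superior, z right). Sources: a muscle name (its
#' generalized force at the given activation), "gravity" (M^-1 G),
#' "reserve" (M^-1 tau_reserve), or "velocity" (M^-1 (-C qd) plus the
#' Jdot qd term).
#'
#' @param model a [model_variant()].
#' @param state list with `q` (named angles), `qd` (velocities), `gravity`
#'   vector.
#' @param activations named activation vector (used for muscle sources).
#' @param source source name.
#' @param reserve optional reserve moment vector (for source = "reserve").
#' @return 3-vector, m/s^2, thorax frame.
#' @export
induced_hand_acceleration <- function(model, state, activations, source,
                                      reserve = NULL) {
  qn <- state$q
  M <- mass_matrix(model, qn)
  hp <- model$hand_point
  J <- point_jacobian(model, qn, hp$body, hp$location)
  if (source == "gravity") {
    tau <- gravity_generalized_forces(model, qn, state$gravity)
  } else if (source == "velocity") {
    b <- bias_forces(model, qn, state$qd)
    qdd <- as.numeric(solve(M, -b))
    return(as.numeric(J %*% qdd) + hand_jdot_qd(model, qn, state$qd))
  } else if (source == "reserve") {
    if (is.null(reserve)) stop("reserve source requires reserve moments")
    tau <- reserve
  } else {
    if (!source %in% names(model$muscles)) stop("unknown source: ", source)
    B <- muscle_torque_basis(model, qn)
    tau <- as.numeric(B[, source]) * activations[[source]]
  }
  as.numeric(J %*% solve(M, tau))
}

#' Per-source decomposition of hand acceleration over a motion
#'
#' For every step of an activation solution, computes each muscle's induced
#' hand acceleration (setting all other muscle forces to zero), plus the
#' gravity, velocity and reserve sources, along the thorax axes. The
#' superposition residual against the full forward-dynamics hand
#' acceleration is reported per step.
#'
#' @param model a [model_variant()].
#' @param solution an [solve_activations()] result (its stored realized
#'   states are used, so grids are aligned by construction).
#' @param stride evaluate every `stride`-th step (default 1 = all steps).
#' @return object of class `induced_acceleration_result`: `time`, `sources`
#'   (character), `contrib` (3-d array time x source x axis), `total`
#'   (time x axis), `residual` (max abs per step), `axes` = c("x","y","z").
#' @export
decompose_motion <- function(model, solution, stride = 1L) {
  coords <- model$coords
  idx <- seq(1, length(solution$time), by = stride)
  nt <- length(idx)
  musc <- names(model$muscles)
  sources <- c(musc, "gravity", "velocity", "reserve")
  hp <- model$hand_point
  g <- solution$history$gravity
  contrib <- array(0, dim = c(nt, length(sources), 3),
                   dimnames = list(NULL, sources, c("x", "y", "z")))
  total <- matrix(0, nt, 3, dimnames = list(NULL, c("x", "y", "z")))
  residual <- numeric(nt)
  for (t in seq_len(nt)) {
    i <- idx[t]
    qn <- stats::setNames(solution$q[i, ], coords)
    qd <- solution$qd[i, ]
    M <- mass_matrix(model, qn)
    Mi <- solve(M)
    J <- point_jacobian(model, qn, hp$body, hp$location)
    B <- muscle_torque_basis(model, qn)
    a <- solution$activation[i, ]
    # muscles
    taus <- B * rep(a, each = length(coords))
    acc_m <- J %*% (Mi %*% taus)                       # 3 x m
    contrib[t, musc, ] <- t(acc_m)
    # gravity
    G <- gravity_generalized_forces(model, qn, g)
    contrib[t, "gravity", ] <- as.numeric(J %*% (Mi %*% G))
    # velocity (Coriolis/centrifugal plus Jdot qd)
    b <- bias_forces(model, qn, qd)
    contrib[t, "velocity", ] <- as.numeric(J %*% (Mi %*% (-b))) +
      hand_jdot_qd(model, qn, qd)
    # reserves
    contrib[t, "reserve", ] <- as.numeric(J %*% (Mi %*% solution$reserve[i, ]))
    # total from full forward dynamics
    tau_full <- as.numeric(B %*% a) + solution$reserve[i, ]
    qdd <- as.numeric(Mi %*% (tau_full + G - b))
    total[t, ] <- as.numeric(J %*% qdd) + hand_jdot_qd(model, qn, qd)
    residual[t] <- max(abs(apply(contrib[t, , , drop = FALSE], 3, sum) -
                             total[t, ]))
  }
  structure(list(time = solution$time[idx], sources = sources,
                 contrib = contrib, total = total, residual = residual,
                 axes = c(x = "anterior-posterior", y = "superior-inferior",
                          z = "lateral-medial")),
            class = "induced_acceleration_result")
}

#' Rank muscle contributors to hand acceleration along one axis
#'
#' Muscles are scored by the time-integrated absolute contribution along the
#' axis (default) or by peak magnitude; gravity/velocity/reserve sources are
#' excluded from the ranking. Ties break deterministically by name.
#'
#' @param result a [decompose_motion()] result.
#' @param axis "x" (anterior-posterior), "y" (superior-inferior) or "z"
#'   (lateral-medial).
#' @param k number of top contributors, default 5.
#' @param metric "integrated" or "peak".
#' @return character vector of muscle names, largest first.
#' @export
rank_contributors <- function(result, axis = c("x", "y", "z"), k = 5,
                              metric = c("integrated", "peak")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  if (!length(result$time)) stop("empty induced-acceleration result")
  keep <- setdiff(result$sources, c("gravity", "velocity", "reserve"))
  x <- result$contrib[, keep, axis, drop = FALSE]
  score <- if (metric == "integrated") {
    apply(abs(x), 2, sum) * mean(diff(result$time))
  } else {
    apply(abs(x), 2, max)
  }
  ord <- order(-score, names(score))
  head(names(score)[ord], k)
}
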
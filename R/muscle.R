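#' Muscle path
#'
#' An ordered sequence of attachment/via points on bodies, with optional
#' single-cylinder wrapping (used for the subpectoral implant), plus the
#' force-generating parameters consumed by the activation solver.
#'
#' @param name muscle path identifier.
#' @param compartment anatomical compartment label (e.g. "pectoralis major,
#'   sternal").
#' @param points list of path points, each `list(body=, location=)`; at least
#'   two, with origin and insertion on different bodies.
#' @param wrap name of a wrap cylinder in the model applying to this path, or
#'   `NULL`.
#' @param wrap_segment index of the path segment (between points i and i+1)
#'   routed over the cylinder; defaults to 1.
#' @param fmax maximum isometric force (N).
#' @param lopt optimal fiber length (m).
#' @return an object of class `muscle_path`.
#' @export
muscle_path <- function(name, compartment, points, wrap = NULL,
                        wrap_segment = 1L, fmax = 100, lopt = 0.1) {
  if (length(points) < 2) stop("muscle path needs at least 2 points")
  points <- lapply(points, function(p) list(body = p$body,
                                            location = as.numeric(p$location)))
  if (points[[1]]$body == points[[length(points)]]$body) {
    stop("origin and insertion must be on different bodies")
  }
  structure(list(name = name, compartment = compartment, points = points,
                 wrap = wrap, wrap_segment = as.integer(wrap_segment),
                 fmax = as.numeric(fmax), lopt = as.numeric(lopt)),
            class = "muscle_path")
}

validate_muscle <- function(muscle, model) {
  for (p in muscle$points) {
    if (!p$body %in% names(model$bodies)) {
      stop("muscle '", muscle$name, "' references unknown body: ", p$body)
    }
  }
  if (!is.null(muscle$wrap) && !muscle$wrap %in% names(model$wraps)) {
    stop("muscle '", muscle$name, "' references unknown wrap: ", muscle$wrap)
  }
  invisible(TRUE)
}

# Ground-frame coordinates of all path points of one muscle (3 x k matrix).
muscle_points_ground <- function(model, muscle, fk) {
  vapply(muscle$points, function(p) point_in_ground(fk, p$body, p$location),
         numeric(3))
}

#' Musculotendon path length at a posture
#'
#' Sum of straight-segment lengths; if the muscle has a wrap cylinder, the
#' designated segment is routed with [wrap_over_cylinder()] (both bracketing
#' points are expressed in the cylinder body frame before the geometry is
#' solved).
#'
#' @param model a [model_variant()].
#' @param muscle a [muscle_path()] or the name of one in the model.
#' @param q posture.
#' @param fk optional precomputed forward kinematics.
#' @param details if TRUE, also return the wrap result.
#' @return path length (m), or a list when `details = TRUE`.
#' @export
path_length <- function(model, muscle, q, fk = NULL, details = FALSE) {
  if (is.character(muscle)) muscle <- model$muscles[[muscle]]
  if (is.null(muscle)) stop("unknown muscle")
  if (is.null(fk)) fk <- forward_kinematics(model, q)
  P <- muscle_points_ground(model, muscle, fk)
  k <- ncol(P)
  seg <- sqrt(colSums((P[, -1, drop = FALSE] - P[, -k, drop = FALSE])^2))
  wrap_res <- NULL
  if (!is.null(muscle$wrap)) {
    cyl <- model$wraps[[muscle$wrap]]
    i <- muscle$wrap_segment
    bf <- fk$bodies[[cyl$body]]
    Rcyl <- frame_from_z(cyl$axis)       # body -> cylinder local
    to_cyl <- function(pg) as.numeric(t(Rcyl) %*% (t(bf$R) %*% (pg - bf$p) - cyl$center))
    p1 <- to_cyl(P[, i]); p2 <- to_cyl(P[, i + 1])
    side <- as.numeric(t(Rcyl) %*% cyl$wrap_side)
    wrap_res <- wrap_over_cylinder(p1, p2, cyl$radius, side = side)
    seg[i] <- wrap_res$length
  }
  L <- sum(seg)
  if (details) list(length = L, wrap = wrap_res) else L
}

# Lengths of all muscles of a model at one posture (named vector); shares one
# forward-kinematics evaluation.
all_path_lengths <- function(model, q, fk = NULL) {
  if (is.null(fk)) fk <- forward_kinematics(model, q)
  vapply(model$muscles, function(m) path_length(model, m, q, fk = fk),
         numeric(1))
}

#' Muscle moment arm by tendon excursion
#'
#' r = -dL/dq by central finite difference (default step 1e-5 rad). A
#' positive moment arm produces a positive generalized force about the
#' coordinate for positive muscle tension. If the step straddles a wrap
#' on/off transition the step is refined and a warning is raised.
#'
#' @param model a [model_variant()].
#' @param muscle a [muscle_path()] or name.
#' @param coordinate coordinate name.
#' @param q posture.
#' @param step finite-difference step (rad).
#' @return signed moment arm (m).
#' @export
moment_arm <- function(model, muscle, coordinate, q, step = 1e-5) {
  if (is.character(muscle)) muscle <- model$muscles[[muscle]]
  if (!coordinate %in% model$coords) stop("unknown coordinate: ", coordinate)
  v <- posture_vector(model, q)
  names(v) <- model$coords
  eval_at <- function(h) {
    vp <- v; vp[coordinate] <- vp[coordinate] + h
    vm <- v; vm[coordinate] <- vm[coordinate] - h
    dp <- path_length(model, muscle, vp, details = TRUE)
    dm <- path_length(model, muscle, vm, details = TRUE)
    wp <- if (is.null(dp$wrap)) NA else dp$wrap$wrapped
    wm <- if (is.null(dm$wrap)) NA else dm$wrap$wrapped
    list(val = -(dp$length - dm$length) / (2 * h), consistent = identical(wp, wm))
  }
  r <- eval_at(step)
  if (!r$consistent) {
    warning("moment arm step straddles a wrap transition near coordinate '",
            coordinate, "'; refining step")
    r <- eval_at(step / 100)
  }
  r$val
}

# Moment-arm matrix (muscles x coordinates) at one posture, sharing FK
# evaluations across muscles: 2*n perturbed postures regardless of muscle
# count. Used by the activation and induced-acceleration pipelines.
moment_arm_matrix <- function(model, q, step = 1e-5) {
  v <- posture_vector(model, q)
  n <- n_coords(model)
  m <- length(model$muscles)
  R <- matrix(0, m, n, dimnames = list(names(model$muscles), model$coords))
  for (k in seq_len(n)) {
    vp <- v; vp[k] <- vp[k] + step
    vm <- v; vm[k] <- vm[k] - step
    Lp <- all_path_lengths(model, stats::setNames(vp, model$coords))
    Lm <- all_path_lengths(model, stats::setNames(vm, model$coords))
    R[, k] <- -(Lp - Lm) / (2 * step)
  }
  R
}

#' Summed pectoralis major moment arm
#'
#' Arithmetic sum of the clavicular, sternal and ribs compartment moment arms
#' about a coordinate (the combination rule is configurable: "sum" or
#' "mean").
#'
#' @param model a [model_variant()].
#' @param coordinate coordinate name.
#' @param q posture.
#' @param combine "sum" (default) or "mean".
#' @return combined moment arm (m).
#' @export
summed_pectoralis_moment_arm <- function(model, coordinate, q,
                                         combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  comps <- c("pec_major_clavicular", "pec_major_sternal", "pec_major_ribs")
  missing <- setdiff(comps, names(model$muscles))
  if (length(missing)) {
    stop("missing pectoralis major compartment(s): ",
         paste(missing, collapse = ", "))
  }
  vals <- vapply(comps, function(m) moment_arm(model, m, coordinate, q),
                 numeric(1))
  if (combine == "sum") sum(vals) else mean(vals)
}

#' Moment-arm sweep over a coordinate range
#'
#' Mirrors the moment-arm figures: sweeps one coordinate (degrees at this
#' boundary) and reports moment arms in cm.
#'
#' @param model a [model_variant()].
#' @param muscle muscle name, or "pectoralis_major" for the summed compartments.
#' @param coordinate swept coordinate.
#' @param from,to,by sweep grid in degrees.
#' @param q0 base posture (defaults to all zeros).
#' @return data.frame with `angle_deg` and `moment_arm_cm`.
#' @export
moment_arm_sweep <- function(model, muscle, coordinate, from = 0, to = 120,
                             by = 5, q0 = NULL) {
  if (is.null(q0)) q0 <- stats::setNames(numeric(n_coords(model)), model$coords)
  angles <- seq(from, to, by = by)
  ma <- vapply(angles, function(a) {
    q <- posture_vector(model, q0)
    names(q) <- model$coords
    q[coordinate] <- deg2rad(a)
    if (identical(muscle, "pectoralis_major")) {
      summed_pectoralis_moment_arm(model, coordinate, q)
    } else {
      moment_arm(model, muscle, coordinate, q)
    }
  }, numeric(1))
  data.frame(angle_deg = angles, moment_arm_cm = 100 * ma)
}
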
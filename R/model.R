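#' Joint specification
#'
#' A joint is a fixed offset transform from the parent frame followed by an
#' ordered intrinsic rotation sequence. Each rotation axis is expressed in the
#' frame produced by the preceding rotations of the same joint (so a
#' three-axis shoulder behaves like an intrinsic Euler sequence).
#'
#' @param name joint identifier.
#' @param axes list of unit 3-vectors, one per coordinate.
#' @param coords character vector of coordinate names (same length as `axes`).
#' @param range 2 x k matrix of [min; max] values in radians per coordinate.
#' @param offset_p fixed translation parent -> joint origin, in the parent
#'   frame (m).
#' @param offset_R fixed rotation parent -> joint zero pose (3x3).
#' @return an object of class `joint_spec`.
#' @export
joint_spec <- function(name, axes, coords, range, offset_p = c(0, 0, 0),
                       offset_R = diag(3)) {
  stopifnot(is.list(axes), length(axes) == length(coords))
  axes <- lapply(axes, function(a) {
    n <- sqrt(sum(a^2))
    if (abs(n - 1) > 1e-9) stop("joint axis must be unit length")
    as.numeric(a)
  })
  range <- matrix(as.numeric(range), nrow = 2,
                  ncol = if (length(range)) length(range) / 2 else 0)
  if (ncol(range) != length(coords)) stop("range must have one column per coordinate")
  if (length(coords) && any(range[1, ] >= range[2, ])) {
    stop("joint range must have min < max")
  }
  structure(list(name = name, axes = axes, coords = coords, range = range,
                 offset_p = as.numeric(offset_p), offset_R = offset_R),
            class = "joint_spec")
}

#' Rigid body segment
#'
#' @param name body identifier.
#' @param mass segment mass (kg), non-negative.
#' @param com centre of mass in the body frame (m).
#' @param inertia symmetric positive-semidefinite 3x3 inertia tensor about the
#'   body COM, in the body frame (kg m^2).
#' @param parent name of the parent body, or `NULL` for the root.
#' @param joint a [joint_spec()] connecting this body to its parent (`NULL`
#'   for the root, which is welded to ground).
#' @return an object of class `rigid_body`.
#' @export
rigid_body <- function(name, mass, com, inertia, parent = NULL, joint = NULL) {
  inertia <- matrix(as.numeric(inertia), 3, 3)
  if (mass < 0) stop("mass must be non-negative")
  if (max(abs(inertia - t(inertia))) > 1e-12) stop("inertia must be symmetric")
  ev <- eigen(inertia, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) stop("inertia must be positive semidefinite")
  d <- diag(inertia)
  if (d[1] + d[2] < d[3] - 1e-12 || d[2] + d[3] < d[1] - 1e-12 ||
      d[3] + d[1] < d[2] - 1e-12) {
    stop("inertia violates triangle inequality")
  }
  structure(list(name = name, mass = as.numeric(mass), com = as.numeric(com),
                 inertia = inertia, parent = parent, joint = joint),
            class = "rigid_body")
}

#' Assemble an articulated model for one surgical variant
#'
#' @param variant one of "lumpectomy", "implant", "flap".
#' @param bodies list of [rigid_body()] in root-first topological order.
#' @param muscles named list of [muscle_path()] objects.
#' @param wraps named list of [wrap_cylinder()] objects (empty except for the
#'   implant variant, which carries exactly one).
#' @param hand_point list(body=, location=) giving the hand reference point
#'   used for induced-acceleration reporting.
#' @return an object of class `model_variant`.
#' @export
model_variant <- function(variant, bodies, muscles = list(), wraps = list(),
                          hand_point = NULL) {
  variant <- match.arg(variant, c("lumpectomy", "implant", "flap"))
  names(bodies) <- vapply(bodies, `[[`, "", "name")
  roots <- vapply(bodies, function(b) is.null(b$parent), TRUE)
  if (sum(roots) != 1) stop("model must have exactly one root body")
  for (b in bodies) {
    if (!is.null(b$parent) && !b$parent %in% names(bodies)) {
      stop("unknown parent body: ", b$parent)
    }
  }
  if (variant == "implant" && length(wraps) != 1) {
    stop("implant variant must contain exactly one wrap cylinder")
  }
  if (variant != "implant" && length(wraps) != 0) {
    stop(variant, " variant must contain no wrap cylinders")
  }
  coords <- character(0); coord_body <- character(0); coord_axis <- integer(0)
  range <- NULL
  for (b in bodies) {
    if (is.null(b$joint)) next
    j <- b$joint
    coords <- c(coords, j$coords)
    coord_body <- c(coord_body, rep(b$name, length(j$coords)))
    coord_axis <- c(coord_axis, seq_along(j$coords))
    range <- cbind(range, j$range)
  }
  if (anyDuplicated(coords)) stop("duplicate coordinate names")
  if (!is.null(range)) colnames(range) <- coords
  if (length(muscles)) names(muscles) <- vapply(muscles, `[[`, "", "name")
  m <- structure(list(variant = variant, bodies = bodies, muscles = muscles,
                      wraps = wraps, hand_point = hand_point,
                      coords = coords, coord_body = coord_body,
                      coord_axis = coord_axis, range = range),
                 class = "model_variant")
  for (mus in muscles) validate_muscle(mus, m)
  m
}

#' Number of generalized coordinates of a model
#' @param model a [model_variant()].
#' @return integer coordinate count.
#' @export
n_coords <- function(model) length(model$coords)

#' Posture: named joint angles (and optional velocities)
#'
#' @param angles named numeric vector, radians; names are model coordinates.
#' @param velocities optional named numeric vector, rad/s.
#' @return an object of class `posture`.
#' @export
posture <- function(angles, velocities = NULL) {
  if (is.null(names(angles))) stop("posture angles must be named")
  if (!is.null(velocities) && is.null(names(velocities))) {
    stop("posture velocities must be named")
  }
  structure(list(angles = angles, velocities = velocities), class = "posture")
}

# Resolve a posture (or named vector) against the model's coordinate list,
# returning angles in model coordinate order. Unknown or missing coordinates
# are configuration errors.
posture_vector <- function(model, q) {
  if (inherits(q, "posture")) q <- q$angles
  if (is.null(names(q))) {
    if (length(q) != n_coords(model)) stop("unnamed posture of wrong length")
    names(q) <- model$coords
  }
  unknown <- setdiff(names(q), model$coords)
  if (length(unknown)) stop("unknown coordinate(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(model$coords, names(q))
  if (length(missing)) stop("posture does not cover coordinate(s): ",
                            paste(missing, collapse = ", "))
  as.numeric(q[model$coords])
}

#' Check whether a posture lies within the model's joint ranges
#' @param model a [model_variant()].
#' @param q a [posture()] or named numeric vector (rad).
#' @return logical vector per coordinate (TRUE = within range).
#' @export
posture_in_range <- function(model, q) {
  v <- posture_vector(model, q)
  r <- model$range
  ok <- v >= r[1, ] & v <= r[2, ]
  names(ok) <- model$coords
  ok
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("<model_variant '%s'>: %d bodies, %d coordinates, %d muscle paths, %d wrap objects\n",
              x$variant, length(x$bodies), n_coords(x), length(x$muscles),
              length(x$wraps)))
  invisible(x)
}
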
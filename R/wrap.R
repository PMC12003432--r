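#' Cylindrical wrapping surface
#'
#' Represents a subpectoral implant as a single-cylinder obstacle for muscle
#' paths. The cylinder is fixed on a body; `wrap_side` is a direction in the
#' body frame (perpendicular to the axis) selecting the tangent family: the
#' wrapped arc bulges towards that side.
#'
#' @param body body carrying the cylinder.
#' @param center cylinder centre in the body frame (m).
#' @param axis cylinder axis direction, body frame (normalized internally).
#' @param radius cylinder radius (m), > 0.
#' @param half_length half of the cylinder length (m), > 0.
#' @param wrap_side 3-vector, body frame: side on which the path wraps.
#' @param applies_to character vector of muscle path names affected.
#' @return an object of class `wrap_cylinder`.
#' @export
wrap_cylinder <- function(body, center, axis, radius, half_length,
                          wrap_side = c(1, 0, 0), applies_to = character(0)) {
  if (radius <= 0) stop("wrap cylinder radius must be > 0")
  if (half_length <= 0) stop("wrap cylinder half_length must be > 0")
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  structure(list(body = body, center = as.numeric(center), axis = axis,
                 radius = radius, half_length = half_length,
                 wrap_side = as.numeric(wrap_side),
                 applies_to = as.character(applies_to)),
            class = "wrap_cylinder")
}

#' Shortest muscle-path routing over a cylinder
#'
#' Both endpoints are expressed in the cylinder frame (z along the axis,
#' origin at the cylinder centre). If the straight segment clears the surface
#' the path is straight; otherwise a tangent--geodesic--tangent path is
#' returned: the geometry is solved on the plane normal to the axis and the
#' axial travel is distributed along the planar arc length (helical geodesic).
#'
#' @param p1,p2 3-vectors, cylinder frame (m).
#' @param radius cylinder radius (m).
#' @param side 2-vector (or 3-vector; z ignored): direction in the cylinder
#'   x-y plane towards which the wrap must bulge. `NULL` picks the shorter of
#'   the two tangent families.
#' @return list with `wrapped` flag, `contacts` (3 x 2 matrix of tangent
#'   points, cylinder frame; NULL when straight) and `length` (m).
#' @export
wrap_over_cylinder <- function(p1, p2, radius, side = NULL) {
  if (inherits(radius, "wrap_cylinder")) {
    side <- radius$wrap_side
    radius <- radius$radius
  }
  q1 <- p1[1:2]; q2 <- p2[1:2]
  r1 <- sqrt(sum(q1^2)); r2 <- sqrt(sum(q2^2))
  if (r1 < radius - 1e-12) stop("point p1 lies strictly inside the wrap cylinder")
  if (r2 < radius - 1e-12) stop("point p2 lies strictly inside the wrap cylinder")
  straight <- sqrt(sum((p2 - p1)^2))
  # distance from the axis to the planar segment q1-q2
  d <- q2 - q1
  dd <- sum(d^2)
  t0 <- if (dd < 1e-30) 0 else max(0, min(1, -sum(q1 * d) / dd))
  closest <- q1 + t0 * d
  if (sqrt(sum(closest^2)) >= radius - 1e-12) {
    return(list(wrapped = FALSE, contacts = NULL, length = straight))
  }
  a1 <- atan2(q1[2], q1[1]); a2 <- atan2(q2[2], q2[1])
  b1 <- acos(min(1, radius / r1)); b2 <- acos(min(1, radius / r2))
  cand <- lapply(c(1, -1), function(s) {
    t1 <- a1 + s * b1
    t2 <- a2 - s * b2
    arc <- (s * (t2 - t1)) %% (2 * pi)
    T1 <- radius * c(cos(t1), sin(t1))
    T2 <- radius * c(cos(t2), sin(t2))
    l1 <- sqrt(sum((T1 - q1)^2))
    la <- radius * arc
    l2 <- sqrt(sum((q2 - T2)^2))
    mid <- radius * c(cos(t1 + s * arc / 2), sin(t1 + s * arc / 2))
    list(s = s, T1 = T1, T2 = T2, l1 = l1, la = la, l2 = l2, mid = mid,
         lp = l1 + la + l2)
  })
  sel <- if (is.null(side)) {
    if (cand[[1]]$lp <= cand[[2]]$lp) cand[[1]] else cand[[2]]
  } else {
    sd <- side[1:2]
    if (sum(cand[[1]]$mid * sd) >= sum(cand[[2]]$mid * sd)) cand[[1]] else cand[[2]]
  }
  # distribute axial travel in proportion to planar path length
  z1 <- p1[3]; z2 <- p2[3]
  lp <- sel$lp
  zT1 <- z1 + (z2 - z1) * sel$l1 / lp
  zT2 <- z1 + (z2 - z1) * (sel$l1 + sel$la) / lp
  len <- sqrt(sel$l1^2 + (zT1 - z1)^2) +
    sqrt(sel$la^2 + (zT2 - zT1)^2) +
    sqrt(sel$l2^2 + (z2 - zT2)^2)
  contacts <- cbind(c(sel$T1, zT1), c(sel$T2, zT2))
  list(wrapped = TRUE, contacts = contacts, length = max(len, straight))
}

#' Wrap cylinder matching a breast implant specification
#'
#' The manufacturer's projection (anterior protrusion, cm) is taken as the
#' cylinder length and the radius solves volume = pi r^2 length. The
#' alternative reading (projection as a radial stand-off, i.e. the cylinder
#' radius itself) is available via `projection_is = "standoff"`.
#'
#' @param volume implant volume in cc (default 405).
#' @param projection implant projection in cm (default 4.4).
#' @param projection_is "length" (default): projection is the cylinder
#'   length; "standoff": projection is the cylinder radius, with length from
#'   the volume.
#' @param body,center,axis,wrap_side,applies_to placement of the cylinder in
#'   the model (see [wrap_cylinder()]); defaults position it beneath the
#'   sternal and ribs compartments of pectoralis major on the thorax.
#' @return a [wrap_cylinder()].
#' @export
implant_wrap_from_spec <- function(volume = 405, projection = 4.4,
                                   projection_is = c("length", "standoff"),
                                   body = "thorax",
                                   center = c(0.020, -0.095, 0.105),
                                   axis = c(0, 1, 0),
                                   wrap_side = c(1, 0, 0),
                                   applies_to = c("pec_major_sternal",
                                                  "pec_major_ribs")) {
  projection_is <- match.arg(projection_is)
  if (volume <= 0) stop("implant volume must be > 0")
  if (projection <= 0) stop("implant projection must be > 0")
  vol_m3 <- volume * 1e-6          # cc -> m^3
  proj_m <- projection * 1e-2      # cm -> m
  if (projection_is == "length") {
    radius <- sqrt(vol_m3 / (pi * proj_m))
    half_length <- proj_m / 2
  } else {
    radius <- proj_m
    half_length <- vol_m3 / (pi * radius^2) / 2
  }
  wrap_cylinder(body = body, center = center, axis = axis, radius = radius,
                half_length = half_length, wrap_side = wrap_side,
                applies_to = applies_to)
}
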
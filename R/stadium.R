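#' Planar section properties of a stadium
#'
#' A stadium is a rectangle of half-width `a` (flat direction) and half-height
#' `r`, capped by two semicircles of radius `r`. Returns closed-form area,
#' centroid and second moments about the centroid. `u` is the flat direction,
#' `v` the cap-radius direction.
#'
#' @param rect_half_width half-length `a` of the flat section (m), >= 0.
#' @param end_radius cap radius `r` (m), >= 0; not both zero.
#' @return list with `area` (m^2), `centroid` (c(0,0)), `I_u` = int v^2 dA,
#'   `I_v` = int u^2 dA (m^4).
#' @export
stadium_section_properties <- function(rect_half_width, end_radius) {
  a <- rect_half_width; r <- end_radius
  if (a < 0 || r < 0) stop("stadium dimensions must be non-negative")
  if (a == 0 && r == 0) stop("stadium dimensions cannot both be zero")
  area <- 4 * a * r + pi * r^2
  I_u <- (4 / 3) * a * r^3 + pi * r^4 / 4
  I_v <- (4 / 3) * a^3 * r + pi * r^4 / 4 + pi * a^2 * r^2 + (8 / 3) * a * r^3
  list(area = area, centroid = c(0, 0), I_u = I_u, I_v = I_v)
}

#' Torso stadium solid
#'
#' @param rect_half_width half-length of the flat section of the cross-section
#'   (lateral direction, m).
#' @param end_radius cap radius (anterior-posterior half-depth, m).
#' @param height prism height (superior-inferior, m).
#' @param base_density homogeneous density (g/mL).
#' @param center solid centre in the torso frame (origin at the suprasternal
#'   notch; x anterior, y superior, z right), m.
#' @return an object of class `stadium_solid`.
#' @export
stadium_solid <- function(rect_half_width, end_radius, height,
                          base_density = 1.0,
                          center = c(-0.0926, -0.166, 0)) {
  if (height <= 0) stop("height must be > 0")
  if (base_density <= 0) stop("density must be > 0")
  structure(list(rect_half_width = rect_half_width, end_radius = end_radius,
                 height = height, base_density = base_density,
                 center = as.numeric(center)),
            class = "stadium_solid")
}

#' Torso mass properties container
#'
#' @param mass kg.
#' @param com 3-vector (m), torso frame (origin suprasternal notch).
#' @param inertia 3x3 tensor (kg m^2) about the COM, torso frame.
#' @return object of class `torso_mass_properties`.
#' @export
torso_mass_properties <- function(mass, com, inertia) {
  inertia <- matrix(as.numeric(inertia), 3, 3)
  inertia <- (inertia + t(inertia)) / 2  # enforce symmetry
  structure(list(mass = as.numeric(mass), com = as.numeric(com),
                 inertia = inertia),
            class = "torso_mass_properties")
}

#' Analytic mass properties of a stadium solid
#'
#' The cross-section lies in the x-z plane (z = flat direction, x = cap
#' direction) and the prism is extruded along y.
#'
#' @param solid a [stadium_solid()].
#' @return a [torso_mass_properties()].
#' @export
solid_mass_properties <- function(solid) {
  sec <- stadium_section_properties(solid$rect_half_width, solid$end_radius)
  rho <- solid$base_density * 1000  # g/mL -> kg/m^3
  h <- solid$height
  m <- rho * sec$area * h
  # u = z, v = x, extrusion = y
  Izz <- rho * h * sec$I_u + m * h^2 / 12
  Ixx <- rho * h * sec$I_v + m * h^2 / 12
  Iyy <- rho * h * (sec$I_u + sec$I_v)
  torso_mass_properties(m, solid$center, diag(c(Ixx, Iyy, Izz)))
}

#' Tissue density scheme for a surgical variant
#'
#' Densities: native breast tissue 0.95 g/mL, silicone implant 1.05 g/mL,
#' DIEP flap tissue 0.84 g/mL. The modified region is a 405-cc cylinder on
#' the anterior chest wall, unilateral.
#'
#' @param variant "lumpectomy", "implant" or "flap".
#' @param region_volume modified region volume (cc), default 405.
#' @param region_center region centre, torso frame (m).
#' @param region_radius region cylinder radius (m); its height follows from
#'   the volume. Axis along y.
#' @return object of class `tissue_scheme`.
#' @export
tissue_scheme <- function(variant, region_volume = 405,
                          region_center = c(0.0, -0.10, 0.09),
                          region_radius = 0.045) {
  variant <- match.arg(variant, c("lumpectomy", "implant", "flap"))
  density <- c(lumpectomy = 0.95, implant = 1.05, flap = 0.84)[[variant]]
  if (density <= 0 || region_volume <= 0) stop("density and volume must be > 0")
  structure(list(variant = variant, breast_density = density,
                 region_volume = region_volume,
                 region_center = as.numeric(region_center),
                 region_radius = region_radius, unilateral = TRUE),
            class = "tissue_scheme")
}

# TRUE when a point lies inside the stadium solid envelope.
point_in_stadium <- function(solid, p) {
  rel <- p - solid$center
  if (abs(rel[2]) > solid$height / 2) return(FALSE)
  a <- solid$rect_half_width; r <- solid$end_radius
  u <- rel[3]; v <- rel[1]
  if (abs(u) <= a) return(abs(v) <= r)
  du <- abs(u) - a
  du^2 + v^2 <= r^2
}

#' Superpose a tissue-density scheme on base torso properties
#'
#' Adds a homogeneous cylindrical region of excess mass
#' dm = (scheme density - native density) * volume at the region centre;
#' COM and inertia are updated exactly (parallel-axis), including the region's
#' own small-cylinder inertia. A scheme at native density returns the base
#' unchanged.
#'
#' @param base a [torso_mass_properties()].
#' @param scheme a [tissue_scheme()].
#' @param native_density native breast tissue density (g/mL), default 0.95.
#' @param solid optional [stadium_solid()]; when given, the region is checked
#'   to lie inside the solid envelope.
#' @return a [torso_mass_properties()].
#' @export
apply_tissue_scheme <- function(base, scheme, native_density = 0.95,
                                solid = NULL) {
  drho <- scheme$breast_density - native_density      # g/mL
  V <- scheme$region_volume * 1e-6                    # cc -> m^3
  Rr <- scheme$region_radius
  hr <- V / (pi * Rr^2)
  cr <- scheme$region_center
  if (!is.null(solid)) {
    for (p in list(cr, cr + c(0, hr / 2, 0), cr - c(0, hr / 2, 0))) {
      if (!point_in_stadium(solid, p)) {
        stop("tissue region lies outside the torso solid envelope")
      }
    }
  }
  dm <- drho * 1000 * V                               # kg
  if (dm == 0) return(base)
  # region self-inertia about its own COM (cylinder, axis y)
  I_ax <- dm * Rr^2 / 2
  I_tr <- dm * (3 * Rr^2 + hr^2) / 12
  I_reg <- diag(c(I_tr, I_ax, I_tr))
  m0 <- base$mass; c0 <- base$com
  m1 <- m0 + dm
  c1 <- (m0 * c0 + dm * cr) / m1
  shift_inertia <- function(I, m, d) {
    # parallel-axis transfer of inertia I (about a COM) by offset d
    I + m * (sum(d^2) * diag(3) - outer(d, d))
  }
  I1 <- shift_inertia(base$inertia, m0, c0 - c1) +
    shift_inertia(I_reg, dm, cr - c1)
  torso_mass_properties(m1, c1, I1)
}

#' Torso mass properties for a surgical variant
#'
#' Builds the anthropometric stadium solid, computes its analytic mass
#' properties, and superposes the variant's tissue-density scheme.
#'
#' @param variant "lumpectomy", "implant" or "flap".
#' @param anthro anthropometry list (see [default_anthropometry()]).
#' @return a [torso_mass_properties()].
#' @export
build_variant_torso <- function(variant, anthro = default_anthropometry()) {
  variant <- match.arg(variant, c("lumpectomy", "implant", "flap"))
  t <- anthro$torso
  solid <- stadium_solid(t$rect_half_width, t$end_radius, t$height,
                         base_density = t$base_density,
                         center = t$center)
  base <- solid_mass_properties(solid)
  scheme <- tissue_scheme(variant, region_volume = t$region_volume,
                          region_center = t$region_center,
                          region_radius = t$region_radius)
  apply_tissue_scheme(base, scheme, native_density = t$native_breast_density,
                      solid = solid)
}
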
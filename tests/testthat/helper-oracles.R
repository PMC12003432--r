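# Independent numerical oracles shared across test files.

# quadrature oracle for the stadium section: reduce to 1-D integrals over v
# (cap direction); half-width at height v is a + sqrt(r^2 - v^2)
section_oracle <- function(a, r) {
  half_w <- function(v) a + sqrt(pmax(r^2 - v^2, 0))
  area <- stats::integrate(function(v) 2 * half_w(v), -r, r,
                           rel.tol = 1e-10)$value
  I_u <- stats::integrate(function(v) 2 * v^2 * half_w(v), -r, r,
                          rel.tol = 1e-10)$value
  I_v <- stats::integrate(function(v) (2 / 3) * half_w(v)^3, -r, r,
                          rel.tol = 1e-10)$value
  list(area = area, I_u = I_u, I_v = I_v)
}

# voxel-integration oracle for the extruded solid (midpoint cells)
voxel_oracle <- function(solid, n = 150) {
  a <- solid$rect_half_width; r <- solid$end_radius; h <- solid$height
  rho <- solid$base_density * 1000
  centers <- function(lo, hi, n) lo + (seq_len(n) - 0.5) * (hi - lo) / n
  gx <- centers(-r, r, n)
  gy <- centers(-h / 2, h / 2, n)
  gz <- centers(-(a + r), a + r, n)
  dv <- (2 * r / n) * (h / n) * (2 * (a + r) / n)
  pts <- expand.grid(x = gx, y = gy, z = gz)
  u <- pts$z; v <- pts$x
  inside <- (abs(u) <= a & abs(v) <= r) | ((abs(u) - a)^2 + v^2 <= r^2 & abs(u) > a)
  p <- pts[inside, ]
  m <- rho * dv * nrow(p)
  com <- rho * dv * colSums(p) / m
  x <- p$x; y <- p$y; z <- p$z
  I <- rho * dv * matrix(c(sum(y^2 + z^2), -sum(x * y), -sum(x * z),
                           -sum(x * y), sum(x^2 + z^2), -sum(y * z),
                           -sum(x * z), -sum(y * z), sum(x^2 + y^2)), 3, 3)
  list(mass = m, inertia = I)
}


# kinetic-energy oracle: T(qd) from finite-difference body velocities,
# M_ij recovered by polarization of the quadratic form
mass_matrix_energy_oracle <- function(model, q) {
  v <- q[model$coords]
  h <- 1e-5
  kinetic <- function(qd) {
    fkp <- forward_kinematics(model, stats::setNames(v + h * qd, model$coords))
    fkm <- forward_kinematics(model, stats::setNames(v - h * qd, model$coords))
    T <- 0
    for (b in model$bodies) {
      if (is.null(b$parent)) next
      vp <- (reconarm:::point_in_ground(fkp, b$name, b$com) -
               reconarm:::point_in_ground(fkm, b$name, b$com)) / (2 * h)
      Rdot <- (fkp$bodies[[b$name]]$R - fkm$bodies[[b$name]]$R) / (2 * h)
      W <- Rdot %*% t(forward_kinematics(model, q)$bodies[[b$name]]$R)
      om <- c(W[3, 2], W[1, 3], W[2, 1])
      R0 <- forward_kinematics(model, q)$bodies[[b$name]]$R
      Iw <- R0 %*% b$inertia %*% t(R0)
      T <- T + 0.5 * b$mass * sum(vp^2) + 0.5 * sum(om * (Iw %*% om))
    }
    T
  }
  n <- n_coords(model)
  basis <- function(i) { e <- numeric(n); e[i] <- 1; e }
  Ti <- vapply(seq_len(n), function(i) kinetic(basis(i)), numeric(1))
  M <- diag(2 * Ti, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      # polarization of the quadratic form: Mij = T(ei+ej) - T(ei) - T(ej)
      M[i, j] <- M[j, i] <- kinetic(basis(i) + basis(j)) - Ti[i] - Ti[j]
    }
  }
  M
}

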
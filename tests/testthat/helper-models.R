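# Shared fixtures: toy chains and lazily-built variant models.

# single hinge pendulum: point mass m at distance l along -y of the child
toy_pendulum <- function(m = 2, l = 0.5, I = 0) {
  bodies <- list(
    rigid_body("base", 0, c(0, 0, 0), diag(3) * 0),
    rigid_body("rod", m, c(0, -l, 0), diag(rep(I, 3)), parent = "base",
               joint = joint_spec("hinge", list(c(0, 0, 1)), "theta",
                                  rbind(-pi, pi)))
  )
  model_variant("lumpectomy", bodies,
                hand_point = list(body = "rod", location = c(0, -l, 0)))
}

# two-link planar arm in the x-y plane, hinges about z
toy_two_link <- function(m1 = 1.5, m2 = 1.0, l1 = 0.4, l2 = 0.3) {
  bodies <- list(
    rigid_body("base", 0, c(0, 0, 0), diag(3) * 0),
    rigid_body("link1", m1, c(0, -l1 / 2, 0), diag(c(1, 0.2, 1)) * m1 * l1^2 / 12,
               parent = "base",
               joint = joint_spec("j1", list(c(0, 0, 1)), "q1", rbind(-pi, pi))),
    rigid_body("link2", m2, c(0, -l2 / 2, 0), diag(c(1, 0.2, 1)) * m2 * l2^2 / 12,
               parent = "link1",
               joint = joint_spec("j2", list(c(0, 0, 1)), "q2", rbind(-pi, pi),
                                  offset_p = c(0, -l1, 0)))
  )
  model_variant("lumpectomy", bodies,
                hand_point = list(body = "link2", location = c(0, -l2, 0)))
}

# random serial chain with n moving bodies, 1-3 rotational axes per joint
random_chain <- function(n_links = 3, seed = 1) {
  set.seed(seed)
  bodies <- list(rigid_body("base", 0, c(0, 0, 0), diag(3) * 0))
  parent <- "base"
  for (i in seq_len(n_links)) {
    k <- sample(1:3, 1)
    axes <- lapply(seq_len(k), function(j) {
      a <- stats::rnorm(3); a / sqrt(sum(a^2))
    })
    coords <- paste0("q", i, "_", seq_len(k))
    d <- diag(abs(stats::rnorm(3, 0.05, 0.02)))
    # enforce the triangle inequality by mixing towards a sphere-like tensor
    d <- d + diag(3) * max(diag(d))
    b <- rigid_body(paste0("link", i), stats::runif(1, 0.5, 3),
                    stats::rnorm(3, 0, 0.1), d, parent = parent,
                    joint = joint_spec(paste0("j", i), axes, coords,
                                       rbind(rep(-pi, k), rep(pi, k)),
                                       offset_p = stats::rnorm(3, 0, 0.2)))
    bodies <- c(bodies, list(b))
    parent <- paste0("link", i)
  }
  model_variant("lumpectomy", bodies,
                hand_point = list(body = parent, location = c(0, -0.1, 0)))
}

random_posture <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- model$range
  stats::setNames(stats::runif(n_coords(model), r[1, ], r[2, ]), model$coords)
}

# variant models are expensive enough to share across tests
.model_cache <- new.env(parent = emptyenv())
fixture_model <- function(variant) {
  if (is.null(.model_cache[[variant]])) {
    .model_cache[[variant]] <- build_variant_model(variant)
  }
  .model_cache[[variant]]
}

zero_posture <- function(model) {
  stats::setNames(numeric(n_coords(model)), model$coords)
}

# independent forward-kinematics oracle using 4x4 homogeneous matrices
fk_oracle_point <- function(model, q, body, point) {
  v <- q[model$coords]
  hom <- function(R, p) rbind(cbind(R, p), c(0, 0, 0, 1))
  Ts <- list()
  k <- 0
  for (b in model$bodies) {
    if (is.null(b$parent)) { Ts[[b$name]] <- diag(4); next }
    j <- b$joint
    Tj <- Ts[[b$parent]] %*% hom(j$offset_R, j$offset_p)
    for (i in seq_along(j$axes)) {
      k <- k + 1
      Tj <- Tj %*% hom(rot_axis_angle_oracle(j$axes[[i]], v[k]), c(0, 0, 0))
    }
    Ts[[b$name]] <- Tj
  }
  as.numeric((Ts[[body]] %*% c(point, 1))[1:3])
}

# quaternion-based rotation, independent of the package's Rodrigues formula
rot_axis_angle_oracle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  w <- cos(angle / 2); xyz <- sin(angle / 2) * a
  x <- xyz[1]; y <- xyz[2]; z <- xyz[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
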
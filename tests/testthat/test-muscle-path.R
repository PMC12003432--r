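# independent planar tangent-arc closed form used as the wrap oracle
planar_wrap_oracle <- function(q1, q2, r) {
  d1 <- sqrt(sum(q1^2)); d2 <- sqrt(sum(q2^2))
  t1 <- sqrt(d1^2 - r^2); t2 <- sqrt(d2^2 - r^2)
  # angle at the center between the two points, minus the tangent half-angles
  ang <- acos(sum(q1 * q2) / (d1 * d2)) - acos(r / d1) - acos(r / d2)
  t1 + t2 + r * ang
}

test_that("wrap_over_cylinder handles clear, grazing and wrapped segments", {
  r <- 0.05
  # segment passing 2*radius from the axis: straight
  res <- wrap_over_cylinder(c(-0.3, -2 * r, 0), c(0.3, -2 * r, 0), r)
  expect_false(res$wrapped)
  expect_equal(res$length, 0.6)

  # symmetric chord cutting the circle: planar closed form
  q1 <- c(-2 * r, -r / 2, 0); q2 <- c(2 * r, -r / 2, 0)
  res <- wrap_over_cylinder(q1, q2, r, side = c(0, -1))
  expect_true(res$wrapped)
  expect_equal(res$length, planar_wrap_oracle(q1[1:2], q2[1:2], r),
               tolerance = 1e-12)
  expect_gte(res$length, sqrt(sum((q2 - q1)^2)))

  # dense polyline shortest-path search around the disc agrees; straight
  # segments that would cut through the disc are not admissible
  th <- seq(0, 2 * pi, length.out = 4001)[-1]
  A <- rbind(r * cos(th), r * sin(th))
  seg_clear <- function(q) {
    d <- A - q
    tt <- pmin(pmax(-(q[1] * d[1, ] + q[2] * d[2, ]) / colSums(d^2), 0), 1)
    cx <- q[1] + tt * d[1, ]; cy <- q[2] + tt * d[2, ]
    sqrt(cx^2 + cy^2) >= r - 1e-9
  }
  ok1 <- seg_clear(q1[1:2]); ok2 <- seg_clear(q2[1:2])
  d1 <- sqrt(colSums((A - q1[1:2])^2))
  d2 <- sqrt(colSums((A - q2[1:2])^2))
  best <- Inf
  lower <- which(sin(th) < 0)  # wrap passes under the disc
  for (i in lower[ok1[lower]]) {
    j <- lower[ok2[lower]]
    arcv <- r * pmin(abs(th[i] - th[j]), 2 * pi - abs(th[i] - th[j]))
    best <- min(best, d1[i] + arcv + d2[j])
  }
  expect_equal(res$length, best, tolerance = 1e-4)

  # radius -> 0 degenerates to the straight segment
  res0 <- wrap_over_cylinder(c(-0.3, -1e-12, 0.1), c(0.3, 1e-12, -0.1), 1e-9)
  expect_equal(res0$length, sqrt(0.6^2 + 0.2^2), tolerance = 1e-6)

  # endpoints strictly inside are geometry errors naming the point
  expect_error(wrap_over_cylinder(c(0.01, 0, 0), c(0.3, 0, 0), r), "p1")
  expect_error(wrap_over_cylinder(c(0.3, 0, 0), c(0.01, 0, 0), r), "p2")
})

test_that("wrapped length is never shorter than the straight segment", {
  set.seed(42)
  r <- 0.04
  n_wrapped <- 0
  for (i in 1:500) {
    p1 <- c(stats::runif(1, -0.4, -0.1), stats::runif(2, -0.2, 0.2))
    p2 <- c(stats::runif(1, 0.1, 0.4), stats::runif(2, -0.2, 0.2))
    if (sqrt(sum(p1[1:2]^2)) <= r || sqrt(sum(p2[1:2]^2)) <= r) next
    res <- wrap_over_cylinder(p1, p2, r, side = c(0, -1))
    expect_gte(res$length, sqrt(sum((p2 - p1)^2)) - 1e-12)
    n_wrapped <- n_wrapped + res$wrapped
  }
  expect_gt(n_wrapped, 50)  # the sample genuinely exercises the wrapped branch
})

test_that("path_length reduces to segment sums and respects the wrap", {
  m <- fixture_model("lumpectomy")
  q0 <- zero_posture(m)
  # two-point muscle: Euclidean distance between ground-frame locations
  fk <- forward_kinematics(m, q0)
  br <- m$muscles$brachioradialis
  p1 <- reconarm:::point_in_ground(fk, br$points[[1]]$body, br$points[[1]]$location)
  p2 <- reconarm:::point_in_ground(fk, br$points[[2]]$body, br$points[[2]]$location)
  expect_equal(path_length(m, "brachioradialis", q0), sqrt(sum((p2 - p1)^2)),
               tolerance = 1e-14)

  # adding a collinear via point leaves the length unchanged (at zero posture
  # the thorax frame coincides with ground, so the midpoint can sit on it)
  mid <- (p1 + p2) / 2
  tri <- muscle_path("test", "test",
                     list(list(body = br$points[[1]]$body, location = br$points[[1]]$location),
                          list(body = "thorax", location = mid),
                          list(body = br$points[[2]]$body, location = br$points[[2]]$location)))
  expect_equal(path_length(m, tri, q0), path_length(m, "brachioradialis", q0),
               tolerance = 1e-12)

  # implant wrap engaged: length >= the same path with the wrap removed
  # postures sampled over the functional range (extreme joint limits can put
  # the humeral insertion inside the implant cylinder, which is an error)
  impl <- fixture_model("implant")
  for (s in 1:50) {
    set.seed(300 + s)
    q <- stats::setNames(deg2rad(c(stats::runif(1, -30, 60),
                                   stats::runif(1, 0, 120),
                                   stats::runif(1, -60, 60),
                                   stats::runif(1, 0, 130))), impl$coords)
    for (mu in c("pec_major_sternal", "pec_major_ribs")) {
      with_wrap <- path_length(impl, mu, q)
      bare <- impl$muscles[[mu]]
      bare$wrap <- NULL
      expect_gte(with_wrap, path_length(impl, bare, q) - 1e-12)
    }
  }
})

test_that("tendon-excursion moment arms match geometric oracles", {
  # planar pulley: two-point path crossing a hinge at perpendicular distance d
  l1 <- 0.4
  arm <- toy_two_link(l1 = l1, l2 = 0.3)
  # geometric oracle r = -z . ((B - c) x u) for the straight segment A->B
  for (s in 1:10) {
    q <- random_posture(arm, seed = 400 + s)
    mus <- muscle_path("m", "toy",
                       list(list(body = "link1", location = c(0.05, -0.25, 0)),
                            list(body = "link2", location = c(0.04, -0.08, 0))))
    got <- moment_arm(arm, mus, "q2", q)
    fk <- forward_kinematics(arm, q)
    A <- reconarm:::point_in_ground(fk, "link1", c(0.05, -0.25, 0))
    B <- reconarm:::point_in_ground(fk, "link2", c(0.04, -0.08, 0))
    cen <- fk$bodies$link2$p
    u <- (B - A) / sqrt(sum((B - A)^2))
    zax <- fk$coord_axes[, 2]
    oracle <- -sum(zax * reconarm:::cross3(B - cen, u))
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("summed pectoralis moment arm behaves per construction", {
  lump <- fixture_model("lumpectomy")
  flap <- fixture_model("flap")
  impl <- fixture_model("implant")
  q90 <- zero_posture(lump); q90["elv_angle"] <- pi / 2

  # lumpectomy and flap moment arms are identical (paths unchanged)
  for (a in c(0, 30, 60, 90, 120)) {
    q <- zero_posture(lump); q["elv_angle"] <- deg2rad(a)
    expect_equal(summed_pectoralis_moment_arm(lump, "elv_angle", q),
                 summed_pectoralis_moment_arm(flap, "elv_angle", q),
                 tolerance = 1e-12)
  }
  # implant magnitude strictly smaller at 90 deg elevation
  expect_lt(abs(summed_pectoralis_moment_arm(impl, "elv_angle", q90)),
            abs(summed_pectoralis_moment_arm(lump, "elv_angle", q90)))
  # sum equals the sum of the compartments
  comps <- c("pec_major_clavicular", "pec_major_sternal", "pec_major_ribs")
  expect_equal(summed_pectoralis_moment_arm(lump, "elv_angle", q90),
               sum(vapply(comps, function(mu) moment_arm(lump, mu, "elv_angle", q90),
                          numeric(1))), tolerance = 1e-14)
  # missing compartment is a configuration error
  m2 <- lump
  m2$muscles <- m2$muscles[setdiff(names(m2$muscles), "pec_major_ribs")]
  expect_error(summed_pectoralis_moment_arm(m2, "elv_angle", q90), "missing")
})

test_that("implant wrap geometry follows the cylinder-volume inversion", {
  w <- implant_wrap_from_spec(405, 4.4)
  expect_equal(w$radius, sqrt(405e-6 / (pi * 0.044)), tolerance = 1e-12)
  expect_equal(w$radius, 0.0541285, tolerance = 1e-6)   # ~5.41 cm
  expect_equal(2 * w$half_length, 0.044)
  # volume pi cc, projection 1 cm -> radius 1 cm
  expect_equal(implant_wrap_from_spec(pi, 1)$radius, 0.01, tolerance = 1e-12)
  # doubling volume at fixed projection scales the radius by sqrt(2)
  expect_equal(implant_wrap_from_spec(810, 4.4)$radius,
               sqrt(2) * implant_wrap_from_spec(405, 4.4)$radius,
               tolerance = 1e-12)
  expect_error(implant_wrap_from_spec(-1, 4.4), "volume")
  expect_error(implant_wrap_from_spec(405, 0), "projection")
  # alternative projection reading: projection is the radius
  w2 <- implant_wrap_from_spec(405, 4.4, projection_is = "standoff")
  expect_equal(w2$radius, 0.044)
  expect_equal(2 * w2$half_length * pi * w2$radius^2, 405e-6, tolerance = 1e-12)
})

test_that("path length is continuous across wrap engagement", {
  impl <- fixture_model("implant")
  q <- zero_posture(impl)
  angles <- seq(0, deg2rad(130), length.out = 400)
  L <- vapply(angles, function(a) {
    q["elv_angle"] <- a
    path_length(impl, "pec_major_sternal", q)
  }, numeric(1))
  step <- diff(angles)[1]
  # no jumps beyond step * max slope (slope bounded by total path scale)
  expect_lt(max(abs(diff(L))), step * 1.0)
})
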
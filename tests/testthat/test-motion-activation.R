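test_that("generated motions hit the printed waypoints with C1 ramps", {
  rot <- generate_motion("rotation")
  ax <- rot$q[, "axial_rotation"]
  expect_equal(max(ax), deg2rad(45), tolerance = 1e-9)
  expect_equal(min(ax), deg2rad(-30), tolerance = 1e-9)
  expect_equal(ax[1], 0, tolerance = 1e-12)

  elev <- generate_motion("scapular_elevation")
  ev <- elev$q[, "elv_angle"]
  expect_equal(max(ev), deg2rad(90), tolerance = 1e-9)
  expect_equal(min(ev), deg2rad(45), tolerance = 1e-9)
  expect_equal(ev[length(ev)], deg2rad(45), tolerance = 1e-9)  # returns to start

  hor <- generate_motion("horizontal_abd_add")
  pl <- hor$q[, "elv_plane"]
  expect_equal(min(pl), deg2rad(-45), tolerance = 1e-9)
  expect_equal(max(pl), deg2rad(30), tolerance = 1e-9)
  expect_equal(hor$gravity, c(-9.80665, 0, 0))  # supine via rotated gravity

  # velocity zero at start, during the pause, and at the end
  i_pause <- rot$time > 4 & rot$time < 5
  expect_equal(max(abs(rot$qd[1, ])), 0)
  expect_equal(max(abs(rot$qd[i_pause, ])), 0)
  expect_equal(max(abs(rot$qd[nrow(rot$qd), ])), 0, tolerance = 1e-12)
  # C1 continuity: finite-difference velocity matches the stored velocity
  fd <- diff(ax) / rot$dt
  mid <- (rot$qd[-1, "axial_rotation"] + rot$qd[-length(ax), "axial_rotation"]) / 2
  expect_lt(max(abs(fd - mid)), 1e-3)
  # angles stay within joint ranges
  m <- fixture_model("lumpectomy")
  expect_true(all(apply(rot$q, 1, function(qq) all(posture_in_range(m, qq)))))

  expect_error(generate_motion("sprint"), "arg")
  expect_error(generate_motion("rotation", phase_duration = 0), "> 0")
})

test_that("rigid-tendon muscle force model behaves", {
  m <- fixture_model("lumpectomy")
  q0 <- zero_posture(m)
  expect_equal(max(abs(muscle_force(m, 0, q0))), 0)      # a = 0 -> F = 0
  # a = 1 at the reference posture -> F = Fmax (fiber at optimal length)
  fmax <- vapply(m$muscles, `[[`, numeric(1), "fmax")
  expect_equal(muscle_force(m, 1, q0), fmax, tolerance = 1e-12)
  # strictly increasing in activation at a fixed posture
  q <- zero_posture(m); q["elv_angle"] <- 0.6
  f1 <- muscle_force(m, 0.3, q); f2 <- muscle_force(m, 0.6, q)
  expect_true(all(f2 > f1))
  expect_error(muscle_force(m, 1.2, q0), "activation")
})

test_that("activation solver inverts a single-muscle toy exactly", {
  # one muscle over one hinge: activation = tau / (Fmax r fL), clipped
  p <- toy_pendulum(m = 2, l = 0.5)
  mus <- muscle_path("flexor", "toy",
                     list(list(body = "base", location = c(0.06, 0.0, 0)),
                          list(body = "rod", location = c(0.06, -0.25, 0))),
                     fmax = 400, lopt = 0.25)
  p$muscles <- list(flexor = mus)
  q <- c(theta = 0.4)
  B <- reconarm:::muscle_torque_basis(p, q)
  tau_need <- -gravity_generalized_forces(p, q)
  sol <- reconarm:::solve_activation_qp(B, tau_need, a_min = 0)
  expect_equal(sol$activation[1], tau_need[[1]] / B[1, 1], tolerance = 1e-5)
  expect_lt(max(abs(sol$reserve)), 1e-2)

  # gravity off, no motion: all activations zero when the floor is removed
  hist0 <- generate_motion("rotation", phase_duration = 0.2, pause = 0.1)
  hist0$q[] <- rep(hist0$q[1, ], each = nrow(hist0$q))
  hist0$qd[] <- 0; hist0$qdd[] <- 0
  hist0$gravity <- c(0, 0, 0)
  m <- fixture_model("lumpectomy")
  s0 <- solve_activations(m, hist0, a_min = 0)
  expect_equal(max(s0$activation), 0, tolerance = 1e-9)
})

test_that("QP solution is locally optimal under feasible perturbations", {
  m <- fixture_model("lumpectomy")
  q <- c(elv_plane = deg2rad(30), elv_angle = deg2rad(50), axial_rotation = 0,
         elbow_flexion = 0.3)
  B <- reconarm:::muscle_torque_basis(m, q)
  tau <- -gravity_generalized_forces(m, q)
  w <- 1e4
  sol <- reconarm:::solve_activation_qp(B, tau, w = w, a_min = 0.02)
  obj <- function(a) sum(a^2) + w * sum((tau - B %*% a)^2)
  f0 <- obj(sol$activation)
  set.seed(3)
  for (i in 1:30) {
    d <- stats::rnorm(ncol(B), 0, 1e-3)
    a2 <- pmin(1, pmax(0.02, sol$activation + d))
    expect_gte(obj(a2), f0 - 1e-10)
  }
})

test_that("tracking round-trip: resimulation reproduces the stored trajectory", {
  m <- fixture_model("lumpectomy")
  hist <- generate_motion("rotation", phase_duration = 1.5, pause = 0.5)
  sol <- solve_activations(m, hist)
  # closed-loop tracking better than 0.5 deg RMS per coordinate
  expect_lt(max(rad2deg(sol$tracking_rms_rad)), 0.5)
  # open-loop resimulation with the stored controls reproduces the stored
  # realized trajectory exactly (same integrator, same step)
  qs <- resimulate_activations(m, sol)
  expect_equal(qs, sol$q, tolerance = 1e-12)
  # activations within bounds, reserves small relative to gravity demands
  expect_true(all(sol$activation >= 0.02 - 1e-12 & sol$activation <= 1 + 1e-12))
  peak_grav <- max(abs(apply(hist$q, 1, function(qq)
    gravity_generalized_forces(m, stats::setNames(qq, m$coords)))))
  expect_lt(max(abs(sol$reserve)), 0.05 * peak_grav)
})
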
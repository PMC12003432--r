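test_that("stadium section properties: degenerate and quadrature cases", {
  # a = 0: circle
  s <- stadium_section_properties(0, 0.1)
  expect_equal(s$area, pi * 0.1^2)
  expect_equal(s$I_u, pi * 0.1^4 / 4)
  expect_equal(s$I_v, pi * 0.1^4 / 4)
  # r -> 0: tends to the 2a x 2r rectangle formulas
  a <- 0.2; r <- 1e-4
  s <- stadium_section_properties(a, r)
  expect_equal(s$area, 4 * a * r, tolerance = 1e-3)
  expect_equal(s$I_v, (2 * r) * (2 * a)^3 / 12, tolerance = 1e-3)
  # random shapes vs dense-grid integration
  set.seed(5)
  for (i in 1:5) {
    a <- stats::runif(1, 0.01, 0.3); r <- stats::runif(1, 0.02, 0.2)
    s <- stadium_section_properties(a, r)
    o <- section_oracle(a, r)
    expect_equal(s$area, o$area, tolerance = 1e-6)
    expect_equal(s$I_u, o$I_u, tolerance = 1e-6)
    expect_equal(s$I_v, o$I_v, tolerance = 1e-6)
  }
  expect_error(stadium_section_properties(-0.1, 0.1), "non-negative")
  expect_error(stadium_section_properties(0, 0), "both")
})

test_that("solid mass properties: cylinder limit, parallel axis, voxel oracle", {
  # a = 0 -> solid cylinder: I about extrusion axis = m r^2 / 2
  cyl <- stadium_solid(0, 0.1, 0.4, base_density = 1.0, center = c(0, 0, 0))
  p <- solid_mass_properties(cyl)
  expect_equal(p$inertia[2, 2], p$mass * 0.1^2 / 2, tolerance = 1e-12)
  expect_equal(p$mass, 1000 * pi * 0.1^2 * 0.4, tolerance = 1e-9)

  # parallel-axis identity: recompute about an offset point and transfer back
  d <- c(0.05, -0.1, 0.02)
  I_off <- p$inertia + p$mass * (sum(d^2) * diag(3) - outer(d, d))
  I_back <- I_off - p$mass * (sum(d^2) * diag(3) - outer(d, d))
  expect_equal(I_back, p$inertia, tolerance = 1e-14)

  # random solids vs voxel integration at 1e-3 relative
  set.seed(11)
  for (i in 1:6) {
    s <- stadium_solid(stats::runif(1, 0.0, 0.15), stats::runif(1, 0.05, 0.2),
                       stats::runif(1, 0.2, 0.6), base_density = stats::runif(1, 0.8, 1.1),
                       center = c(0, 0, 0))
    ana <- solid_mass_properties(s)
    vox <- voxel_oracle(s)
    expect_equal(ana$mass, vox$mass, tolerance = 2e-3)
    expect_equal(diag(ana$inertia), diag(vox$inertia), tolerance = 2e-3)
  }
})

test_that("tissue scheme superposition is exact and matches printed deltas", {
  base <- solid_mass_properties(stadium_solid(0.019, 0.119, 0.52, 1.0,
                                              center = c(-0.0926, -0.166, 0)))
  # implant: dm = (1.05 - 0.95) g/mL * 405 cc = +0.0405 kg
  impl <- apply_tissue_scheme(base, tissue_scheme("implant"))
  expect_equal(impl$mass - base$mass, 0.0405, tolerance = 1e-12)
  # flap: dm = (0.84 - 0.95) * 405 cc = -0.04455 kg, COM shifts off the region
  flap <- apply_tissue_scheme(base, tissue_scheme("flap"))
  expect_equal(flap$mass - base$mass, -0.04455, tolerance = 1e-12)
  expect_lt(flap$com[3], 0)  # region at +z, mass removed -> COM moves to -z
  expect_gt(impl$com[3], 0)
  # native scheme returns the base unchanged
  expect_identical(apply_tissue_scheme(base, tissue_scheme("lumpectomy")), base)
  # composing then decomposing recovers the base to 1e-12
  sch <- tissue_scheme("implant")
  inv <- sch; inv$breast_density <- 2 * 0.95 - sch$breast_density
  back <- apply_tissue_scheme(impl, inv)
  expect_equal(back$mass, base$mass, tolerance = 1e-12)
  expect_equal(back$com, base$com, tolerance = 1e-12)
  expect_equal(back$inertia, base$inertia, tolerance = 1e-12)
  # region outside the solid envelope is rejected
  solid <- stadium_solid(0.019, 0.119, 0.52, 1.0, center = c(-0.0926, -0.166, 0))
  far <- tissue_scheme("implant", region_center = c(0.5, -0.1, 0))
  expect_error(apply_tissue_scheme(base, far, solid = solid), "outside")
})

test_that("variant torsos reproduce the density-driven structure", {
  tl <- build_variant_torso("lumpectomy")
  ti <- build_variant_torso("implant")
  tf <- build_variant_torso("flap")
  # inertia ordering about every principal axis
  for (k in 1:3) {
    expect_gt(ti$inertia[k, k], tl$inertia[k, k])
    expect_lt(tf$inertia[k, k], tl$inertia[k, k])
  }
  # symmetric lumpectomy: COM z = 0 and no products of inertia
  expect_equal(tl$com[3], 0)
  expect_equal(max(abs(tl$inertia - diag(diag(tl$inertia)))), 0)
  # unilateral region: opposite COM z signs, nonzero products
  expect_gt(ti$com[3], 0); expect_lt(tf$com[3], 0)
  expect_gt(max(abs(ti$inertia - diag(diag(ti$inertia)))), 0)
  expect_gt(max(abs(tf$inertia - diag(diag(tf$inertia)))), 0)
  # inertia tensors are exactly symmetric
  expect_equal(ti$inertia, t(ti$inertia))
  expect_error(build_variant_torso("mastopexy"), "arg")
})
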
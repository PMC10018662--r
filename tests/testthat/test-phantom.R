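test_that("phantom generation is deterministic given the seed", {
  spec <- phantom_spec(noise_sd = 15, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$ct, b$ct)
  expect_identical(a$masks, b$masks)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(phantom_spec(lens_radius = 13), "lens_radius")
  expect_error(phantom_spec(brain_semi_axes = c(74, 70, 58)),
               "brain_semi_axes")
  expect_error(phantom_spec(hu_map = c(air = -1000)), "hu_map")
  expect_error(phantom_spec(voxel_spacing = c(2, 2)), "voxel_spacing")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(c1_top_z = -10), "c1_top_z")
})

test_that("lens mask volume approximates the analytic sphere volume", {
  vol <- default_volume()
  vox <- prod(vol$spacing)
  analytic <- 4 / 3 * pi * phantom_spec()$lens_radius^3
  for (side in c("lens_L", "lens_R")) {
    got <- sum(vol$masks[[side]]) * vox
    expect_lt(abs(got - analytic) / analytic, 0.15)
  }
})

test_that("containment and disjointness invariants hold across random specs", {
  for (seed in 1:4) {
    vol <- generate_phantom(random_phantom_spec(seed))
    m <- vol$masks
    expect_true(all(vapply(m, any, logical(1))))      # all nonempty
    expect_false(any(m$lens_L & !m$eye_L))            # lens inside eye
    expect_false(any(m$lens_R & !m$eye_R))
    expect_false(any(m$brain & (m$eye_L | m$eye_R)))  # brain/eye disjoint
    for (nm in c("brain", "eye_L", "eye_R", "C1", "C2"))
      expect_false(any(m[[nm]] & !m$external))        # inside external
  }
})

test_that("zero tilt equals a full turn", {
  s0 <- phantom_spec(head_tilt_deg = 0)
  s360 <- phantom_spec(head_tilt_deg = 360)
  expect_equal(generate_phantom(s0)$masks, generate_phantom(s360)$masks,
               tolerance = 0)
})

test_that("C1 lies strictly inferior to the brain", {
  vol <- default_volume()
  z <- vol$origin[3] + (seq_len(dim(vol$ct)[3]) - 1) * vol$spacing[3]
  c1_top <- max(z[apply(vol$masks$C1, 3, any)])
  brain_bottom <- min(z[apply(vol$masks$brain, 3, any)])
  expect_lt(c1_top, brain_bottom)
})

test_that("mask volumes converge to analytic volumes as spacing shrinks", {
  ## digitization error of a solid's voxel volume is a surface term, so a
  ## 2.5x spacing refinement must shrink the combined eye+brain error
  analytic <- list(eye_L = 4 / 3 * pi * 12^3,
                   brain = 4 / 3 * pi * 60 * 69 * 58)
  err <- vapply(c(4, 1.6), function(sp) {
    vol <- generate_phantom(phantom_spec(voxel_spacing = rep(sp, 3),
                                         ct_supersample = 1))
    sum(vapply(names(analytic), function(nm)
      abs(sum(vol$masks[[nm]]) * sp^3 - analytic[[nm]]) / analytic[[nm]],
      numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})
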
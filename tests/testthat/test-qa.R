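square <- function(side = 50, at = c(0, 0)) {
  cbind(at[1] + c(0, side, side, 0), at[2] + c(0, 0, side, side))
}

test_that("evaluation ROI matches the hand-derived fixture rectangle", {
  roi <- evaluation_roi(fixture_structures())
  ## u: [C1 u C2 posterior edge - 5, forehead anterior edge + 20]
  expect_equal(roi$u, c(-40 - 5, 80 + 20))
  ## v: [C1 inferior edge, skin top + flash]
  expect_equal(roi$v, c(-75, 70 + 15))
  roi2 <- evaluation_roi(fixture_structures(),
                         aperture_config(caudal_vertebra = "C2",
                                         skin_flash = 10))
  expect_equal(roi2$v, c(-103, 80))
})

test_that("a vertebra anterior to the forehead gives an empty-ROI error", {
  ss <- fixture_structures()
  ## shrink the skin to far posterior so forehead+20 lies behind vertebrae-5
  ss$masks$external <- outer(ss$u > -90 & ss$u < -70,
                             ss$v > -110 & ss$v < 70, `&`)
  expect_error(evaluation_roi(ss), "ROI")
})

test_that("hausdorff and MSD follow closed forms for translated squares", {
  a <- square()
  b <- square(at = c(3, 0))
  expect_equal(hausdorff(a, a), 0)
  expect_equal(mean_surface_distance(a, a), 0)
  expect_equal(hausdorff(a, b), 3, tolerance = 1e-12)
  m <- mean_surface_distance(a, b)
  expect_gt(m, 0)
  expect_lte(m, 3)
  ## symmetry
  expect_equal(hausdorff(b, a), hausdorff(a, b))
  expect_equal(mean_surface_distance(b, a), mean_surface_distance(a, b))
})

test_that("metrics agree with the brute-force oracle on random polygons", {
  for (seed in 1:6) {
    pa <- star_polygon(seed)
    pb <- star_polygon(seed + 100)
    bf <- bf_surface_distances(pa, pb)
    expect_lt(abs(hausdorff(pa, pb) - bf$hd), 1e-9)
    expect_lt(abs(mean_surface_distance(pa, pb) - bf$msd), 1e-9)
    expect_gte(hausdorff(pa, pb), mean_surface_distance(pa, pb))
  }
})

test_that("ROI clipping never increases the Hausdorff distance", {
  roi <- structure(list(u = c(-30, 30), v = c(-30, 30)),
                   class = "evaluation_roi")
  for (seed in 7:10) {
    pa <- star_polygon(seed)
    pb <- star_polygon(seed + 50)
    expect_lte(hausdorff(pa, pb, roi), hausdorff(pa, pb) + 1e-12)
  }
  tiny <- structure(list(u = c(500, 510), v = c(500, 510)),
                    class = "evaluation_roi")
  expect_error(hausdorff(star_polygon(1), star_polygon(2), tiny), "ROI")
})

test_that("compare_approaches issues pass/flag verdicts", {
  ss <- fixture_structures()
  cfg <- aperture_config(ce_shape = "straight")
  ap1 <- build_aperture(compute_landmarks(ss, cfg), cfg)
  rep0 <- compare_approaches(ap1, ap1)
  expect_equal(rep0$verdict, "pass")
  expect_identical(rep0$hd, 0)
  expect_identical(rep0$msd, 0)
  ap2 <- ap1
  ap2$vertices[, 1] <- ap2$vertices[, 1] + 20
  rep1 <- compare_approaches(ap1, ap2)
  expect_equal(rep1$verdict, "flag")
  ap3 <- ap1; ap3$gantry_deg <- 90
  expect_error(compare_approaches(ap1, ap3), "frames")
})
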
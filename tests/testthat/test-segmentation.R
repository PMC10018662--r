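test_that("dice follows its closed forms and conventions", {
  a <- matrix(FALSE, 20, 20); a[3:12, 5:14] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[15:18, 15:18] <- TRUE
  expect_equal(dice(a, b), 0)
  ## 10x10 square against itself shifted to overlap 5x10: 2*50/200
  s <- matrix(FALSE, 20, 20); s[8:17, 5:14] <- TRUE
  expect_equal(dice(a, s), 0.5)
  expect_equal(dice(b, a), dice(a, b))
  e <- matrix(FALSE, 4, 4)
  expect_warning(z <- dice(e, e), "empty")
  expect_equal(z, 0)
  expect_error(dice(a, e), "shapes")
})

test_that("an all-air DRR fails with every structure reported missing", {
  air <- array(-1000, c(20, 20, 20))
  drr <- render_drr(air, beam_geometry(270), c(2, 2, 2), c(-19, -19, -19))
  err <- tryCatch(segment_drr(drr, segmentation_hints(phantom_spec())),
                  wbrt_segmentation_failure = function(e) e)
  expect_s3_class(err, "wbrt_segmentation_failure")
  expect_setequal(err$missing, REQUIRED_STRUCTURES)
})

test_that("the noise-free default phantom segments with high Dice", {
  seg <- default_segmentation()
  truth <- default_projection()
  d <- vapply(names(truth$masks), function(nm)
    dice(seg$masks[[nm]], truth$masks[[nm]]), numeric(1))
  expect_true(all(d >= 0.90))
  expect_gte(d[["brain"]], 0.95)
})

test_that("segmented structures are subsets of the segmented external", {
  seg <- default_segmentation()
  for (nm in setdiff(names(seg$masks), "external"))
    expect_false(any(seg$masks[[nm]] & !seg$masks$external))
})

test_that("20 HU noise degrades Dice only marginally", {
  truth <- default_projection()
  seg0 <- default_segmentation()
  noisy <- generate_phantom(phantom_spec(noise_sd = 20))
  seg1 <- segment_drr(render_drr(noisy, beam_geometry(270)),
                      segmentation_hints(phantom_spec(noise_sd = 20)))
  for (nm in names(truth$masks)) {
    d0 <- dice(seg0$masks[[nm]], truth$masks[[nm]])
    d1 <- dice(seg1$masks[[nm]], truth$masks[[nm]])
    if (nm %in% c("lens_L", "lens_R")) {
      ## a 4 mm structure at 2 mm pixels sits at its localization limit
      ## under ray noise; it must still be found close to its true position
      expect_gte(d1, 0.75)
    } else {
      expect_gt(d1 - d0, -0.05)
    }
  }
})
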
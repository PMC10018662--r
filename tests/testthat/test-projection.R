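make_sphere <- function(r = 20, n = 31, sp = 2) {
  x <- (seq_len(n) - (n + 1) / 2) * sp
  arr <- array(FALSE, c(n, n, n))
  for (i in 1:n) arr[i, , ] <- outer(x^2, x^2, `+`) + x[i]^2 <= r^2
  list(mask = arr, spacing = rep(sp, 3), origin = rep(x[1], 3))
}

test_that("empty masks project to empty BEV masks with a warning", {
  m <- array(FALSE, c(5, 6, 7))
  expect_warning(
    bev <- project_mask_bev(m, beam_geometry(270), c(2, 2, 2), c(0, 0, 0)),
    "empty")
  expect_false(any(bev$pixels))
})

test_that("a centered sphere projects to a disk with the analytic box", {
  s <- make_sphere(r = 20)
  bev <- project_mask_bev(s$mask, beam_geometry(270), s$spacing, s$origin)
  bb <- bounding_box(bev)
  expect_lt(abs((bb["umax"] - bb["umin"]) - 40), 2 + 1e-9)
  expect_lt(abs((bb["vmax"] - bb["vmin"]) - 40), 2 + 1e-9)
})

test_that("mask projection matches the brute-force per-ray oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- c(9, 11, 8)
    mask <- array(runif(prod(d)) < 0.08, d)
    spacing <- runif(3, 1.5, 3)
    origin <- runif(3, -12, -8)
    for (g in c(270, 90)) {
      bev <- project_mask_bev(mask, beam_geometry(g), spacing, origin)
      expect_identical(bev$pixels,
                       bf_project_mask(mask, spacing, origin,
                                       bev$u, bev$v, g))
    }
  }
})

test_that("DRR rendering matches closed forms and the brute-force oracle", {
  ## uniform air renders to zero
  air <- array(-1000, c(6, 6, 6))
  drr <- render_drr(air, beam_geometry(270), c(2, 2, 2), c(-5, -5, -5))
  expect_true(all(drr$pixels == 0))
  ## single voxel of HU 0 at 2 mm spacing integrates to 1000 * 2
  ct <- array(-1000, c(5, 5, 5)); ct[3, 3, 3] <- 0
  drr1 <- render_drr(ct, beam_geometry(270), c(2, 2, 2), c(-4, -4, -4))
  expect_equal(max(drr1$pixels), 2000)
  expect_equal(sum(drr1$pixels > 0), 1)
  ## random volume equals the naive per-pixel summation oracle
  set.seed(9)
  d <- c(8, 10, 9)
  ct <- array(runif(prod(d), -1000, 1500), d)
  spacing <- c(2.5, 1.8, 2.2); origin <- c(-9, -8, -10)
  for (g in c(270, 90)) {
    drr <- render_drr(ct, beam_geometry(g), spacing, origin)
    oracle <- bf_drr(ct, spacing, origin, drr$u, drr$v, g)
    expect_lt(max(abs(drr$pixels - oracle)) / max(oracle), 1e-9)
  }
})

test_that("gantry 90 and 270 are exact u-mirrors", {
  vol <- default_volume()
  m270 <- project_mask_bev(vol$masks$brain, beam_geometry(270),
                           vol$spacing, vol$origin)
  m90 <- project_mask_bev(vol$masks$brain, beam_geometry(90),
                          vol$spacing, vol$origin)
  expect_identical(m90$pixels, m270$pixels[nrow(m270$pixels):1, ])
  d270 <- render_drr(vol, beam_geometry(270))
  d90 <- render_drr(vol, beam_geometry(90))
  expect_identical(d90$pixels, d270$pixels[nrow(d270$pixels):1, ])
})

test_that("projection respects union and subset structure", {
  set.seed(4)
  d <- c(10, 12, 11)
  a <- array(runif(prod(d)) < 0.1, d)
  b <- array(runif(prod(d)) < 0.1, d)
  g <- beam_geometry(270); sp <- c(2, 2, 2); or <- c(-9, -11, -10)
  pa <- project_mask_bev(a, g, sp, or)$pixels
  pb <- project_mask_bev(b, g, sp, or)$pixels
  pab <- project_mask_bev(a | b, g, sp, or)$pixels
  expect_identical(pab, pa | pb)
  sub <- a & b
  if (any(sub)) {
    psub <- project_mask_bev(sub, g, sp, or)$pixels
    expect_false(any(psub & !pa))
  }
})

test_that("divergent fan geometry approaches the parallel limit at large SAD", {
  s <- make_sphere(r = 16, n = 25)
  par <- project_mask_bev(s$mask, beam_geometry(270), s$spacing, s$origin)
  div <- project_mask_bev(s$mask, beam_geometry(270, "divergent", sad = 1000),
                          s$spacing, s$origin)
  ## magnification at SAD 1000 for a 16 mm sphere is ~1.01: at most one
  ## pixel of disagreement at the rim
  expect_lt(sum(xor(par$pixels, div$pixels)) / sum(par$pixels), 0.15)
  ## symmetric volume: divergent views mirror too
  div90 <- project_mask_bev(s$mask, beam_geometry(90, "divergent", sad = 1000),
                            s$spacing, s$origin)
  expect_identical(div90$pixels, div$pixels[nrow(div$pixels):1, ])
})

test_that("boundary extraction closes contours and preserves area", {
  u <- seq(0.5, 29.5, 1); v <- seq(0.5, 24.5, 1)
  sq <- outer(u > 5 & u < 15, v > 5 & v < 15, `&`)
  pl <- mask_to_polyline(sq, u, v)
  expect_length(pl, 1)
  expect_true(pl[[1]]$closed)
  expect_lt(abs(polygon_area(pl[[1]]$vertices) - 100), 40 * 0.5)
  ## two disjoint squares -> two counter-clockwise polylines
  sq2 <- sq | outer(u > 20 & u < 26, v > 16 & v < 22, `&`)
  pl2 <- mask_to_polyline(sq2, u, v)
  expect_length(pl2, 2)
  ## random blob: area consistency within perimeter * spacing / 2
  set.seed(11)
  blob <- matrix(runif(30 * 25) < 0.4, 30, 25)
  blob <- blob & !blob[c(2:30, 1), ]  # thin it out a bit
  blob[c(1, 30), ] <- FALSE; blob[, c(1, 25)] <- FALSE
  if (any(blob)) {
    pls <- mask_to_polyline(blob, u, v)
    area <- sum(vapply(pls, function(p) polygon_area(p$vertices), numeric(1)))
    perim <- sum(vapply(pls, function(p) {
      pts <- rbind(p$vertices, p$vertices[1, ])
      sum(sqrt(rowSums(diff(pts)^2)))
    }, numeric(1)))
    expect_lt(abs(area - sum(blob)), perim * 0.5)
  }
  expect_error(mask_to_polyline(sq & FALSE, u, v), "empty")
})
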
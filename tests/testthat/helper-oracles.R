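# Independent brute-force oracles and shared fixtures.

# ---- brute-force projection oracles (explicit per-pixel/per-voxel loops) ----

bf_project_mask <- function(mask, spacing, origin, u, v, gantry = 270) {
  s <- if (gantry == 270) 1 else -1
  d <- dim(mask)
  out <- matrix(FALSE, length(u), length(v))
  for (iu in seq_along(u)) {
    yw <- -s * u[iu]
    j <- round((yw - origin[2]) / spacing[2]) + 1
    if (j < 1 || j > d[2]) next
    for (iv in seq_along(v)) {
      k <- round((v[iv] - origin[3]) / spacing[3]) + 1
      if (k < 1 || k > d[3]) next
      hit <- FALSE
      for (i in seq_len(d[1])) if (mask[i, j, k]) { hit <- TRUE; break }
      out[iu, iv] <- hit
    }
  }
  out
}

bf_drr <- function(ct, spacing, origin, u, v, gantry = 270) {
  s <- if (gantry == 270) 1 else -1
  d <- dim(ct)
  out <- matrix(0, length(u), length(v))
  for (iu in seq_along(u)) {
    yw <- -s * u[iu]
    j <- round((yw - origin[2]) / spacing[2]) + 1
    if (j < 1 || j > d[2]) next
    for (iv in seq_along(v)) {
      k <- round((v[iv] - origin[3]) / spacing[3]) + 1
      if (k < 1 || k > d[3]) next
      acc <- 0
      for (i in seq_len(d[1])) acc <- acc + max(ct[i, j, k] + 1000, 0)
      out[iu, iv] <- acc * spacing[1]
    }
  }
  out
}

# ---- brute-force surface distances (own densification, O(N^2) loops) ----

bf_densify <- function(p, step = 0.5) {
  n <- nrow(p)
  pts <- NULL
  for (e in seq_len(n)) {
    a <- p[e, ]; b <- p[if (e == n) 1 else e + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1, ceiling(len / step))
    for (t in seq(0, k - 1) / k) pts <- rbind(pts, a + t * (b - a))
  }
  pts
}

bf_clip <- function(pts, roi) {
  keep <- pts[, 1] >= roi$u[1] & pts[, 1] <= roi$u[2] &
    pts[, 2] >= roi$v[1] & pts[, 2] <= roi$v[2]
  pts[keep, , drop = FALSE]
}

bf_surface_distances <- function(pa, pb, roi = NULL, step = 0.5) {
  a <- bf_densify(pa, step); b <- bf_densify(pb, step)
  if (!is.null(roi)) { a <- bf_clip(a, roi); b <- bf_clip(b, roi) }
  dmin_ab <- numeric(nrow(a)); dmin_ba <- numeric(nrow(b))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      dd <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (dd < best) best <- dd
    }
    dmin_ab[i] <- best
  }
  for (j in seq_len(nrow(b))) {
    best <- Inf
    for (i in seq_len(nrow(a))) {
      dd <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (dd < best) best <- dd
    }
    dmin_ba[j] <- best
  }
  list(hd = max(max(dmin_ab), max(dmin_ba)),
       msd = (mean(dmin_ab) + mean(dmin_ba)) / 2)
}

# random star-shaped simple polygon
star_polygon <- function(seed, n = 12, r_range = c(20, 50),
                         center = c(0, 0)) {
  set.seed(seed)
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_range[1], r_range[2])
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# ---- rectangle fixture for the landmark hand-check ----
#
# 1 mm grid, u in [-100, 100], v in [-120, 80]; every structure is an
# axis-aligned box with edges on integer mm so bounding boxes are exact:
#   external [-90, 80] x [-110, 70]
#   brain    [-70, 55] x [ -40, 60]
#   eyes     [ 40, 64] x [ -20,  4]
#   lenses   [ 54, 62] x [ -12, -4]
#   C1       [-40,-10] x [ -75,-55]
#   C2       [-40,-10] x [-103,-83]
fixture_boxes <- list(
  external = c(-90, 80, -110, 70),
  brain = c(-70, 55, -40, 60),
  eye = c(40, 64, -20, 4),
  lens = c(54, 62, -12, -4),
  C1 = c(-40, -10, -75, -55),
  C2 = c(-40, -10, -103, -83)
)

fixture_structures <- function() {
  u <- seq(-99.5, 99.5, by = 1)
  v <- seq(-119.5, 79.5, by = 1)
  box_mask <- function(b) {
    outer(u > b[1] & u < b[2], v > b[3] & v < b[4], `&`)
  }
  masks <- list(external = box_mask(fixture_boxes$external),
                brain = box_mask(fixture_boxes$brain),
                eye_L = box_mask(fixture_boxes$eye),
                eye_R = box_mask(fixture_boxes$eye),
                lens_L = box_mask(fixture_boxes$lens),
                lens_R = box_mask(fixture_boxes$lens),
                C1 = box_mask(fixture_boxes$C1),
                C2 = box_mask(fixture_boxes$C2))
  structure_set_2d(masks, u, v, beam_geometry(270), "approach1")
}

# hand-derived landmark coordinates for the fixture under a config
# (worked out from the construction rules; see test-aperture.R)
fixture_landmarks <- function(config) {
  flash <- config$skin_flash
  v_HI <- 70 + flash
  u_IA <- 80 + flash
  u_GH <- -90 - flash
  v_F <- if (config$caudal_vertebra == "C1") -75 else -103
  if (config$include_orbits) {
    u_a <- 80 + flash
    lm <- rbind(A = c(u_a, 4), B = c(u_a, 4), C = c(u_a, 4), D = c(u_a, 4),
                E = c(u_a, v_F), F = c(u_a, v_F), G = c(u_GH, v_F),
                H = c(u_GH, v_HI), I = c(u_a, v_HI))
  } else {
    u_B <- switch(config$bc_position, lens = 54, eye = 40, mid = 47)
    v_B <- 4
    A <- if (config$ab_shape == "horizontal") c(u_IA, v_B)
         else c(u_IA, v_B + config$ab_diagonal_rise)
    C <- c(u_B, -55)  # EB flat bottom: brain vmin - 15 mm margin
    E <- c(-10 + config$vertebra_anterior_margin, -55)
    D <- if (config$ce_shape == "straight") (C + E) / 2 else C
    lm <- rbind(A = A, B = c(u_B, v_B), C = C, D = D, E = E,
                F = c(E[1], v_F), G = c(u_GH, v_F), H = c(u_GH, v_HI),
                I = c(u_IA, v_HI))
  }
  colnames(lm) <- c("u", "v")
  lm
}

# ---- randomized phantom family ----
#
# anatomy co-varied so the orbit abuts the anterior skull with its pole
# ~2.5 mm behind the skin, and the brain width at orbit-top level sits
# ~5 mm behind the default (bc = mid) BC line
random_phantom_spec <- function(seed, noise_sd = 0) {
  set.seed(seed)
  hx <- runif(1, 72, 78); hy <- runif(1, 97, 104); hz <- runif(1, 82, 88)
  bx <- runif(1, 57, 62); bz <- runif(1, 55, 59)
  re <- runif(1, 10.5, 13); rl <- runif(1, 3.5, 4.5)
  xe <- runif(1, 24, 28); ze <- runif(1, -43, -38)
  hc <- c(0, 2, -8)
  wy <- hy * sqrt(1 - (xe / hx)^2 - ((ze - hc[3]) / hz)^2)
  ye <- hc[2] - (wy - re - 2.5)
  u_bc <- -ye - rl
  s_top <- sqrt(1 - ((ze + re) / bz)^2)
  by <- (u_bc - 5 + runif(1, -1.5, 1.5)) / s_top
  phantom_spec(
    head_semi_axes = c(hx, hy, hz), brain_semi_axes = c(bx, by, bz),
    eye_radius = re, lens_radius = rl,
    eye_center_offsets = list(left = c(xe, ye, ze), right = c(-xe, ye, ze)),
    vertebra_heights = c(C1 = runif(1, 18, 22), C2 = runif(1, 18, 22)),
    vertebra_radius = runif(1, 12, 15), c1_top_z = runif(1, -74, -68),
    head_tilt_deg = runif(1, -4, 4), noise_sd = noise_sd, seed = seed)
}

# ---- shared caches (phantom generation dominates test time) ----

.wbrt_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .wbrt_cache)) assign(key, expr, envir = .wbrt_cache)
  get(key, envir = .wbrt_cache)
}

default_volume <- function() cached("default_volume",
                                    generate_phantom(phantom_spec()))

default_projection <- function() cached(
  "default_projection",
  project_structures(default_volume(), beam_geometry(270)))

default_segmentation <- function() cached(
  "default_segmentation",
  segment_drr(render_drr(default_volume(), beam_geometry(270)),
              segmentation_hints(phantom_spec())))

random_pipeline <- function(seed) cached(
  paste0("pipeline_", seed),
  run_pipeline(random_phantom_spec(seed)))
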
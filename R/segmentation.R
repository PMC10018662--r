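## Rule-based segmentation of landmark structures directly on the DRR
## (approach 2). The chain combines a water-equivalent intensity model of
## the body outline (per-row elliptical chord fit) with intensity bands
## derived from the phantom's HU map and anatomically constrained searches;
## it is an exchangeable stand-in for a learned BEV contouring model and is
## scoped to phantom-class images.

#' Intensity-band hints for the DRR segmenter
#'
#' Derives the attenuation contrasts the segmenter needs from a phantom's
#' HU map and geometry. `mu` values are `max(HU + 1000, 0)` per mm of path;
#' eye and lens bands are doubled because the lateral view superimposes the
#' left and right globes.
#'
#' @param spec a [phantom_spec()].
#' @return List of intensity bands (HU.mm) and geometric scales (mm).
#' @export
segmentation_hints <- function(spec) {
  mu <- function(name) max(spec$hu_map[[name]] + 1000, 0)
  list(
    air_threshold = mu("soft_tissue") * 1.0,        # >= ~1 mm of tissue
    bone_excess_per_mm = mu("bone") - mu("soft_tissue"),
    eye_deficit_per_mm = 2 * (mu("soft_tissue") - mu("eye")),  # paired eyes
    lens_excess_per_mm = 2 * (mu("lens") - mu("eye")),
    skull_thickness = spec$skull_thickness,
    eye_radius = spec$eye_radius,
    lens_radius = spec$lens_radius,
    vertebra_radius = spec$vertebra_radius,
    morph_radius = 3
  )
}

#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; 0 (with a warning) when both masks are empty.
#'
#' @param mask_a,mask_b logical matrices or arrays on the same grid.
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (inherits(mask_a, "bev_image")) mask_a <- mask_a$pixels
  if (inherits(mask_b, "bev_image")) mask_b <- mask_b$pixels
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("dice: masks have different shapes")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) {
    warning("dice of two empty masks defined as 0")
    return(0)
  }
  2 * sum(mask_a & mask_b) / (na + nb)
}

largest_cc <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  matrix(lab == which.max(sizes), nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  matrix(as.numeric(EBImage::fillHull(mask + 0)) > 0.5,
         nrow(mask), ncol(mask))
}

## Water-equivalent background model: for every image row (fixed v) the body
## cross-section of an ellipsoidal head or cylindrical neck gives a chord
## profile m(v) * sqrt(1 - ((u - uc)/a)^2); the scale m(v) is fit robustly
## (median), so compact internal structures (bone, eyes) survive in the
## residual I - baseline.
chord_baseline <- function(I, body, u, exclude = NULL) {
  baseline <- matrix(0, nrow(I), ncol(I))
  pmap <- matrix(0, nrow(I), ncol(I))
  du <- u[2] - u[1]
  for (j in seq_len(ncol(I))) {
    on <- which(body[, j])
    if (length(on) < 5) next
    uc <- (u[on[1]] + u[on[length(on)]]) / 2
    a <- (u[on[length(on)]] - u[on[1]]) / 2 + du / 2
    p <- sqrt(pmax(0, 1 - ((u[on] - uc) / a)^2))
    sel <- p > 0.25
    if (!is.null(exclude)) {
      sel2 <- sel & !exclude[on, j]
      if (sum(sel2) >= 3) sel <- sel2
    }
    if (sum(sel) < 3) next
    m <- stats::median(I[on[sel], j] / p[sel])
    baseline[on, j] <- m * p
    pmap[on, j] <- p
  }
  list(baseline = baseline, p = pmap)
}

## Sub-pixel baseline used for the faint eye/lens contrasts. For rays along
## x through a homogeneous (possibly tilted) ellipsoid the squared line
## integral I^2 is an exact quadric in (u, v) including a uv cross term, so
## one global least-squares fit of I^2 on (1, u, u^2, v, v^2, uv) over the
## head-only rows (v >= v_min), with bone pixels excluded, gives a
## soft-tissue baseline accurate to sub-voxel level. `p` is the relative
## chord (1 at the fitted apex, 0 at the rim), a reliability score.
ellipsoid_baseline <- function(I, body, u, v, v_min, exclude = NULL) {
  U <- matrix(u, length(u), length(v))
  V <- matrix(v, length(u), length(v), byrow = TRUE)
  region <- body & V >= v_min
  fitsel <- region
  if (!is.null(exclude)) {
    cand <- region & !exclude
    if (sum(cand) >= 50) fitsel <- cand
  }
  out <- list(baseline = matrix(0, nrow(I), ncol(I)),
              p = matrix(0, nrow(I), ncol(I)), region = region)
  if (sum(fitsel) < 50) return(out)
  X <- cbind(1, U[fitsel], U[fitsel]^2, V[fitsel], V[fitsel]^2,
             U[fitsel] * V[fitsel])
  co <- tryCatch(stats::lm.fit(X, I[fitsel]^2)$coefficients,
                 error = function(e) rep(NA_real_, 6))
  ## the quadratic form must be negative definite (an ellipse rim)
  if (anyNA(co) || co[3] >= 0 || co[5] >= 0 ||
      4 * co[3] * co[5] - co[6]^2 <= 0) return(out)
  pred <- co[1] + co[2] * U + co[3] * U^2 + co[4] * V + co[5] * V^2 +
    co[6] * U * V
  ## apex: stationary point of the quadric
  A <- matrix(c(2 * co[3], co[6], co[6], 2 * co[5]), 2, 2)
  cc <- solve(A, -c(co[2], co[4]))
  m2 <- co[1] + co[2] * cc[1] + co[3] * cc[1]^2 + co[4] * cc[2] +
    co[5] * cc[2]^2 + co[6] * cc[1] * cc[2]
  if (m2 <= 0) return(out)
  base <- sqrt(pmax(pred, 0))
  base[!region] <- 0
  pmap <- sqrt(pmax(pred, 0) / m2)
  pmap[!region] <- 0
  list(baseline = base, p = pmap, region = region)
}

## template-matching search on a residual map: at every candidate center the
## expected signal pattern (a signed weight matrix from `tmpl`) is fit by
## least squares with an intercept over pixels marked valid, and the center
## with the largest fitted amplitude wins. The intercept keeps broad
## background offsets from masquerading as signal.
match_template <- function(score, valid, u, v, centers_u, centers_v,
                           radius, tmpl, min_coverage = 0.25,
                           max_amp = Inf) {
  du <- u[2] - u[1]; dv <- v[2] - v[1]
  ri <- ceiling(radius / du); rj <- ceiling(radius / dv)
  U0 <- matrix(seq(-ri, ri) * du, 2 * ri + 1, 2 * rj + 1)
  V0 <- matrix(seq(-rj, rj) * dv, 2 * ri + 1, 2 * rj + 1, byrow = TRUE)
  full <- sum(abs(tmpl(U0, V0)) > 0)
  best <- list(score = -Inf, center = c(NA_real_, NA_real_))
  for (cu in centers_u) for (cv in centers_v) {
    i0 <- round((cu - u[1]) / du) + 1
    j0 <- round((cv - v[1]) / dv) + 1
    ii <- max(1, i0 - ri):min(length(u), i0 + ri)
    jj <- max(1, j0 - rj):min(length(v), j0 + rj)
    U <- matrix(u[ii] - cu, length(ii), length(jj))
    V <- matrix(v[jj] - cv, length(ii), length(jj), byrow = TRUE)
    w <- tmpl(U, V)
    ok <- valid[ii, jj] & is.finite(score[ii, jj])
    if (sum(ok & abs(w) > 0) < min_coverage * full) next
    ww <- w[ok]; dd2 <- score[ii, jj][ok]
    den <- sum(ok) * sum(ww^2) - sum(ww)^2
    if (den < 1e-9) next
    amp <- (sum(ok) * sum(dd2 * ww) - sum(ww) * sum(dd2)) / den
    if (amp > max_amp) next  # implausibly strong: an artifact, not the organ
    if (amp > best$score) best <- list(score = amp, center = c(cu, cv))
  }
  best
}

## projected chord of a sphere of radius r at in-plane distance d
sphere_chord <- function(d, r) 2 * sqrt(pmax(r^2 - d^2, 0))

disk_at <- function(center, radius, u, v) {
  sqrt(outer((u - center[1])^2, (v - center[2])^2, `+`)) <= radius
}

#' Segment landmark structures on a DRR
#'
#' Rule-based chain: the external contour is the largest connected
#' component above the air threshold. A per-row elliptical chord model of
#' the body gives a soft-tissue baseline; its residual exposes bone as
#' positive excess and the paired eyes as an attenuation deficit. The
#' cranial bone region (largest excess component), hole-filled and eroded by
#' the skull thickness, yields the brain; excess components below the brain,
#' in superior-to-inferior order, yield C1 and C2. The eyes are located by
#' fitting a disk-shaped deficit template in the anterior face (outside the
#' skull shadow) and each lens by a bright-core template at the anterior
#' pole of its eye. Masks are post-processed by 3 mm opening/closing and
#' clipped to the external contour.
#'
#' @param drr a numeric [bev_image()] from [render_drr()].
#' @param hints intensity bands from [segmentation_hints()].
#' @return A [structure_set_2d()] (provenance `"approach2"`) with all of
#'   `r paste(REQUIRED_STRUCTURES, collapse = ", ")`.
#' @section Failure: when any required structure cannot be located a
#'   condition of class `wbrt_segmentation_failure` is signalled carrying the
#'   missing names; the pipeline catches it and issues a flagged QA report.
#' @export
segment_drr <- function(drr, hints) {
  stopifnot(inherits(drr, "bev_image"))
  I <- drr$pixels
  u <- drr$u; v <- drr$v
  sp <- drr$spacing
  s <- drr$u_anterior
  morph_kern <- disk_kernel(hints$morph_radius, sp)
  post <- function(m) binary_morph(binary_morph(m, morph_kern,
                                                EBImage::opening),
                                   morph_kern, EBImage::closing)

  ## -- external ------------------------------------------------------------
  ## air rays are not exactly zero when the CT is noisy (negative HU clip
  ## to a positive floor), so estimate the air level from the image border:
  ## lateral (anterior/posterior) and superior edges only — the anatomy may
  ## legitimately extend through the inferior field-of-view edge
  frame <- c(I[c(1, 2, nrow(I) - 1, nrow(I)), ],
             I[, c(ncol(I) - 1, ncol(I))])
  air_level <- max(frame)
  body_raw <- I > air_level + hints$air_threshold
  if (!any(body_raw)) stop(segmentation_failure(REQUIRED_STRUCTURES))
  body <- fill_holes(largest_cc(body_raw))
  external <- post(body)
  if (!any(external)) stop(segmentation_failure(REQUIRED_STRUCTURES))

  ## -- residual over the elliptical-chord baseline -------------------------
  cm <- chord_baseline(I, body, u)
  resid <- I - cm$baseline
  resid[!body] <- 0
  bone_thr <- hints$bone_excess_per_mm * 4  # >= ~4 mm of bone on the ray
  interior <- binary_morph(body, disk_kernel(3, sp), EBImage::erode)
  ## bone of interest (skull, vertebral bodies) lies well inside the body
  ## outline where the chord model is reliable; the p-gate discards rim
  ## artifacts that could ring-connect around the neck
  bone <- resid > bone_thr & interior & cm$p > 0.4

  ## -- cranium / brain ------------------------------------------------------
  missing <- character(0)
  brain <- NULL
  skull_fill <- NULL
  cranium <- largest_cc(binary_morph(bone, disk_kernel(6, sp),
                                     EBImage::closing))
  if (!any(cranium)) {
    missing <- c(missing, "brain")
  } else {
    ## the calvarium is several times wider than the cervical column: cut
    ## the filled region below the first row (scanning down from the widest
    ## row) narrower than ~3 vertebra radii, then open to detach any
    ## remaining neck appendage the closing may have fused to the skull base
    skull_fill <- fill_holes(cranium)
    widths <- colSums(skull_fill) * sp[1]
    j_peak <- which.max(widths)
    narrow <- which(widths < 3 * hints$vertebra_radius & widths > 0)
    narrow <- narrow[narrow < j_peak]
    if (length(narrow)) skull_fill[, seq_len(max(narrow))] <- FALSE
    skull_fill <- binary_morph(skull_fill,
                               disk_kernel(hints$vertebra_radius + 4, sp),
                               EBImage::opening)
    brain <- binary_morph(skull_fill,
                          disk_kernel(hints$skull_thickness, sp),
                          EBImage::erode)
    brain <- post(brain) & external
    if (!any(brain)) missing <- c(missing, "brain")
  }

  ## -- vertebrae below the cranium -----------------------------------------
  c1 <- c2 <- NULL
  if (!("brain" %in% missing)) {
    brain_bottom <- bounding_box(brain, u, v)[["vmin"]]
    neck_bone <- bone & !skull_fill
    neck_bone[, v > brain_bottom] <- FALSE
    ## a vertebral body fills most of its rows with bone, while model
    ## artifacts (e.g. over head/neck junction rows) are narrow: split the
    ## column into bodies at rows whose bone width collapses, which also
    ## separates C1 from C2 across the disc space
    nrow_thr <- max(3, 0.45 * 2 * hints$vertebra_radius / sp[1])
    wide <- colSums(neck_bone) >= nrow_thr
    runs <- rle(wide)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    min_rows <- max(2, floor(0.4 * min(12, 18 / sp[2])))
    bodies <- which(runs$values & runs$lengths >= min_rows)
    bodies <- bodies[order(ends[bodies], decreasing = TRUE)]  # sup -> inf
    take_body <- function(k) {
      m <- neck_bone
      m[, -(starts[k]:ends[k])] <- FALSE
      post(m) & external
    }
    if (length(bodies) >= 1) c1 <- take_body(bodies[1])
    if (length(bodies) >= 2) c2 <- take_body(bodies[2])
    if (is.null(c1) || !any(c1)) missing <- c(missing, "C1")
    if (is.null(c2) || !any(c2)) missing <- c(missing, "C2")
  } else {
    missing <- c(missing, "C1", "C2")
  }

  ## -- eyes: disk-shaped deficit in the anterior face ----------------------
  eye <- lens <- NULL
  if (!("brain" %in% missing) &&
      hints$eye_deficit_per_mm > 0 && hints$lens_excess_per_mm > 0) {
    ## refit the soft-tissue baseline on the head-only rows without the
    ## bone/skull pixels, so the shell attenuation does not bias it
    bb <- bounding_box(brain, u, v)
    cm2 <- ellipsoid_baseline(I, body, u, v, v_min = bb[["vmin"]],
                              exclude = skull_fill | bone)
    soft_resid <- I - cm2$baseline
    soft_resid[!cm2$region] <- 0
    deficit <- -soft_resid
    ant_edge <- if (s > 0) bb[["umax"]] else bb[["umin"]]
    ## search centers: just anterior of the skull edge, lower cranium level
    cu <- u[(u - ant_edge) * s >= -0.5 * hints$eye_radius &
              (u - ant_edge) * s <= 1.5 * hints$eye_radius]
    ## the orbit floor sits above the skull base: the globe center cannot
    ## be below the brain's inferior edge plus one eye radius
    cv <- v[v >= bb[["vmin"]] + hints$eye_radius &
              v <= (bb[["vmin"]] + bb[["vmax"]]) / 2]
    ## fit only where the skull shadow does not corrupt the deficit and the
    ## chord model is reliable (away from the grazing body rim)
    valid <- interior & cm2$p > 0.2 & cm2$region &
      !binary_morph(skull_fill, disk_kernel(2, sp), EBImage::dilate)
    if (length(cu) && length(cv)) {
      re <- hints$eye_radius; rl <- hints$lens_radius
      lens_off <- s * (re - rl)  # lens sits at the eye's anterior pole
      ratio <- hints$lens_excess_per_mm / hints$eye_deficit_per_mm
      ## expected deficit pattern: eye chord minus the lens bright core
      eye_tmpl <- function(U, V)
        sphere_chord(sqrt(U^2 + V^2), re) -
          ratio * sphere_chord(sqrt((U - lens_off)^2 + V^2), rl)
      fit <- match_template(deficit, valid, u, v, cu, cv, re, eye_tmpl,
                            min_coverage = 0.45,
                            max_amp = 2.5 * hints$eye_deficit_per_mm)
      if (is.finite(fit$score) &&
          fit$score > 0.3 * hints$eye_deficit_per_mm) {
        ## sub-pixel refinement around the winning pixel-grid center
        ref <- match_template(deficit, valid, u, v,
                              seq(fit$center[1] - 2, fit$center[1] + 2, 0.5),
                              seq(fit$center[2] - 2, fit$center[2] + 2, 0.5),
                              re, eye_tmpl, min_coverage = 0.45,
                              max_amp = 2.5 * hints$eye_deficit_per_mm)
        if (is.finite(ref$score)) fit <- ref
        eye <- disk_at(fit$center, re, u, v) & external
        ## lens: bright core at the anterior pole. Remove the fitted eye
        ## deficit from the residual so the lens is an isolated bump, then
        ## match a pure lens-chord template around the expected pole.
        ecen <- fit$center
        lc0 <- ecen + c(lens_off, 0)
        De <- sqrt(outer((u - ecen[1])^2, (v - ecen[2])^2, `+`))
        lens_map <- soft_resid + fit$score * sphere_chord(De, re)
        lens_tmpl <- function(U, V) sphere_chord(sqrt(U^2 + V^2), rl)
        lfit <- match_template(lens_map, cm2$region, u, v,
                               seq(lc0[1] - 3, lc0[1] + 3, 0.5),
                               seq(lc0[2] - 3, lc0[2] + 3, 0.5),
                               rl + 2, lens_tmpl)
        lcen <- if (is.finite(lfit$score) &&
                    lfit$score > 0.2 * hints$lens_excess_per_mm)
          lfit$center else lc0
        lens <- disk_at(lcen, rl, u, v) & eye
      }
    }
  }
  if (is.null(eye) || !any(eye)) missing <- c(missing, "eye_L", "eye_R")
  if (is.null(lens) || !any(lens)) missing <- c(missing, "lens_L", "lens_R")

  if (length(missing)) stop(segmentation_failure(unique(missing)))

  geometry <- beam_geometry(gantry_deg = drr$gantry_deg, model = drr$model)
  structure_set_2d(
    list(external = external, brain = brain,
         eye_L = eye, eye_R = eye, lens_L = lens, lens_R = lens,
         C1 = c1, C2 = c2),
    u, v, geometry, provenance = "approach2")
}
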
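## Synthetic head phantom: parameterized CT volume plus ground-truth masks.
##
## Axis convention (DICOM-LPS-like, head-first supine):
##   x: patient right -> left, y: anterior -> posterior, z: inferior -> superior.
## World coordinates are in mm with the isocenter (= brain center) at the
## origin, so gantry 90/270 beams travel along +/- x.

#' Structure names every phantom (and imported case) must provide
#' @export
REQUIRED_STRUCTURES <- c("external", "brain", "eye_L", "eye_R",
                         "lens_L", "lens_R", "C1", "C2")

#' Phantom specification
#'
#' Parameterizes a synthetic head-and-neck CT: an ellipsoidal head with an
#' ellipsoidal brain inside a bony skull shell, two spherical eyes with
#' anterior lenses, a soft-tissue neck extension containing stacked C1/C2
#' vertebral-body cylinders, and an external skin surface. All lengths in mm,
#' HU values in Hounsfield units.
#'
#' @param head_semi_axes semi-axes (x, y, z) of the head ellipsoid.
#' @param brain_semi_axes semi-axes of the brain ellipsoid (centered at the
#'   isocenter; must fit strictly inside the head).
#' @param skull_thickness thickness of the bony shell wrapped around the brain.
#' @param eye_radius,lens_radius radii of the eye globes and lenses; each lens
#'   sits at the anterior pole of its eye.
#' @param eye_center_offsets list with `left`/`right` eye centers (mm triples,
#'   world coordinates).
#' @param vertebra_heights named pair `c(C1 = , C2 = )` of cylinder heights.
#' @param vertebra_radius radius of the vertebral-body cylinders.
#' @param vertebra_gap intervertebral disc space between C1 and C2.
#' @param c1_top_z superior extent of C1 (must be inferior to the brain).
#' @param neck_radius,neck_length radius and inferior extent of the neck
#'   cylinder appended below the cranium.
#' @param voxel_spacing grid spacing (mm triple).
#' @param hu_map named HU values; must cover `air`, `soft_tissue`, `bone`,
#'   `brain`, `eye`, `lens`.
#' @param noise_sd additive Gaussian CT noise (HU); 0 keeps geometry exact.
#' @param ct_supersample integer x-axis supersampling factor for the CT
#'   assembly: boundary voxels receive fractional (partial-volume) HU as in
#'   real CT, so ray integrals through the phantom are smooth rather than
#'   quantized to whole voxels. 1 disables partial volume. Masks are always
#'   binary at voxel centers.
#' @param head_tilt_deg anatomy rotation about the left-right (x) axis,
#'   positive pitches the chin up.
#' @param seed integer seed making the noise reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(head_semi_axes = c(75, 100, 85),
                         brain_semi_axes = c(60, 69, 58),
                         skull_thickness = 4,
                         eye_radius = 12,
                         lens_radius = 4,
                         eye_center_offsets = list(left  = c(26, -69, -40),
                                                   right = c(-26, -69, -40)),
                         vertebra_heights = c(C1 = 20, C2 = 20),
                         vertebra_radius = 14,
                         vertebra_gap = 4,
                         c1_top_z = -70,
                         neck_radius = 45,
                         neck_length = 85,
                         voxel_spacing = c(2, 2, 2),
                         hu_map = c(air = -1000, soft_tissue = 40, bone = 700,
                                    brain = 35, eye = 20, lens = 80),
                         noise_sd = 0,
                         head_tilt_deg = 0,
                         ct_supersample = 4L,
                         seed = 1L) {
  spec <- structure(
    list(head_semi_axes = as.numeric(head_semi_axes),
         brain_semi_axes = as.numeric(brain_semi_axes),
         skull_thickness = as.numeric(skull_thickness),
         eye_radius = as.numeric(eye_radius),
         lens_radius = as.numeric(lens_radius),
         eye_center_offsets = lapply(eye_center_offsets, as.numeric),
         vertebra_heights = c(C1 = unname(vertebra_heights[["C1"]]),
                              C2 = unname(vertebra_heights[["C2"]])),
         vertebra_radius = as.numeric(vertebra_radius),
         vertebra_gap = as.numeric(vertebra_gap),
         c1_top_z = as.numeric(c1_top_z),
         neck_radius = as.numeric(neck_radius),
         neck_length = as.numeric(neck_length),
         voxel_spacing = as.numeric(voxel_spacing),
         hu_map = hu_map,
         noise_sd = as.numeric(noise_sd),
         head_tilt_deg = as.numeric(head_tilt_deg),
         ct_supersample = as.integer(ct_supersample),
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  len_fields <- c("head_semi_axes", "brain_semi_axes", "skull_thickness",
                  "eye_radius", "lens_radius", "vertebra_heights",
                  "vertebra_radius", "vertebra_gap", "neck_radius",
                  "neck_length", "voxel_spacing")
  for (f in len_fields)
    check_that(all(is.finite(spec[[f]])) && all(spec[[f]] > 0), f,
               "all lengths must be finite and > 0")
  check_that(length(spec$head_semi_axes) == 3L, "head_semi_axes", "need 3 values")
  check_that(length(spec$brain_semi_axes) == 3L, "brain_semi_axes", "need 3 values")
  check_that(length(spec$voxel_spacing) == 3L, "voxel_spacing", "need 3 values")
  check_that(spec$lens_radius < spec$eye_radius, "lens_radius",
             "must be smaller than eye_radius")
  check_that(all(spec$brain_semi_axes + spec$skull_thickness <
                 spec$head_semi_axes),
             "brain_semi_axes",
             "brain plus skull shell must fit inside head_semi_axes")
  check_that(all(c("left", "right") %in% names(spec$eye_center_offsets)),
             "eye_center_offsets", "need `left` and `right` entries")
  for (side in c("left", "right"))
    check_that(length(spec$eye_center_offsets[[side]]) == 3L,
               "eye_center_offsets", "each offset must be a mm triple")
  check_that(all(c("C1", "C2") %in% names(spec$vertebra_heights)),
             "vertebra_heights", "need named C1 and C2 heights")
  needed_hu <- c("air", "soft_tissue", "bone", "brain", "eye", "lens")
  check_that(all(needed_hu %in% names(spec$hu_map)), "hu_map",
             paste("must name HU for", paste(needed_hu, collapse = ", ")))
  check_that(num1(spec$noise_sd) && spec$noise_sd >= 0, "noise_sd",
             "must be a single non-negative number")
  check_that(num1(spec$head_tilt_deg), "head_tilt_deg", "must be a number")
  check_that(length(spec$ct_supersample) == 1L && spec$ct_supersample >= 1,
             "ct_supersample", "must be a positive integer")
  check_that(spec$c1_top_z < -spec$brain_semi_axes[3], "c1_top_z",
             "C1 must start inferior to the brain")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  head %s mm, brain %s mm, skull %.1f mm\n",
              paste(x$head_semi_axes, collapse = "x"),
              paste(x$brain_semi_axes, collapse = "x"), x$skull_thickness))
  cat(sprintf("  eyes r=%.1f (lens r=%.1f); C1/C2 h=%s r=%.1f\n",
              x$eye_radius, x$lens_radius,
              paste(x$vertebra_heights, collapse = "/"), x$vertebra_radius))
  cat(sprintf("  spacing %s mm, noise %.1f HU, tilt %.1f deg, seed %d\n",
              paste(x$voxel_spacing, collapse = "x"), x$noise_sd,
              x$head_tilt_deg, x$seed))
  invisible(x)
}

## head ellipsoid center in world coordinates (brain center = origin)
.head_center <- c(0, 2, -8)

## 3D array [nx,ny,nz] from a [ny,nz] matrix replicated along x
rep_yz <- function(M, nx) {
  aperm(array(M, c(dim(M), nx)), c(3L, 1L, 2L))
}

## quadric helpers; YP/ZP are [ny,nz] matrices of (possibly tilted) y/z coords
ellipsoid_mask <- function(x, YP, ZP, center, semi) {
  qx <- ((x - center[1]) / semi[1])^2
  qyz <- ((YP - center[2]) / semi[2])^2 + ((ZP - center[3]) / semi[3])^2
  outer(qx, qyz, `+`) <= 1
}

sphere_mask <- function(x, YP, ZP, center, r) {
  ellipsoid_mask(x, YP, ZP, center, rep(r, 3))
}

## z-axis-aligned cylinder in the (tilted) anatomy frame
cylinder_mask <- function(x, YP, ZP, center_xy, radius, z_range, nx) {
  qx <- (x - center_xy[1])^2
  qy <- (YP - center_xy[2])^2
  radial <- outer(qx, qy, `+`) <= radius^2
  zok <- ZP >= z_range[1] & ZP <= z_range[2]
  radial & rep_yz(zok, nx)
}

#' Generate a synthetic head phantom
#'
#' Evaluates the implicit solids of a [phantom_spec()] on a regular voxel grid
#' and assembles a CT volume (innermost structure wins, Gaussian noise added
#' when `noise_sd > 0`) together with binary ground-truth masks for
#' `r paste(REQUIRED_STRUCTURES, collapse = ", ")`.
#'
#' Overlap between independently parameterized solids is resolved so the
#' emitted masks always satisfy the declared invariants: eyes are carved out
#' of the skull shell and brain, lenses are clipped to their eyes, and every
#' structure is clipped to the external surface.
#'
#' @param spec a [phantom_spec()].
#' @return A `structure_volume`: list with `ct` (3D HU array), `masks` (named
#'   list of logical arrays), `spacing`, `origin` (world mm of voxel
#'   `[1,1,1]`'s center), `axes` tag, and the generating `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  sp <- spec$voxel_spacing
  hc <- .head_center
  margin <- 6

  ## symmetric-in-x/y grids so opposed-beam views share a pixel lattice
  half_n <- function(extent, s) ceiling((extent + margin) / s)
  nxh <- half_n(spec$head_semi_axes[1] + abs(hc[1]), sp[1])
  nyh <- half_n(spec$head_semi_axes[2] + abs(hc[2]), sp[2])
  x <- (seq_len(2 * nxh) - nxh - 0.5) * sp[1]
  y <- (seq_len(2 * nyh) - nyh - 0.5) * sp[2]
  z_hi <- hc[3] + spec$head_semi_axes[3] + margin
  z_lo <- neck_top_z(spec) - spec$neck_length - margin
  nz <- ceiling((z_hi - z_lo) / sp[3])
  z <- z_lo + (seq_len(nz) - 0.5) * sp[3]

  ## tilt: rotate anatomy by +theta about x == evaluate solids at R^-1 p
  th <- spec$head_tilt_deg * pi / 180
  YZ <- expand_yz(y, z)
  YP <- cos(th) * YZ$Y + sin(th) * YZ$Z
  ZP <- -sin(th) * YZ$Y + cos(th) * YZ$Z

  solids <- phantom_solids(x, YP, ZP, spec, hc)

  ## CT with partial volume: solids re-evaluated on an x-supersampled grid
  ## so boundary voxels carry fractional occupancy, then averaged down
  S <- spec$ct_supersample
  if (S > 1) {
    xf <- as.vector(vapply(x, function(xc)
      xc + ((seq_len(S) - (S + 1) / 2) / S) * sp[1], numeric(S)))
    ctf <- assemble_ct(phantom_solids(xf, YP, ZP, spec, hc), spec$hu_map)
    dim(ctf) <- c(S, length(x), length(y), nz)
    ct <- colMeans(ctf, dims = 1)
  } else {
    ct <- assemble_ct(solids, spec$hu_map)
  }

  if (spec$noise_sd > 0) {
    ct <- ct + with_seed(spec$seed,
                         array(stats::rnorm(length(ct), 0, spec$noise_sd),
                               dim = dim(ct)))
  }

  masks <- list(external = solids$external, brain = solids$brain,
                eye_L = solids$eye_L, eye_R = solids$eye_R,
                lens_L = solids$lens_L, lens_R = solids$lens_R,
                C1 = solids$C1, C2 = solids$C2)
  empty <- names(masks)[!vapply(masks, any, logical(1))]
  if (length(empty))
    stop_field("spec", paste("generated empty mask(s):",
                             paste(empty, collapse = ", ")))

  structure(
    list(ct = ct, masks = masks, spacing = sp,
         origin = c(x[1], y[1], z[1]),
         axes = "x:R->L y:A->P z:I->S", spec = spec),
    class = "structure_volume")
}

## evaluate all phantom solids on an arbitrary x grid (shared y/z planes);
## overlap between independently parameterized solids is resolved here so
## the masks always satisfy the declared invariants
phantom_solids <- function(x, YP, ZP, spec, hc) {
  nx <- length(x)
  head <- ellipsoid_mask(x, YP, ZP, hc, spec$head_semi_axes)
  neck <- cylinder_mask(x, YP, ZP, c(0, hc[2] + 8), spec$neck_radius,
                        c(neck_top_z(spec) - spec$neck_length,
                          neck_top_z(spec)), nx)
  external <- head | neck

  brain <- ellipsoid_mask(x, YP, ZP, c(0, 0, 0), spec$brain_semi_axes)
  shell_outer <- ellipsoid_mask(x, YP, ZP, c(0, 0, 0),
                                spec$brain_semi_axes + spec$skull_thickness)
  out <- list(external = external,
              shell = shell_outer & !brain & external,
              brain = brain & external)
  for (side in c("left", "right")) {
    ec <- spec$eye_center_offsets[[side]]
    lc <- ec + c(0, -(spec$eye_radius - spec$lens_radius), 0)
    eye <- sphere_mask(x, YP, ZP, ec, spec$eye_radius)
    eye <- eye & !shell_outer & external
    lens <- sphere_mask(x, YP, ZP, lc, spec$lens_radius) & eye
    nm <- if (side == "left") "L" else "R"
    out[[paste0("eye_", nm)]] <- eye
    out[[paste0("lens_", nm)]] <- lens
  }
  h <- spec$vertebra_heights
  c1 <- cylinder_mask(x, YP, ZP, c(0, 18), spec$vertebra_radius,
                      c(spec$c1_top_z - h[["C1"]], spec$c1_top_z), nx)
  c2_top <- spec$c1_top_z - h[["C1"]] - spec$vertebra_gap
  c2 <- cylinder_mask(x, YP, ZP, c(0, 18), spec$vertebra_radius,
                      c(c2_top - h[["C2"]], c2_top), nx)
  out$C1 <- c1 & external
  out$C2 <- c2 & external
  out
}

## layered HU composition, innermost structure wins
assemble_ct <- function(solids, hu) {
  ct <- array(hu[["air"]], dim = dim(solids$external))
  ct[solids$external] <- hu[["soft_tissue"]]
  ct[solids$shell] <- hu[["bone"]]
  ct[solids$brain] <- hu[["brain"]]
  ct[solids$eye_L | solids$eye_R] <- hu[["eye"]]
  ct[solids$lens_L | solids$lens_R] <- hu[["lens"]]
  ct[solids$C1 | solids$C2] <- hu[["bone"]]
  ct
}

neck_top_z <- function(spec) .head_center[3] - 0.6 * spec$head_semi_axes[3]

expand_yz <- function(y, z) {
  list(Y = matrix(y, length(y), length(z)),
       Z = matrix(z, length(y), length(z), byrow = TRUE))
}

#' @export
print.structure_volume <- function(x, ...) {
  cat("<structure_volume>\n")
  cat(sprintf("  grid %s voxels @ %s mm, origin (%s) mm\n",
              paste(dim(x$ct), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              paste(sprintf("%.1f", x$origin), collapse = ", ")))
  cat(sprintf("  masks: %s\n", paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

## world-mm voxel-center coordinate vectors of a structure_volume
volume_axes <- function(vol) {
  d <- dim(vol$ct)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
}
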
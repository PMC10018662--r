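## Beam's-eye-view (BEV) frame
##
## For the lateral opposed WBRT fields the beam axis is the patient x axis.
## The BEV image is indexed (u, v) with v increasing toward superior for both
## gantry angles; u increases toward patient anterior at gantry 270 (left
## lateral, viewed from the source) and toward posterior at gantry 90, so the
## two views are exact u-mirrors of one another.

#' Beam geometry for BEV projection and DRR rendering
#'
#' @param gantry_deg gantry angle, 90 (right lateral) or 270 (left lateral).
#' @param model `"parallel"` (default) or `"divergent"` (point source at
#'   source-axis distance `sad`).
#' @param sad source-to-axis distance in mm (divergent model only).
#' @param pixel_spacing optional detector pixel spacing `c(du, dv)` mm; when
#'   `NULL` the BEV grid is inherited from the volume's y/z voxel lattice.
#' @param image_extent optional detector extent `c(eu, ev)` mm (centered on
#'   the isocenter axis); only used together with `pixel_spacing`.
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(gantry_deg = 270, model = c("parallel", "divergent"),
                          sad = 1000, pixel_spacing = NULL,
                          image_extent = NULL) {
  model <- match.arg(model)
  check_that(gantry_deg %in% c(90, 270), "gantry_deg", "must be 90 or 270")
  check_that(num1(sad) && sad > 0, "sad", "must be a positive number")
  if (!is.null(pixel_spacing))
    check_that(length(pixel_spacing) == 2 && all(pixel_spacing > 0),
               "pixel_spacing", "must be two positive numbers")
  if (!is.null(image_extent))
    check_that(length(image_extent) == 2 && all(image_extent > 0),
               "image_extent", "must be two positive numbers")
  structure(list(gantry_deg = gantry_deg, model = model, sad = sad,
                 pixel_spacing = pixel_spacing, image_extent = image_extent),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> gantry %d, %s%s\n", x$gantry_deg, x$model,
              if (x$model == "divergent") sprintf(" (SAD %.0f mm)", x$sad)
              else ""))
  invisible(x)
}

## u axis sign: +1 when u increases toward anterior (gantry 270)
u_anterior_sign <- function(gantry_deg) if (gantry_deg == 270) 1 else -1

## BEV pixel-center grid for a volume under a geometry.
## With inherited spacing and a y-grid symmetric about 0 the gantry 90 and
## 270 grids coincide, which makes the mirror property exact.
bev_grid_for <- function(vol, geometry) {
  ax <- volume_axes(vol)
  s <- u_anterior_sign(geometry$gantry_deg)
  if (is.null(geometry$pixel_spacing)) {
    u <- sort(-s * ax$y)  # u = -y at gantry 270, +y at gantry 90
    v <- ax$z
    spacing <- c(vol$spacing[2], vol$spacing[3])
  } else {
    spacing <- geometry$pixel_spacing
    ext <- geometry$image_extent %||%
      c(diff(range(ax$y)) + vol$spacing[2],
        diff(range(ax$z)) + vol$spacing[3])
    nu <- max(2L, ceiling(ext[1] / spacing[1]))
    nv <- max(2L, ceiling(ext[2] / spacing[2]))
    u <- (seq_len(nu) - (nu + 1) / 2) * spacing[1]
    v0 <- mean(range(ax$z))
    v <- v0 + (seq_len(nv) - (nv + 1) / 2) * spacing[2]
  }
  list(u = u, v = v, spacing = spacing)
}

#' BEV image container
#'
#' @param pixels numeric (DRR) or logical (mask) matrix indexed `[u, v]`.
#' @param u,v pixel-center coordinates in mm (ascending).
#' @param geometry the [beam_geometry()] the image was formed under.
#' @return An object of class `bev_image`.
#' @export
bev_image <- function(pixels, u, v, geometry) {
  stopifnot(nrow(pixels) == length(u), ncol(pixels) == length(v))
  if (is.numeric(pixels))
    check_that(all(is.finite(pixels)), "pixels", "must be finite")
  structure(list(pixels = pixels, u = u, v = v,
                 spacing = c(u[2] - u[1], v[2] - v[1]),
                 gantry_deg = geometry$gantry_deg,
                 u_anterior = u_anterior_sign(geometry$gantry_deg),
                 model = geometry$model),
            class = "bev_image")
}

#' @export
print.bev_image <- function(x, ...) {
  cat(sprintf("<bev_image> %dx%d px @ %.2fx%.2f mm, gantry %d (%s), u->%s\n",
              length(x$u), length(x$v), x$spacing[1], x$spacing[2],
              x$gantry_deg, x$model,
              if (x$u_anterior > 0) "anterior" else "posterior"))
  invisible(x)
}

## shared-grid check for 2D containers
same_bev_frame <- function(a, b, tol = 1e-9) {
  length(a$u) == length(b$u) && length(a$v) == length(b$v) &&
    max(abs(a$u - b$u)) < tol && max(abs(a$v - b$v)) < tol &&
    a$gantry_deg == b$gantry_deg
}

#' Named set of BEV structure masks on a shared grid
#'
#' @param masks named list of logical matrices (one per structure).
#' @param u,v pixel-center coordinates in mm.
#' @param geometry the [beam_geometry()] of the frame.
#' @param provenance `"approach1"` (3D mask projection) or `"approach2"`
#'   (DRR segmentation).
#' @return An object of class `structure_set_2d`.
#' @export
structure_set_2d <- function(masks, u, v, geometry,
                             provenance = c("approach1", "approach2")) {
  provenance <- match.arg(provenance)
  dims <- vapply(masks, dim, numeric(2))
  check_that(all(dims[1, ] == length(u)) && all(dims[2, ] == length(v)),
             "masks", "all masks must share the BEV grid")
  structure(list(masks = masks, u = u, v = v,
                 spacing = c(u[2] - u[1], v[2] - v[1]),
                 gantry_deg = geometry$gantry_deg,
                 u_anterior = u_anterior_sign(geometry$gantry_deg),
                 provenance = provenance),
            class = "structure_set_2d")
}

#' @export
print.structure_set_2d <- function(x, ...) {
  cat(sprintf("<structure_set_2d> [%s] %dx%d px, gantry %d: %s\n",
              x$provenance, length(x$u), length(x$v), x$gantry_deg,
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}
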
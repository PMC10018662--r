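## Quality-assurance comparison of two apertures: Hausdorff distance and
## mean surface distance on densified boundary point sets, optionally
## restricted to a clinical evaluation rectangle.

#' Clinical evaluation rectangle for aperture comparison
#'
#' The u-range runs from 5 mm behind the posterior edge of the vertebral
#' bodies (C1 and C2 together) to 20 mm in front of the forehead; the v-range
#' from the caudal landmark level (inferior edge of the configured vertebra)
#' to the cranial landmark level (skin top plus skin flash).
#'
#' @param structures a [structure_set_2d()] with `external` and vertebra masks.
#' @param config an [aperture_config()] supplying the skin flash and caudal
#'   vertebra choice.
#' @return An `evaluation_roi`: list with `u` and `v` ranges (mm).
#' @export
evaluation_roi <- function(structures, config = aperture_config()) {
  require_structures(structures, c("external", "C1", "C2"))
  u <- structures$u; v <- structures$v
  s <- structures$u_anterior
  dv <- structures$spacing[2]

  vert_union <- bounding_box(union_mask(structures, c("C1", "C2")), u, v)
  vert_cfg <- bounding_box(structures$masks[[config$caudal_vertebra]], u, v)
  eye_names <- intersect(c("eye_L", "eye_R"), names(structures$masks))
  v_ref <- if (length(eye_names) &&
               any(vapply(structures$masks[eye_names], any, logical(1)))) {
    bounding_box(union_mask(structures, eye_names), u, v)[["vmax"]]
  } else {
    vert_union[["vmax"]]  # forehead fallback: rows above the vertebrae
  }
  rows_up <- v >= v_ref - dv / 2 - 1e-9
  skin_box <- bounding_box(structures$masks$external[, rows_up, drop = FALSE],
                           u, v[rows_up])

  u_post <- box_post(vert_union, s) - s * 5
  u_ant <- box_ant(skin_box, s) + s * 20
  u_range <- sort(c(u_post, u_ant))
  if (diff(u_range) <= 0 || (u_ant - u_post) * s <= 0)
    stop("empty ROI: vertebra posterior edge is anterior to the forehead")
  v_range <- c(vert_cfg[["vmin"]], skin_box[["vmax"]] + config$skin_flash)
  if (diff(v_range) <= 0) stop("empty ROI: degenerate v-range")
  structure(list(u = u_range, v = v_range), class = "evaluation_roi")
}

#' @export
print.evaluation_roi <- function(x, ...) {
  cat(sprintf("<evaluation_roi> u [%.1f, %.1f] mm, v [%.1f, %.1f] mm\n",
              x$u[1], x$u[2], x$v[1], x$v[2]))
  invisible(x)
}

## densified boundary point set of a polygon, clipped to an optional ROI
boundary_points <- function(x, roi = NULL, max_step = 0.5) {
  p <- if (inherits(x, "aperture_polygon")) x$vertices else as.matrix(x)
  pts <- densify_polygon(p, max_step = max_step, closed = TRUE)
  if (!is.null(roi)) {
    keep <- pts[, 1] >= roi$u[1] & pts[, 1] <= roi$u[2] &
      pts[, 2] >= roi$v[1] & pts[, 2] <= roi$v[2]
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) == 0)
      stop("ROI clipping removed the entire boundary")
  }
  pts
}

## pairwise distance matrix between two point sets (rows a, cols b)
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 1e-9] <- 0  # sub-nanometer: rounding of coincident points
  sqrt(d2)
}

surface_distances <- function(poly_a, poly_b, roi = NULL, max_step = 0.5) {
  a <- boundary_points(poly_a, roi, max_step)
  b <- boundary_points(poly_b, roi, max_step)
  D <- cross_dist(a, b)
  ab <- apply(D, 1, min)  # nearest b for each a
  ba <- apply(D, 2, min)
  list(hd = max(max(ab), max(ba)), msd = (mean(ab) + mean(ba)) / 2)
}

#' Hausdorff distance between two aperture boundaries
#'
#' Boundaries are densified to <= 0.5 mm vertex spacing, optionally clipped
#' to the ROI, and compared as point sets: the maximum of the two directed
#' maximal nearest-neighbor distances.
#'
#' @param poly_a,poly_b `aperture_polygon`s or n x 2 vertex matrices.
#' @param roi optional [evaluation_roi()].
#' @param max_step densification spacing in mm.
#' @return Distance in mm.
#' @export
hausdorff <- function(poly_a, poly_b, roi = NULL, max_step = 0.5) {
  surface_distances(poly_a, poly_b, roi, max_step)$hd
}

#' Mean surface distance between two aperture boundaries
#'
#' Average of the two directed mean nearest-neighbor distances on the
#' densified (and optionally ROI-clipped) boundary point sets.
#'
#' @inheritParams hausdorff
#' @return Distance in mm.
#' @export
mean_surface_distance <- function(poly_a, poly_b, roi = NULL,
                                  max_step = 0.5) {
  surface_distances(poly_a, poly_b, roi, max_step)$msd
}

#' Compare two apertures and issue a QA verdict
#'
#' The two-approach cross-check: the aperture from projected 3D contours
#' (approach 1) and the aperture from DRR-segmented contours (approach 2)
#' should nearly coincide; large HD/MSD flags a potential failure of either
#' approach.
#'
#' @param ap1,ap2 `aperture_polygon`s in the same BEV frame.
#' @param roi optional [evaluation_roi()] restricting the comparison.
#' @param thresholds named numeric `c(hd_mm = , msd_mm = )`; the verdict is
#'   `"pass"` iff both metrics are within their thresholds.
#' @param reason optional free-text reason recorded in the report (used by
#'   the pipeline when segmentation fails outright).
#' @return A `qa_report`: list with `hd`, `msd` (mm), `roi`, `thresholds`,
#'   `verdict` (`"pass"`/`"flag"`), `reason`, and both provenances.
#' @export
compare_approaches <- function(ap1, ap2, roi = NULL,
                               thresholds = c(hd_mm = 10, msd_mm = 5),
                               reason = NULL) {
  g1 <- ap1$gantry_deg %||% NA
  g2 <- ap2$gantry_deg %||% NA
  if (!is.na(g1) && !is.na(g2) && g1 != g2)
    stop("apertures are in different BEV frames (gantry ", g1, " vs ", g2, ")")
  sd <- surface_distances(ap1, ap2, roi)
  ok <- sd$hd <= thresholds[["hd_mm"]] && sd$msd <= thresholds[["msd_mm"]]
  structure(list(hd = sd$hd, msd = sd$msd, roi = roi,
                 thresholds = thresholds,
                 verdict = if (ok) "pass" else "flag",
                 reason = reason,
                 provenance = c(ap1$provenance %||% "unknown",
                                ap2$provenance %||% "unknown")),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %s vs %s: HD %.2f mm, MSD %.2f mm -> %s\n",
              x$provenance[1], x$provenance[2], x$hd, x$msd,
              toupper(x$verdict)))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}
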
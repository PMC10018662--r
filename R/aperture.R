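## Customizable landmark-based field aperture design.
##
## Nine landmarks (A-I) derived from BEV structure bounding boxes form the
## aperture boundary: HI cranial, FG caudal, AI/EF anterior, GH posterior,
## and AB/BC/CD/DE the anterior-caudal cut shielding the eyes and lenses.

#' Aperture design configuration
#'
#' The eight user-facing options shaping the nine landmarks. Defaults follow
#' the initial configuration preferred in multi-institutional physician
#' review: diagonal AB, BC midway between the posterior edges of the lens
#' and eye boxes, CD/DE following the brain expansion, 15 mm brain margin,
#' 15 mm skin flash, caudal border at C1, orbits excluded.
#'
#' @param ab_shape `"diagonal"` or `"horizontal"` AB segment.
#' @param ab_diagonal_rise vertical rise (mm) of A above B when diagonal.
#' @param bc_position `"mid"`, `"lens"`, or `"eye"`: u of the BC line at the
#'   posterior edge of the lens box, the eye box, or their midpoint.
#' @param ce_shape `"follow_expansion"` (trace the expanded-brain boundary
#'   from C to E) or `"straight"` (chord).
#' @param brain_margin morphological brain expansion (mm, 0-30).
#' @param skin_flash field extension beyond the skin surface (mm, 0-30).
#' @param caudal_vertebra `"C1"` or `"C2"`: vertebral body whose inferior
#'   edge sets the caudal border.
#' @param include_orbits if `TRUE` the anterior-caudal cut is dropped and the
#'   anterior border is a single vertical line flashing the whole face.
#' @param vertebra_anterior_margin anterior offset (mm) of E/F from the
#'   vertebra box.
#' @return An object of class `aperture_config`.
#' @export
aperture_config <- function(ab_shape = c("diagonal", "horizontal"),
                            ab_diagonal_rise = 10,
                            bc_position = c("mid", "lens", "eye"),
                            ce_shape = c("follow_expansion", "straight"),
                            brain_margin = 15,
                            skin_flash = 15,
                            caudal_vertebra = c("C1", "C2"),
                            include_orbits = FALSE,
                            vertebra_anterior_margin = 5) {
  cfg <- structure(list(
    ab_shape = match.arg(ab_shape),
    ab_diagonal_rise = as.numeric(ab_diagonal_rise),
    bc_position = match.arg(bc_position),
    ce_shape = match.arg(ce_shape),
    brain_margin = as.numeric(brain_margin),
    skin_flash = as.numeric(skin_flash),
    caudal_vertebra = match.arg(caudal_vertebra),
    include_orbits = isTRUE(include_orbits),
    vertebra_anterior_margin = as.numeric(vertebra_anterior_margin)),
    class = "aperture_config")
  check_that(num1(cfg$brain_margin) && cfg$brain_margin >= 0 &&
               cfg$brain_margin <= 30, "brain_margin", "must be in [0, 30] mm")
  check_that(num1(cfg$skin_flash) && cfg$skin_flash >= 0 &&
               cfg$skin_flash <= 30, "skin_flash", "must be in [0, 30] mm")
  check_that(num1(cfg$ab_diagonal_rise) && cfg$ab_diagonal_rise >= 0,
             "ab_diagonal_rise", "must be >= 0")
  check_that(num1(cfg$vertebra_anterior_margin) &&
               cfg$vertebra_anterior_margin >= 0,
             "vertebra_anterior_margin", "must be >= 0")
  cfg
}

#' @export
print.aperture_config <- function(x, ...) {
  cat("<aperture_config>\n")
  cat(sprintf("  AB %s (rise %.0f mm), BC at %s, CE %s\n", x$ab_shape,
              x$ab_diagonal_rise, x$bc_position, x$ce_shape))
  cat(sprintf("  brain margin %.0f mm, skin flash %.0f mm, caudal %s,%s orbits\n",
              x$brain_margin, x$skin_flash, x$caudal_vertebra,
              if (x$include_orbits) " include" else " exclude"))
  invisible(x)
}

#' Tight bounding box of a BEV mask
#'
#' Edges sit at the outer pixel borders of the on-pixels.
#'
#' @param mask logical matrix `[u, v]` or logical [bev_image()].
#' @param u,v pixel-center coordinates (taken from `mask` when a `bev_image`).
#' @return Named numeric `c(umin, umax, vmin, vmax)` in mm.
#' @export
bounding_box <- function(mask, u = NULL, v = NULL) {
  if (inherits(mask, "bev_image")) {
    u <- mask$u; v <- mask$v; mask <- mask$pixels
  }
  if (!any(mask)) stop("bounding_box: mask is empty")
  du <- u[2] - u[1]; dv <- v[2] - v[1]
  ui <- range(which(rowSums(mask) > 0))
  vi <- range(which(colSums(mask) > 0))
  c(umin = u[ui[1]] - du / 2, umax = u[ui[2]] + du / 2,
    vmin = v[vi[1]] - dv / 2, vmax = v[vi[2]] + dv / 2)
}

## elliptical structuring element covering a disk of `margin` mm
disk_kernel <- function(margin, spacing) {
  ru <- round(margin / spacing[1])
  rv <- round(margin / spacing[2])
  if (ru == 0 && rv == 0) return(matrix(1, 1, 1))
  di <- seq(-ru, ru); dj <- seq(-rv, rv)
  k <- outer((di / max(ru, 1e-9))^2, (dj / max(rv, 1e-9))^2, `+`) <= 1 + 1e-9
  k + 0
}

binary_morph <- function(mask, kern, op) {
  if (nrow(kern) == 1 && ncol(kern) == 1) return(mask)
  res <- op(mask + 0, kern)
  matrix(as.numeric(res) > 0.5, nrow(mask), ncol(mask))
}

#' Morphological brain expansion on the BEV
#'
#' Dilates the brain mask with a disk structuring element of the given
#' radius (mm, converted to pixels by rounding to nearest).
#'
#' @param mask logical matrix `[u, v]` or logical [bev_image()].
#' @param margin dilation radius in mm (>= 0; 0 is the identity).
#' @param u,v pixel-center coordinates when `mask` is a plain matrix.
#' @return List with `mask` (dilated logical matrix), `boundary` (polylines
#'   from [mask_to_polyline()]), and `u`, `v`.
#' @export
expand_brain <- function(mask, margin, u = NULL, v = NULL) {
  if (inherits(mask, "bev_image")) {
    u <- mask$u; v <- mask$v; mask <- mask$pixels
  }
  check_that(num1(margin) && margin >= 0, "margin", "must be >= 0")
  spacing <- c(u[2] - u[1], v[2] - v[1])
  out <- binary_morph(mask, disk_kernel(margin, spacing), EBImage::dilate)
  list(mask = out, boundary = mask_to_polyline(out, u, v), u = u, v = v)
}

## anterior/posterior box edges respecting the frame's u direction
box_ant <- function(box, s) if (s > 0) box[["umax"]] else box[["umin"]]
box_post <- function(box, s) if (s > 0) box[["umin"]] else box[["umax"]]

union_mask <- function(structures, names) {
  Reduce(`|`, structures$masks[names])
}

require_structures <- function(structures, needed) {
  missing <- setdiff(needed, names(structures$masks))
  if (length(missing))
    stop("missing structure(s): ", paste(missing, collapse = ", "))
  empty <- needed[!vapply(structures$masks[needed], any, logical(1))]
  if (length(empty))
    stop("empty structure mask(s): ", paste(empty, collapse = ", "))
  invisible(TRUE)
}

#' Compute the nine aperture landmarks A-I
#'
#' Applies the landmark rules to the BEV structure set: skin/forehead, eye,
#' lens, and vertebra bounding boxes plus the expanded-brain (EB) boundary
#' position the points; see the package vignette for the full construction.
#'
#' @param structures a [structure_set_2d()] containing `external`, `brain`,
#'   both eyes, both lenses, and the configured vertebra.
#' @param config an [aperture_config()].
#' @return A `landmark_set`: 9 x 2 matrix (rows A-I, columns u, v) carrying
#'   the EB boundary, the C-E arc, and the config as attributes.
#' @export
compute_landmarks <- function(structures, config = aperture_config()) {
  vert <- config$caudal_vertebra
  require_structures(structures,
                     c("external", "brain", "eye_L", "eye_R",
                       "lens_L", "lens_R", vert))
  u <- structures$u; v <- structures$v
  s <- structures$u_anterior
  dv <- structures$spacing[2]
  flash <- config$skin_flash

  eye_box <- bounding_box(union_mask(structures, c("eye_L", "eye_R")), u, v)
  lens_box <- bounding_box(union_mask(structures, c("lens_L", "lens_R")), u, v)
  vert_box <- bounding_box(structures$masks[[vert]], u, v)

  ## forehead: skin restricted to rows at/above the eye-box top, so the
  ## nose/face below the eyes never drives the AI line
  rows_up <- v >= eye_box[["vmax"]] - dv / 2 - 1e-9
  skin_up <- structures$masks$external[, rows_up, drop = FALSE]
  skin_box <- bounding_box(skin_up, u, v[rows_up])
  face_box <- bounding_box(structures$masks$external, u, v)

  eb <- expand_brain(structures$masks$brain, config$brain_margin, u, v)
  eb_poly <- eb$boundary[[which.max(vapply(eb$boundary, function(p)
    polygon_area(p$vertices), numeric(1)))]]$vertices

  v_HI <- skin_box[["vmax"]] + flash
  u_GH <- box_post(skin_box, s) - s * flash
  u_IA <- box_ant(skin_box, s) + s * flash
  v_FG <- vert_box[["vmin"]]

  if (config$include_orbits) {
    u_anchor <- box_ant(face_box, s) + s * flash
    v_B <- eye_box[["vmax"]]
    lm <- rbind(A = c(u_anchor, v_B), B = c(u_anchor, v_B),
                C = c(u_anchor, v_B), D = c(u_anchor, v_B),
                E = c(u_anchor, v_FG), F = c(u_anchor, v_FG),
                G = c(u_GH, v_FG), H = c(u_GH, v_HI), I = c(u_anchor, v_HI))
    arc <- lm[c("C", "E"), , drop = FALSE]
  } else {
    u_B <- switch(config$bc_position,
                  lens = box_post(lens_box, s),
                  eye = box_post(eye_box, s),
                  mid = (box_post(lens_box, s) + box_post(eye_box, s)) / 2)
    v_B <- eye_box[["vmax"]]
    A <- if (config$ab_shape == "horizontal") c(u_IA, v_B)
         else c(u_IA, v_B + config$ab_diagonal_rise)
    ## C: first hit of the downward vertical ray from B on the EB boundary
    hits <- polyline_vertical_intersections(eb_poly, u_B)
    hits <- hits[hits <= v_B + 1e-9]
    if (!length(hits)) stop("landmark C undefined: ",
                            "vertical ray from B misses the brain expansion")
    C <- c(u_B, max(hits))
    u_E <- box_ant(vert_box, s) + s * config$vertebra_anterior_margin
    e_hits <- polyline_vertical_intersections(eb_poly, u_E)
    fell_back <- !length(e_hits)
    v_E <- if (fell_back) C[2] else min(e_hits)
    E <- c(u_E, v_E)
    straight <- config$ce_shape == "straight" || fell_back
    arc <- eb_arc_between(eb_poly, C, E, straight = straight)
    ## D: straight chord -> the C-E midpoint; expansion-following -> the
    ## lowest point of the arc (ties resolved toward C, the walk start)
    D <- if (straight) (C + E) / 2 else arc[which.min(arc[, 2])[1], ]
    lm <- rbind(A = A, B = c(u_B, v_B), C = C, D = D, E = E,
                F = c(u_E, v_FG), G = c(u_GH, v_FG), H = c(u_GH, v_HI),
                I = c(u_IA, v_HI))
  }
  colnames(lm) <- c("u", "v")
  structure(lm, class = c("landmark_set", class(lm)),
            config = config, arc = arc, eb_boundary = eb_poly,
            gantry_deg = structures$gantry_deg,
            u_anterior = s, spacing = structures$spacing)
}

## path along the EB boundary from C to E avoiding the cranial top: of the
## two ways around the closed polyline, keep the one with the lower maximum v
eb_arc_between <- function(poly, C, E, straight = FALSE) {
  if (straight) {
    mid <- (C + E) / 2
    return(rbind(C, mid, E))
  }
  n <- nrow(poly)
  posC <- insert_point_position(poly, C)
  posE <- insert_point_position(poly, E)
  path <- function(dir) {
    vpos <- seq_len(n) - 1          # cyclic position of each vertex
    span <- if (dir > 0) (posE - posC) %% n else (posC - posE) %% n
    ds <- if (dir > 0) (vpos - posC) %% n else (posC - vpos) %% n
    keep <- which(ds > 1e-9 & ds < span - 1e-9)
    keep <- keep[order(ds[keep])]
    rbind(C, poly[keep, , drop = FALSE], E)
  }
  fw <- path(+1)
  bw <- path(-1)
  arc <- if (max(fw[, 2]) <= max(bw[, 2])) fw else bw
  dedupe_vertices_open(arc)
}

## dedupe for open polylines (keeps both endpoints)
dedupe_vertices_open <- function(p, tol = 1e-9) {
  n <- nrow(p)
  if (n < 2) return(p)
  keep <- c(TRUE, rowSums(abs(p[-1, , drop = FALSE] -
                              p[-n, , drop = FALSE])) > tol)
  p[keep, , drop = FALSE]
}

## fractional position (edge index - 1 + t) of a point lying on the polyline
insert_point_position <- function(poly, p) {
  n <- nrow(poly)
  i2 <- c(2:n, 1)
  best <- c(pos = 0, d = Inf)
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[i2[e], ]
    ab <- b - a
    L2 <- sum(ab^2)
    t <- if (L2 < 1e-300) 0 else sum((p - a) * ab) / L2
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d <- sum((p - q)^2)
    if (d < best["d"]) best <- c(pos = e - 1 + t, d = d)
  }
  best[["pos"]]
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> (u, v) mm\n")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(round(m, 2))
  invisible(x)
}
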
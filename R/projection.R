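## Structure projection and DRR rendering into the beam's-eye-view.

## minimal volume-like wrapper so plain arrays reuse the grid helpers
vol_like <- function(arr, spacing, origin) {
  list(ct = arr, spacing = as.numeric(spacing), origin = as.numeric(origin))
}

## nearest-voxel index of world coordinates along one axis; NA out of range
axis_index <- function(w, origin, spacing, n) {
  j <- as.integer(round((w - origin) / spacing)) + 1L
  j[j < 1L | j > n] <- NA_integer_
  j
}

## parallel-beam lookup of a per-(y,z)-column reduction M onto the BEV grid
parallel_lookup <- function(M, grid, geometry, vol, fill) {
  s <- u_anterior_sign(geometry$gantry_deg)
  yw <- -s * grid$u
  d <- dim(M)
  j <- axis_index(yw, vol$origin[2], vol$spacing[2], d[1])
  k <- axis_index(grid$v, vol$origin[3], vol$spacing[3], d[2])
  out <- matrix(fill, length(grid$u), length(grid$v))
  ju <- which(!is.na(j)); kv <- which(!is.na(k))
  if (length(ju) && length(kv)) out[ju, kv] <- M[j[ju], k[kv]]
  out
}

## divergent (fan) accumulation: march along x through the volume, scaling
## the in-plane coordinates toward the point source at x = source_x
divergent_accumulate <- function(arr, grid, geometry, vol, reduce) {
  s <- u_anterior_sign(geometry$gantry_deg)
  source_x <- if (geometry$gantry_deg == 270) geometry$sad else -geometry$sad
  d <- dim(arr)
  ax_x <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  X <- max(abs(range(ax_x))) + vol$spacing[1]
  step <- min(vol$spacing) / 2
  ns <- ceiling(X / step)
  xs <- seq(-ns, ns) * step  # symmetric about the isocenter plane
  yw0 <- -s * grid$u
  zw0 <- grid$v
  logical_mode <- identical(reduce, "any")
  acc <- matrix(if (logical_mode) FALSE else 0,
                length(grid$u), length(grid$v))
  for (x in xs) {
    i <- axis_index(x, vol$origin[1], vol$spacing[1], d[1])
    if (is.na(i)) next
    scale <- 1 - x / source_x
    j <- axis_index(yw0 * scale, vol$origin[2], vol$spacing[2], d[2])
    k <- axis_index(zw0 * scale, vol$origin[3], vol$spacing[3], d[3])
    ju <- which(!is.na(j)); kv <- which(!is.na(k))
    if (!length(ju) || !length(kv)) next
    slab <- arr[i, , ][cbind(rep(j[ju], length(kv)),
                             rep(k[kv], each = length(ju)))]
    slab <- matrix(slab, length(ju), length(kv))
    if (logical_mode) acc[ju, kv] <- acc[ju, kv] | slab
    else acc[ju, kv] <- acc[ju, kv] + slab
  }
  if (!logical_mode) {
    ## oblique path length per unit x-step
    obliq <- sqrt(1 + outer((yw0 / source_x)^2, (zw0 / source_x)^2, `+`))
    acc <- acc * step * obliq
  }
  acc
}

#' Project a 3D binary mask into the beam's-eye-view
#'
#' Parallel model: a BEV pixel is on iff any voxel along the x ray through
#' its center is on. Divergent model: fan rays from a point source at the
#' configured SAD. At gantry 90 the output is the exact u-mirror of the
#' gantry 270 projection (parallel model).
#'
#' @param mask 3D logical (or 0/1) array over the volume grid.
#' @param geometry a [beam_geometry()].
#' @param spacing,origin voxel spacing and world origin (mm) of `mask`.
#' @return A logical-[bev_image()].
#' @export
project_mask_bev <- function(mask, geometry, spacing, origin) {
  vol <- vol_like(mask, spacing, origin)
  grid <- bev_grid_for(vol, geometry)
  if (!any(mask)) {
    warning("empty mask projects to an empty BEV mask")
    return(bev_image(matrix(FALSE, length(grid$u), length(grid$v)),
                     grid$u, grid$v, geometry))
  }
  px <- if (geometry$model == "parallel") {
    d <- dim(mask)
    M <- matrix(colSums(matrix(mask, d[1], d[2] * d[3])) > 0, d[2], d[3])
    parallel_lookup(M, grid, geometry, vol, FALSE)
  } else {
    divergent_accumulate(mask, grid, geometry, vol, "any")
  }
  bev_image(px, grid$u, grid$v, geometry)
}

#' Render a digitally reconstructed radiograph
#'
#' Pixel value is the line integral of `max(HU + 1000, 0)` (a water-equivalent
#' attenuation proxy) times path length along the ray, in HU.mm. Linear in
#' the input under the parallel model.
#'
#' @param ct a `structure_volume` or a 3D HU array.
#' @param geometry a [beam_geometry()].
#' @param spacing,origin required when `ct` is a plain array.
#' @return A numeric [bev_image()].
#' @export
render_drr <- function(ct, geometry, spacing = NULL, origin = NULL) {
  vol <- if (inherits(ct, "structure_volume")) ct
         else vol_like(ct, spacing, origin)
  grid <- bev_grid_for(vol, geometry)
  mu <- pmax(vol$ct + 1000, 0)
  px <- if (geometry$model == "parallel") {
    d <- dim(mu)
    M <- matrix(colSums(matrix(mu, d[1], d[2] * d[3])), d[2], d[3]) *
      vol$spacing[1]
    parallel_lookup(M, grid, geometry, vol, 0)
  } else {
    divergent_accumulate(mu, grid, geometry, vol, "sum")
  }
  bev_image(px, grid$u, grid$v, geometry)
}

#' Project all masks of a volume into a BEV structure set
#'
#' Approach 1's structure source: every ground-truth 3D mask is projected on
#' a shared BEV grid.
#'
#' @param vol a `structure_volume`.
#' @param geometry a [beam_geometry()].
#' @return A [structure_set_2d()] with provenance `"approach1"`.
#' @export
project_structures <- function(vol, geometry) {
  masks <- lapply(vol$masks, function(m)
    project_mask_bev(m, geometry, vol$spacing, vol$origin)$pixels)
  grid <- bev_grid_for(vol, geometry)
  structure_set_2d(masks, grid$u, grid$v, geometry, "approach1")
}

#' Extract sub-pixel boundary polylines of a BEV mask
#'
#' Iso-contours the 0/1 pixel field at level 0.5 with bilinear interpolation
#' (marching squares as implemented by [grDevices::contourLines()]); each
#' connected component yields one closed, counter-clockwise polyline in mm.
#' The grid is zero-padded first so contours always close, and saddle
#' ambiguities are resolved toward the foreground by nudging the level just
#' below 0.5.
#'
#' @param mask logical matrix `[u, v]`, a logical [bev_image()], or 0/1 matrix.
#' @param u,v pixel-center coordinates (ignored when `mask` is a `bev_image`).
#' @return List of polylines: each `list(vertices = <n x 2 matrix (u, v)>,
#'   closed = TRUE)`.
#' @export
mask_to_polyline <- function(mask, u = NULL, v = NULL) {
  if (inherits(mask, "bev_image")) {
    u <- mask$u; v <- mask$v; mask <- mask$pixels
  }
  if (!any(mask)) stop("cannot extract a boundary from an empty mask")
  du <- u[2] - u[1]; dv <- v[2] - v[1]
  up <- c(u[1] - du, u, u[length(u)] + du)
  vp <- c(v[1] - dv, v, v[length(v)] + dv)
  zp <- matrix(0, length(up), length(vp))
  zp[2:(length(u) + 1), 2:(length(v) + 1)] <- mask + 0
  cl <- grDevices::contourLines(up, vp, zp, levels = 0.5 - 1e-9)
  lapply(cl, function(li) {
    pts <- cbind(u = li$x, v = li$y)
    n <- nrow(pts)
    if (n > 1 && all(abs(pts[1, ] - pts[n, ]) < 1e-12))
      pts <- pts[-n, , drop = FALSE]
    if (polygon_signed_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
    list(vertices = pts, closed = TRUE)
  })
}
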
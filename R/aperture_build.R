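## Assembly of the closed aperture polygon from the landmark set, the
## opposed-field mirror, and multileaf-collimator leaf fitting.

#' Assemble the closed field-aperture polygon
#'
#' Traverses I -> A -> B -> C -> (C..D..E stretch) -> F -> G -> H and closes
#' back to I. When `ce_shape = "follow_expansion"` the C..E stretch is the
#' sampled expanded-brain boundary arc (vertex spacing <= 2 mm); otherwise it
#' is the C-D-E chord. Collinear vertices are merged (0.1 mm tolerance) and
#' the result is checked to be simple with positive area.
#'
#' @param landmarks a `landmark_set` from [compute_landmarks()].
#' @param config the [aperture_config()] used; defaults to the one stored in
#'   `landmarks`.
#' @param provenance `"approach1"` or `"approach2"` tag carried by the result.
#' @return An `aperture_polygon`: list with `vertices` (n x 2, mm, closed
#'   implicitly, counter-clockwise), `landmarks`, `config`, `gantry_deg`,
#'   `u_anterior`, `provenance`.
#' @export
build_aperture <- function(landmarks, config = NULL,
                           provenance = c("approach1", "approach2")) {
  provenance <- match.arg(provenance)
  config <- config %||% attr(landmarks, "config")
  lm <- unclass(landmarks)
  arc <- attr(landmarks, "arc")
  if (identical(config$ce_shape, "follow_expansion") && nrow(arc) > 2)
    arc <- densify_polygon(arc, max_step = 2, closed = FALSE)
  verts <- rbind(lm["I", ], lm["A", ], lm["B", ], arc,
                 lm["F", ], lm["G", ], lm["H", ])
  verts <- simplify_polygon(verts, tol = 0.1)
  if (polygon_signed_area(verts) < 0)
    verts <- verts[nrow(verts):1, , drop = FALSE]
  if (!polygon_is_simple(verts))
    stop("aperture polygon is self-intersecting; landmarks are inconsistent")
  if (polygon_area(verts) <= 0) stop("aperture polygon has zero area")
  colnames(verts) <- c("u", "v")
  rownames(verts) <- NULL
  structure(list(vertices = verts, landmarks = lm, config = config,
                 gantry_deg = attr(landmarks, "gantry_deg"),
                 u_anterior = attr(landmarks, "u_anterior"),
                 provenance = provenance),
            class = "aperture_polygon")
}

#' @export
print.aperture_polygon <- function(x, ...) {
  cat(sprintf("<aperture_polygon> [%s] gantry %s: %d vertices, %.1f cm^2\n",
              x$provenance, x$gantry_deg %||% "?", nrow(x$vertices),
              polygon_area(x$vertices) / 100))
  invisible(x)
}

#' Mirror an aperture for the opposed lateral field
#'
#' Reflects the polygon about the isocenter axis (u = 0) and swaps the gantry
#' tag 90 <-> 270. Applying the mirror twice is the identity.
#'
#' @param aperture an `aperture_polygon`.
#' @return The mirrored `aperture_polygon`.
#' @export
mirror_aperture <- function(aperture) {
  v <- aperture$vertices
  v[, 1] <- -v[, 1]
  v <- v[nrow(v):1, , drop = FALSE]  # keep counter-clockwise orientation
  lm <- aperture$landmarks
  if (!is.null(lm)) lm[, 1] <- -lm[, 1]
  out <- aperture
  out$vertices <- v
  out$landmarks <- lm
  if (!is.null(aperture$gantry_deg))
    out$gantry_deg <- if (aperture$gantry_deg == 270) 90 else 270
  out$u_anterior <- -(aperture$u_anterior %||% 1)
  out
}

#' Fit multileaf-collimator leaves to an aperture
#'
#' Leaves travel along one axis (default u) and are stacked along the other
#' in bands of `leaf_width`. For every band intersecting the polygon the leaf
#' edges are the min/max travel coordinate of the polygon within the band;
#' bands missing the polygon are closed.
#'
#' @param aperture an `aperture_polygon` or an n x 2 vertex matrix.
#' @param leaf_width leaf width in mm (> 0).
#' @param leaf_travel_axis `"u"` (leaves move anterior-posterior) or `"v"`.
#' @return List with `leaves` (data frame: `band_lo`, `band_hi`, `near`,
#'   `far`, `open`) and `jaw` (bounding box of the polygon).
#' @export
fit_mlc <- function(aperture, leaf_width = 5, leaf_travel_axis = c("u", "v")) {
  leaf_travel_axis <- match.arg(leaf_travel_axis)
  check_that(num1(leaf_width) && leaf_width > 0, "leaf_width",
             "must be a positive number")
  p <- if (inherits(aperture, "aperture_polygon")) aperture$vertices
       else as.matrix(aperture)
  if (leaf_travel_axis == "v") p <- p[, 2:1, drop = FALSE]
  n <- nrow(p)
  i2 <- c(2:n, 1)
  lo <- min(p[, 2]); hi <- max(p[, 2])
  nb <- ceiling((hi - lo) / leaf_width - 1e-9)
  bands <- data.frame(band_lo = lo + (seq_len(nb) - 1) * leaf_width)
  bands$band_hi <- bands$band_lo + leaf_width
  bands$near <- NA_real_; bands$far <- NA_real_; bands$open <- FALSE
  for (b in seq_len(nb)) {
    b0 <- bands$band_lo[b]; b1 <- bands$band_hi[b]
    us <- numeric(0)
    for (e in seq_len(n)) {
      v1 <- p[e, 2]; v2 <- p[i2[e], 2]
      u1 <- p[e, 1]; u2 <- p[i2[e], 1]
      if (max(v1, v2) < b0 || min(v1, v2) > b1) next
      if (abs(v2 - v1) < 1e-12) { us <- c(us, u1, u2); next }
      tt <- sort(c(pmin(pmax((b0 - v1) / (v2 - v1), 0), 1),
                   pmin(pmax((b1 - v1) / (v2 - v1), 0), 1)))
      us <- c(us, u1 + tt * (u2 - u1))
    }
    if (length(us)) {
      bands$near[b] <- min(us); bands$far[b] <- max(us); bands$open[b] <- TRUE
    }
  }
  jaw <- c(umin = min(p[, 1]), umax = max(p[, 1]),
           vmin = lo, vmax = hi)
  if (leaf_travel_axis == "v")
    jaw <- c(umin = jaw[["vmin"]], umax = jaw[["vmax"]],
             vmin = jaw[["umin"]], vmax = jaw[["umax"]])
  list(leaves = bands, jaw = jaw, leaf_width = leaf_width,
       leaf_travel_axis = leaf_travel_axis)
}
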
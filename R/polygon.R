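## Planar polygon utilities shared by the aperture and QA modules.
## Polygons are n x 2 matrices (columns u, v, mm), implicitly closed.

polygon_signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

#' Polygon area
#' @param p n x 2 vertex matrix (closed implicitly).
#' @return Area in mm^2 (non-negative).
#' @export
polygon_area <- function(p) abs(polygon_signed_area(p))

## drop consecutive duplicate vertices (closing duplicate included)
dedupe_vertices <- function(p, tol = 1e-9) {
  n <- nrow(p)
  if (n < 2) return(p)
  keep <- c(TRUE, rowSums(abs(p[-1, , drop = FALSE] -
                              p[-n, , drop = FALSE])) > tol)
  p <- p[keep, , drop = FALSE]
  n <- nrow(p)
  if (n > 1 && all(abs(p[1, ] - p[n, ]) <= tol)) p <- p[-n, , drop = FALSE]
  p
}

## merge vertices collinear with their neighbors (perpendicular distance
## below tol); iterates until stable
simplify_polygon <- function(p, tol = 0.1) {
  p <- dedupe_vertices(p)
  repeat {
    n <- nrow(p)
    if (n <= 3) return(p)
    prev <- p[c(n, 1:(n - 1)), , drop = FALSE]
    nxt <- p[c(2:n, 1), , drop = FALSE]
    chord <- nxt - prev
    len <- sqrt(rowSums(chord^2))
    rel <- p - prev
    d <- abs(chord[, 1] * rel[, 2] - chord[, 2] * rel[, 1]) / pmax(len, 1e-12)
    drop <- d < tol & len > 1e-12
    if (!any(drop)) return(p)
    ## remove one vertex at a time so neighbors re-evaluate
    p <- p[-which(drop)[1], , drop = FALSE]
  }
}

## insert vertices so consecutive spacing <= max_step (closed polygon)
densify_polygon <- function(p, max_step = 0.5, closed = TRUE) {
  n <- nrow(p)
  idx <- if (closed) c(seq_len(n), 1) else seq_len(n)
  out <- vector("list", length(idx) - 1)
  for (e in seq_len(length(idx) - 1)) {
    a <- p[idx[e], ]; b <- p[idx[e + 1], ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / max_step))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    out[[e]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  pts <- do.call(rbind, out)
  if (!closed) pts <- rbind(pts, p[n, , drop = FALSE])
  colnames(pts) <- c("u", "v")
  pts
}

#' Test points against a closed polygon
#'
#' Even-odd ray-crossing rule; points on an edge count as inside (the use
#' here is containment checks of anatomy strictly interior to apertures).
#'
#' @param pts m x 2 matrix of points.
#' @param poly n x 2 polygon vertex matrix.
#' @return Logical vector of length m.
#' @export
points_in_polygon <- function(pts, poly) {
  pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  i2 <- c(2:n, 1)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  on_edge <- rep(FALSE, nrow(pts))
  for (e in seq_len(n)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[i2[e], 1]; y2 <- poly[i2[e], 2]
    crosses <- ((y1 > y) != (y2 > y))
    xi <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
    inside <- xor(inside, crosses & x < ifelse(crosses, xi, Inf))
    ## on-segment check
    dx <- x2 - x1; dy <- y2 - y1
    tt <- ((x - x1) * dx + (y - y1) * dy) / max(dx^2 + dy^2, 1e-300)
    tt <- pmin(pmax(tt, 0), 1)
    dist2 <- (x1 + tt * dx - x)^2 + (y1 + tt * dy - y)^2
    on_edge <- on_edge | dist2 < 1e-18
  }
  inside | on_edge
}

## proper-intersection test between segments (a1,a2) and (b1,b2)
segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) -
    (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

## O(n^2) simplicity check over non-adjacent edge pairs
polygon_is_simple <- function(p) {
  p <- dedupe_vertices(p)
  n <- nrow(p)
  if (n < 3) return(FALSE)
  i2 <- c(2:n, 1)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (b == a || i2[a] == b || i2[b] == a) next
      if (segments_cross(p[a, ], p[i2[a], ], p[b, ], p[i2[b], ]))
        return(FALSE)
    }
  }
  TRUE
}

## all intersections of a closed polyline with the vertical line u = u0;
## returns v values (may be empty)
polyline_vertical_intersections <- function(pts, u0, closed = TRUE) {
  n <- nrow(pts)
  idx <- if (closed) c(seq_len(n), 1) else seq_len(n)
  vs <- numeric(0)
  for (e in seq_len(length(idx) - 1)) {
    u1 <- pts[idx[e], 1]; u2 <- pts[idx[e + 1], 1]
    if ((u1 - u0) * (u2 - u0) > 0) next
    if (u1 == u2) {  # vertical segment lying on the line
      if (u1 == u0) vs <- c(vs, pts[idx[e], 2], pts[idx[e + 1], 2])
      next
    }
    t <- (u0 - u1) / (u2 - u1)
    if (t >= 0 && t <= 1)
      vs <- c(vs, pts[idx[e], 2] + t * (pts[idx[e + 1], 2] - pts[idx[e], 2]))
  }
  vs
}
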
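# Planar polygon primitives for fiber morphometry. Polygons are n x 2
# matrices of vertices (open ring, any orientation); all units are micrometres.

poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Sutherland-Hodgman clip of a convex polygon by the half-plane a*x + b*y <= c
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - c
  inside <- d <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# scale a polygon about a point by a factor in (0, 1]; convexity guarantees
# the result stays inside the original cell
shrink_poly <- function(poly, center, factor) {
  sweep(sweep(poly, 2, center) * factor, 2, center, `+`)
}

#' Minimum cross-sectional (Feret) diameter of a polygon
#'
#' The minimum Feret (caliper) diameter is the smallest distance between two
#' parallel lines enclosing the shape, the standard reading of a muscle
#' fiber's "minimum cross-sectional diameter". It is computed on the convex
#' hull by rotating calipers: the minimum width of a convex polygon is
#' attained perpendicular to one of its edges, so the minimum over hull edges
#' of the farthest vertex distance from the edge line is exact.
#'
#' @param poly numeric matrix (n x 2) of polygon vertices in micrometres.
#' @return the minimum caliper diameter in micrometres.
#' @export
min_cross_sectional_diameter <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("polygon must have at least 3 vertices")
  if (poly_area(poly) <= 0) stop("degenerate (zero-area) polygon")
  h <- poly[grDevices::chull(poly), , drop = FALSE]
  n <- nrow(h)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- h[j, ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) { widths[i] <- Inf; next }
    # distance of every hull vertex from the line through edge i
    widths[i] <- max(abs((h[, 1] - h[i, 1]) * e[2] - (h[, 2] - h[i, 2]) * e[1])) / len
  }
  min(widths)
}

# even-odd point-in-polygon test, vectorised over points (m x 2)
points_in_poly <- function(pts, poly) {
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum distance from each point (m x 2) to the polygon boundary
dist_to_boundary <- function(pts, poly) {
  n <- nrow(poly)
  m <- nrow(pts)
  dmin <- rep(Inf, m)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

# uniform sample of k points inside a polygon (rejection from bounding box),
# optionally restricted by a predicate on the points
sample_in_poly <- function(k, poly, accept = NULL, max_iter = 2000L) {
  lo <- apply(poly, 2, min); hi <- apply(poly, 2, max)
  out <- matrix(numeric(0), ncol = 2)
  it <- 0L
  while (nrow(out) < k && it < max_iter) {
    it <- it + 1L
    m <- max(4L * (k - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]))
    keep <- points_in_poly(cand, poly)
    if (!is.null(accept)) keep <- keep & accept(cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  if (nrow(out) < k) stop("rejection sampling failed to place points in polygon")
  out[seq_len(k), , drop = FALSE]
}
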
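# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# Benjamini-Hochberg step-up, written directly from the definition:
# adj_(i) = min_{j >= i} min(1, p_(j) * m / j) over the sorted order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, ps * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# enrichment score by explicit running-sum enumeration; the signed
# maximum-magnitude deviation, with exact ties resolved to the positive side
# (the package's documented convention)
es_oracle <- function(genes, scores, set, weight = 1) {
  N <- length(genes)
  hit <- genes %in% set
  w <- abs(scores)^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - sum(hit)))
  running <- cumsum(inc)
  hi <- max(c(running, 0))
  lo <- min(c(running, 0))
  if (hi >= -lo - 1e-9) hi else lo
}

# minimum caliper width by scanning projection widths over an angular grid
# (3600 coarse angles, then local grid refinement around the minimum, since
# the width function is piecewise smooth with a kink at the optimum)
feret_oracle <- function(poly, n_angles = 3600) {
  width_at <- function(a) {
    proj <- outer(poly[, 1], cos(a)) + outer(poly[, 2], sin(a))
    apply(proj, 2, max) - apply(proj, 2, min)
  }
  th <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  w <- width_at(th)
  lo <- th[which.min(w)] - pi / n_angles
  hi <- th[which.min(w)] + pi / n_angles
  for (it in 1:10) {
    th <- seq(lo, hi, length.out = 41)
    w <- width_at(th)
    i <- which.min(w)
    lo <- th[max(1, i - 1)]
    hi <- th[min(41, i + 1)]
  }
  min(w)
}

# random convex polygon: convex hull of random points on an ellipse-ish cloud
random_convex_poly <- function(n_pts = 12, scale = c(1, 1)) {
  pts <- cbind(rnorm(n_pts) * scale[1], rnorm(n_pts) * scale[2])
  pts[grDevices::chull(pts), , drop = FALSE]
}

# closed-form Poisson likelihood-ratio statistic for a two-group rate model
# with exposure offsets (MLE rates are count sums over exposure sums)
poisson_lr_oracle <- function(y, totals, g) {
  lv <- unique(g)
  y1 <- sum(y[g == lv[1]]); y2 <- sum(y[g == lv[2]])
  t1 <- sum(totals[g == lv[1]]); t2 <- sum(totals[g == lv[2]])
  r1 <- y1 / t1; r2 <- y2 / t2; r0 <- (y1 + y2) / (t1 + t2)
  ll <- function(y, t, r) if (y == 0) -r * t else y * log(r) - r * t
  2 * (ll(y1, t1, r1) + ll(y2, t2, r2) - ll(y1, t1, r0) - ll(y2, t2, r0))
}

# pooled-variance two-sample t statistic
pooled_t_oracle <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (length(a) + length(b) - 2)
  (mean(b) - mean(a)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# square fiber centred at (x, y) for hand-built fiber maps
square_fiber <- function(id, x, y, half = 10, has_rods = FALSE,
                         rod_points = matrix(numeric(0), ncol = 2)) {
  list(id = id,
       polygon = rbind(c(x - half, y - half), c(x + half, y - half),
                       c(x + half, y + half), c(x - half, y + half)),
       has_rods = has_rods, rod_points = rod_points,
       pattern = NA_character_, necrotic = FALSE, regenerating = FALSE,
       atrophic_filled = FALSE)
}

toy_fiber_map <- function(fibers, bounds = c(0, 0, 1000, 1000), group = "A") {
  structure(list(section_bounds = bounds, group = group, fibers = fibers),
            class = "fiber_map")
}

# regular n-gon of radius r around (cx, cy)
regular_polygon <- function(n, r, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
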
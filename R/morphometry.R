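# Stereological morphometry: systematic uniform random sampling with counting
# frames, per-fiber metrics, rod-distribution classification, per-sample
# summaries and two-group statistics.

#' Plan systematic uniform random sampling for a fiber map
#'
#' Chooses the counting-frame size and spacing realizing systematic uniform
#' random sampling: square frames on a regular grid with random x/y offsets.
#' The frame size is the smallest of 100, 200 or 400 um whose expected fiber
#' count per frame (mean fiber density times frame area) falls within
#' `fibers_per_site_range`; the spacing in \[800, 2000\] um is the one whose
#' expected number of sites is closest to `target_sites`. Offsets are drawn
#' uniformly in \[0, spacing).
#'
#' @param map a `fiber_map`.
#' @param target_sites desired number of counting sites (about 25).
#' @param fibers_per_site_range admissible expected fibers per frame.
#' @param frame_sizes candidate frame edge lengths, um.
#' @param spacing_range admissible grid spacing, um.
#' @param seed integer seed for the random offsets.
#' @return an object of class `sampling_plan`: `frame_size`, `spacing`,
#'   `offset_x`, `offset_y`, `site_origins` (matrix of frame corners).
#' @export
plan_sampling <- function(map, target_sites = 25,
                          fibers_per_site_range = c(4, 20),
                          frame_sizes = c(100, 200, 400),
                          spacing_range = c(800, 2000),
                          seed = 1L) {
  stopifnot(inherits(map, "fiber_map"), length(map$fibers) > 0)
  b <- map$section_bounds
  W <- b[3] - b[1]; H <- b[4] - b[2]
  density <- length(map$fibers) / (W * H)
  expected <- density * frame_sizes^2
  ok_low <- expected >= fibers_per_site_range[1]
  if (!any(ok_low))
    stop("no supported frame size reaches ", fibers_per_site_range[1],
         " expected fibers per site; larger frames are unsupported")
  in_range <- ok_low & expected <= fibers_per_site_range[2]
  frame_size <- if (any(in_range)) frame_sizes[which(in_range)[1]]
                else frame_sizes[which(ok_low)[1]]
  # expected site count is (W/spacing)*(H/spacing); pick the spacing closest
  # to the target, clipped to the supported range
  sp <- sqrt(W * H / target_sites)
  spacing <- min(max(sp, spacing_range[1]), spacing_range[2])
  with_seed(seed, {
    offset_x <- stats::runif(1, 0, spacing)
    offset_y <- stats::runif(1, 0, spacing)
    ox <- seq(b[1] + offset_x, b[3], by = spacing)
    oy <- seq(b[2] + offset_y, b[4], by = spacing)
    structure(list(frame_size = frame_size, spacing = spacing,
                   offset_x = offset_x, offset_y = offset_y,
                   site_origins = as.matrix(expand.grid(x = ox, y = oy))),
              class = "sampling_plan")
  })
}

#' Sample fibers with counting frames
#'
#' A fiber is sampled iff its area centroid lies inside a frame's half-open
#' square `[x, x + s) x [y, y + s)`. The half-open rule makes exhaustive
#' tiling (spacing = frame size, zero offset) a partition of the plane, so no
#' fiber is counted twice and edge fibers are handled without bias.
#'
#' @param map a `fiber_map`.
#' @param plan a `sampling_plan` (or a list with `frame_size` and
#'   `site_origins`).
#' @return the list of sampled fibers (possibly empty).
#' @export
sample_fibers <- function(map, plan) {
  stopifnot(inherits(map, "fiber_map"))
  cent <- t(vapply(map$fibers, function(f) poly_centroid(f$polygon), numeric(2)))
  s <- plan$frame_size
  org <- plan$site_origins
  taken <- logical(nrow(cent))
  for (i in seq_len(nrow(org))) {
    hit <- cent[, 1] >= org[i, 1] & cent[, 1] < org[i, 1] + s &
           cent[, 2] >= org[i, 2] & cent[, 2] < org[i, 2] + s
    taken <- taken | hit
  }
  map$fibers[taken]
}

#' Classify the spatial distribution of rods within a fiber
#'
#' Labels a rod-bearing fiber `subsarcolemmal` if at least 80\% of its rod
#' points lie within `band_frac * r_eq` of the fiber boundary (`r_eq` the
#' equivalent-area radius), `central` if at least 80\% lie within
#' `core_frac * r_eq` of the centroid, and `diffuse` otherwise. Ties resolve
#' subsarcolemmal over central.
#'
#' @param fiber a fiber (list with `polygon`, `rod_points`, `has_rods`).
#' @param band_frac boundary band width as a fraction of `r_eq`.
#' @param core_frac central core radius as a fraction of `r_eq`.
#' @param min_frac fraction of rod points required for a pattern call.
#' @return one of `"subsarcolemmal"`, `"central"`, `"diffuse"`.
#' @export
classify_rod_distribution <- function(fiber, band_frac = 0.15, core_frac = 0.30,
                                      min_frac = 0.8) {
  if (!isTRUE(fiber$has_rods) || nrow(fiber$rod_points) == 0)
    stop("fiber has no rods to classify")
  poly <- fiber$polygon
  pts <- fiber$rod_points
  r_eq <- sqrt(poly_area(poly) / pi)
  cen <- poly_centroid(poly)
  if (mean(dist_to_boundary(pts, poly) <= band_frac * r_eq) >= min_frac)
    return("subsarcolemmal")
  d_cen <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2)
  if (mean(d_cen <= core_frac * r_eq) >= min_frac) return("central")
  "diffuse"
}

#' Summarize a sample of fibers
#'
#' Computes the per-sample morphometric summary: proportion of rod-bearing
#' fibers, mean minimum Feret diameters of rod-positive and rod-negative
#' fibers and their ratio, the fraction of rod-positive fibers that are
#' atrophic-and-filled-with-rods (diameter below `atrophy_diam_cutoff` and at
#' least `filled_rod_count_cutoff` rods), the set of rod-distribution
#' patterns observed (a pattern is reported when at least `label_min_frac` of
#' rod-positive fibers carry it — more than one pattern may be seen per
#' sample), and lesion presence flags.
#'
#' @param fibers list of fibers (e.g. from [sample_fibers()]).
#' @param atrophy_diam_cutoff um; default half the median rod-negative
#'   diameter of the sample.
#' @param filled_rod_count_cutoff minimum rod count of a "filled" fiber.
#' @param label_min_frac fraction of rod+ fibers needed to report a pattern.
#' @return an object of class `morphometry_summary`.
#' @export
summarize_sample <- function(fibers, atrophy_diam_cutoff = NULL,
                             filled_rod_count_cutoff = 20,
                             label_min_frac = 0.10) {
  if (length(fibers) == 0) stop("no fibers to summarize")
  has <- vapply(fibers, `[[`, logical(1), "has_rods")
  diam <- vapply(fibers, function(f) min_cross_sectional_diameter(f$polygon),
                 numeric(1))
  mean_rod <- if (any(has)) mean(diam[has]) else NA_real_
  mean_norod <- if (any(!has)) mean(diam[!has]) else NA_real_
  size_ratio <- if (any(has) && any(!has)) mean_rod / mean_norod else NA_real_
  if (is.null(atrophy_diam_cutoff))
    atrophy_diam_cutoff <- if (any(!has)) 0.5 * stats::median(diam[!has]) else NA_real_
  n_rods <- vapply(fibers, function(f) nrow(f$rod_points), integer(1))
  filled <- has & !is.na(atrophy_diam_cutoff) &
    diam < atrophy_diam_cutoff & n_rods >= filled_rod_count_cutoff
  prop_filled <- if (any(has)) mean(filled[has]) else NA_real_
  labels <- character(0)
  if (any(has)) {
    pat <- vapply(fibers[has], classify_rod_distribution, character(1))
    tab <- table(pat) / sum(has)
    labels <- sort(names(tab)[tab >= label_min_frac])
  }
  structure(list(
    n_fibers_sampled = length(fibers),
    prop_rod_fibers = mean(has),
    mean_diam_rod = mean_rod, mean_diam_norod = mean_norod,
    size_ratio = size_ratio,
    prop_atrophic_filled = prop_filled,
    distribution_labels = labels,
    has_necrotic = any(vapply(fibers, `[[`, logical(1), "necrotic")),
    has_regenerating = any(vapply(fibers, `[[`, logical(1), "regenerating")),
    has_atrophic_filled = any(filled)),
    class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf(paste0("morphometry_summary: %d fibers, %.1f%% rod+, size ratio %s, ",
                     "patterns {%s}\n"),
              x$n_fibers_sampled, 100 * x$prop_rod_fibers,
              ifelse(is.na(x$size_ratio), "NA", sprintf("%.2f", x$size_ratio)),
              paste(x$distribution_labels, collapse = ", ")))
  invisible(x)
}

summary_row <- function(s) {
  data.frame(n_fibers_sampled = s$n_fibers_sampled,
             prop_rod_fibers = s$prop_rod_fibers,
             mean_diam_rod = s$mean_diam_rod,
             mean_diam_norod = s$mean_diam_norod,
             size_ratio = s$size_ratio,
             prop_atrophic_filled = s$prop_atrophic_filled,
             diffuse = "diffuse" %in% s$distribution_labels,
             central = "central" %in% s$distribution_labels,
             subsarcolemmal = "subsarcolemmal" %in% s$distribution_labels,
             has_necrotic = s$has_necrotic,
             has_regenerating = s$has_regenerating,
             has_atrophic_filled = s$has_atrophic_filled)
}

#' Compare morphometry between two groups of samples
#'
#' Continuous metrics (proportion of rod fibers, size ratio, mean rod+ fiber
#' diameter) are compared by two-sided pooled-variance Student t tests;
#' binary sample-level features (lesion presence, rod-distribution patterns)
#' by chi-square tests on the 2 x 2 table without continuity correction.
#' Undefined values (e.g. missing size ratios) are dropped per metric; a test
#' with zero pooled variance reports a missing p value.
#'
#' @param summaries_a,summaries_b lists of `morphometry_summary` objects.
#' @param labels group labels, length 2.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per metric: group means/SDs (proportions
#'   for binary features), statistic, p value, test name, significance flag.
#' @export
compare_groups <- function(summaries_a, summaries_b,
                           labels = c("A", "B"), alpha = 0.05) {
  stopifnot(length(summaries_a) >= 2, length(summaries_b) >= 2)
  da <- do.call(rbind, lapply(summaries_a, summary_row))
  db <- do.call(rbind, lapply(summaries_b, summary_row))
  cont <- c("prop_rod_fibers", "size_ratio", "mean_diam_rod", "mean_diam_norod")
  bin <- c("has_necrotic", "has_regenerating", "has_atrophic_filled",
           "diffuse", "central", "subsarcolemmal")
  rows <- lapply(cont, function(metric) {
    xa <- da[[metric]]; xb <- db[[metric]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2 ||
        (stats::var(xa) + stats::var(xb)) == 0) {
      stat <- if (length(xa) && length(xb) && mean(xa) == mean(xb)) 0 else NA_real_
      p <- NA_real_
    } else {
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(metric = metric, test = "t",
               mean_a = mean(xa), sd_a = stats::sd(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb),
               statistic = stat, p = p)
  })
  rows_b <- lapply(bin, function(metric) {
    xa <- da[[metric]]; xb <- db[[metric]]
    tab <- rbind(c(sum(xa), sum(!xa)), c(sum(xb), sum(!xb)))
    if (any(colSums(tab) == 0)) {
      stat <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic); p <- ct$p.value
    }
    data.frame(metric = metric, test = "chi-square",
               mean_a = mean(xa), sd_a = stats::sd(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb),
               statistic = stat, p = p)
  })
  out <- rbind(do.call(rbind, rows), do.call(rbind, rows_b))
  out$significant <- !is.na(out$p) & out$p < alpha
  attr(out, "group_labels") <- labels
  out
}
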
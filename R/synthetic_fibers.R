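#' Cohort-level parameters for synthetic muscle sections
#'
#' Bundles the per-group settings used by [generate_section()]: how many
#' biopsies per group, what fraction of fibers carry nemaline rods, how large
#' rod-bearing fibers are relative to rod-free fibers, how rods are spatially
#' distributed within fibers, and per-fiber lesion rates. Defaults emulate
#' the published group means for inherited (iNM) versus sporadic late-onset
#' (SLONM) nemaline myopathy cohorts; they are generator settings, not data.
#'
#' @param n_samples_per_group integer >= 1, biopsies simulated per group.
#' @param rod_prevalence_by_group named numeric in \[0,1\]: mean fraction of
#'   fibers carrying rods, per group.
#' @param size_ratio_by_group named positive numeric: expected ratio of mean
#'   minimum diameter, rod-positive over rod-negative fibers (1.12 means rod
#'   fibers are 12\% larger; 0.60 means markedly smaller).
#' @param distribution_mix_by_group named list; per group a probability vector
#'   over the rod spatial patterns `c(diffuse=, central=, subsarcolemmal=)`,
#'   summing to 1. Each rod-positive fiber samples its pattern from this mix.
#' @param lesion_rates named list; per group the per-fiber probabilities
#'   `c(necrotic=, regenerating=, atrophic_filled=)`. `atrophic_filled`
#'   applies to rod-positive fibers only (shrunken fibers packed with rods).
#' @param seed integer global seed for the cohort.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_samples_per_group = 9L,
                          rod_prevalence_by_group = c(iNM = 0.53, SLONM = 0.11),
                          size_ratio_by_group = c(iNM = 1.12, SLONM = 0.60),
                          distribution_mix_by_group = list(
                            iNM   = c(diffuse = 0.10, central = 0.45, subsarcolemmal = 0.45),
                            SLONM = c(diffuse = 0.80, central = 0.10, subsarcolemmal = 0.10)),
                          lesion_rates = list(
                            iNM   = c(necrotic = 0.002, regenerating = 0.004, atrophic_filled = 0.01),
                            SLONM = c(necrotic = 0.02,  regenerating = 0.04,  atrophic_filled = 0.15)),
                          seed = 1L) {
  groups <- names(rod_prevalence_by_group)
  stopifnot(n_samples_per_group >= 1,
            !is.null(groups), all(nzchar(groups)),
            identical(groups, names(size_ratio_by_group)),
            identical(groups, names(distribution_mix_by_group)),
            identical(groups, names(lesion_rates)))
  if (any(rod_prevalence_by_group < 0 | rod_prevalence_by_group > 1))
    stop("rod prevalence must be in [0, 1]")
  if (any(size_ratio_by_group <= 0)) stop("size ratios must be positive")
  for (g in groups) {
    mix <- distribution_mix_by_group[[g]]
    stopifnot(identical(sort(names(mix)),
                        sort(c("diffuse", "central", "subsarcolemmal"))))
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
      stop("distribution_mix must be a probability vector summing to 1 (group ", g, ")")
    lr <- lesion_rates[[g]]
    if (any(lr < 0 | lr > 1)) stop("lesion rates must be probabilities (group ", g, ")")
  }
  structure(list(n_samples_per_group = as.integer(n_samples_per_group),
                 rod_prevalence_by_group = rod_prevalence_by_group,
                 size_ratio_by_group = size_ratio_by_group,
                 distribution_mix_by_group = distribution_mix_by_group,
                 lesion_rates = lesion_rates,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# place rod points inside a fiber polygon according to a spatial pattern:
# subsarcolemmal = within band_frac * r_eq of the boundary, central = within
# core_frac * r_eq of the centroid, diffuse = uniform over the fiber
place_rods <- function(n, poly, pattern, band_frac = 0.15, core_frac = 0.30) {
  r_eq <- sqrt(poly_area(poly) / pi)
  cen <- poly_centroid(poly)
  accept <- switch(pattern,
    diffuse = NULL,
    central = function(p) sqrt((p[, 1] - cen[1])^2 + (p[, 2] - cen[2])^2) <= core_frac * r_eq,
    subsarcolemmal = function(p) dist_to_boundary(p, poly) <= band_frac * r_eq,
    stop("unknown rod pattern: ", pattern))
  sample_in_poly(n, poly, accept)
}

#' Generate a synthetic muscle cross-section
#'
#' Builds a fiber map: a rectangular section tiled by non-overlapping fiber
#' polygons, each annotated with rod status, rod point coordinates, the
#' ground-truth rod spatial pattern, and lesion flags. Fiber outlines are the
#' Voronoi cells of a jittered hexagonal-ish grid (computed exactly by
#' clipping each point's neighbourhood with perpendicular-bisector
#' half-planes), shrunk towards their centroids to leave endomysial gaps.
#' Rod-positive fibers are scaled so that the expected rod+/rod- diameter
#' ratio equals the group's `size_ratio_by_group`; "atrophic filled" fibers
#' are additionally shrunken and packed with >= 20 rods.
#'
#' @param params a [cohort_params()] object.
#' @param group group label, one of `names(params$rod_prevalence_by_group)`.
#' @param seed integer seed for this section.
#' @param section_um numeric length-2, section width and height in um.
#' @param fiber_pitch_um grid pitch in um controlling fiber density
#'   (one fiber per `fiber_pitch_um^2` on average).
#' @return an object of class `fiber_map`: list with `section_bounds`
#'   (xmin, ymin, xmax, ymax), `group`, and `fibers`, a list of fibers each
#'   holding `id`, `polygon`, `has_rods`, `rod_points`, `pattern` (truth
#'   label or NA), `necrotic`, `regenerating`, `atrophic_filled`.
#' @export
generate_section <- function(params, group, seed = params$seed,
                             section_um = c(3000, 3000),
                             fiber_pitch_um = 65) {
  stopifnot(inherits(params, "cohort_params"))
  if (!group %in% names(params$rod_prevalence_by_group))
    stop("unknown group: ", group)
  if (any(section_um <= 0)) stop("section dimensions must be positive")
  prev <- params$rod_prevalence_by_group[[group]]
  if (prev < 0 || prev > 1) stop("rod prevalence must be in [0, 1]")
  ratio <- params$size_ratio_by_group[[group]]
  mix <- params$distribution_mix_by_group[[group]]
  lesions <- params$lesion_rates[[group]]

  with_seed(seed, {
    W <- section_um[1]; H <- section_um[2]; pitch <- fiber_pitch_um
    nx <- max(2L, floor(W / pitch)); ny <- max(2L, floor(H / pitch))
    gx <- (seq_len(nx) - 0.5) * W / nx
    gy <- (seq_len(ny) - 0.5) * H / ny
    pts <- cbind(rep(gx, times = ny), rep(gy, each = nx))
    # jitter < 0.35 * pitch keeps true Voronoi neighbours within 3 * pitch
    jit <- 0.30 * pitch
    pts <- pts + matrix(stats::runif(2 * nrow(pts), -jit, jit), ncol = 2)

    n <- nrow(pts)
    box <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))
    # per-fiber annotations drawn up front so geometry and labels share one stream
    has_rods <- stats::runif(n) < prev
    pat <- rep(NA_character_, n)
    if (any(has_rods))
      pat[has_rods] <- sample(names(mix), sum(has_rods), replace = TRUE, prob = mix)
    necrotic <- stats::runif(n) < lesions[["necrotic"]]
    regen <- stats::runif(n) < lesions[["regenerating"]]
    atrophic <- has_rods & (stats::runif(n) < lesions[["atrophic_filled"]])

    # scale factors: ratio of expected diameters rod+/rod- equals `ratio`
    s_minus <- 0.88 / max(1, ratio)
    s_plus <- s_minus * ratio
    jfac <- stats::runif(n, 0.85, 1.0)
    scale <- ifelse(has_rods, s_plus, s_minus) * jfac
    scale[atrophic] <- scale[atrophic] * 0.35

    n_rods <- integer(n)
    n_rods[has_rods] <- 5L + stats::rpois(sum(has_rods), 6)
    n_rods[atrophic] <- 20L + stats::rpois(sum(atrophic), 10)

    fibers <- vector("list", n)
    r_neigh <- 3 * pitch
    for (i in seq_len(n)) {
      dx <- pts[, 1] - pts[i, 1]; dy <- pts[, 2] - pts[i, 2]
      nb <- which(dx^2 + dy^2 <= r_neigh^2 & seq_len(n) != i)
      cell <- box
      for (k in nb) {
        # half-plane closer to i than to k
        mx <- (pts[i, 1] + pts[k, 1]) / 2; my <- (pts[i, 2] + pts[k, 2]) / 2
        a <- pts[k, 1] - pts[i, 1]; b <- pts[k, 2] - pts[i, 2]
        cell <- clip_halfplane(cell, a, b, a * mx + b * my)
        if (nrow(cell) < 3L) break
      }
      if (nrow(cell) < 3L) next
      poly <- shrink_poly(cell, poly_centroid(cell), scale[i])
      rods <- if (has_rods[i]) place_rods(n_rods[i], poly, pat[i])
              else matrix(numeric(0), ncol = 2)
      fibers[[i]] <- list(id = i, polygon = poly,
                          has_rods = has_rods[i], rod_points = rods,
                          pattern = pat[i],
                          necrotic = necrotic[i], regenerating = regen[i],
                          atrophic_filled = atrophic[i])
    }
    fibers <- Filter(Negate(is.null), fibers)
    structure(list(section_bounds = c(0, 0, W, H), group = group,
                   fibers = fibers),
              class = "fiber_map")
  })
}

#' @export
print.fiber_map <- function(x, ...) {
  nr <- sum(vapply(x$fibers, `[[`, logical(1), "has_rods"))
  cat(sprintf("fiber_map: %d fibers (%d rod+), section %.0f x %.0f um, group %s\n",
              length(x$fibers), nr, x$section_bounds[3], x$section_bounds[4],
              x$group %||% "?"))
  invisible(x)
}

# section-wide census values (ground truth a sampling plan estimates)
fiber_map_truth <- function(map) {
  has <- vapply(map$fibers, `[[`, logical(1), "has_rods")
  list(n_fibers = length(map$fibers), prop_rod_fibers = mean(has))
}

#' Write a fiber map as a GeoJSON-style FeatureCollection
#'
#' One Polygon feature per fiber; properties carry `id`, `has_rods`,
#' `rod_points` (list of \[x, y\]), `pattern` and the lesion flags. This is
#' the package's on-disk fiber-map dialect. Coordinates are written at fixed
#' precision so repeated writes are byte-identical.
#'
#' @param map a `fiber_map`.
#' @param path output file path.
#' @param digits decimal places for coordinates.
#' @return `path`, invisibly.
#' @export
write_fiber_map <- function(map, path, digits = 4L) {
  rnd <- function(m) round(unname(as.matrix(m)), digits)
  feats <- lapply(map$fibers, function(f) {
    ring <- rnd(f$polygon)
    ring <- rbind(ring, ring[1, ])  # closed ring per GeoJSON
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(apply(ring, 1, c, simplify = FALSE))),
         properties = list(id = f$id, has_rods = f$has_rods,
                           rod_points = if (nrow(f$rod_points))
                             apply(rnd(f$rod_points), 1, c, simplify = FALSE)
                           else list(),
                           pattern = f$pattern,
                           necrotic = f$necrotic, regenerating = f$regenerating,
                           atrophic_filled = f$atrophic_filled))
  })
  obj <- list(type = "FeatureCollection",
              section_bounds = map$section_bounds,
              group = map$group %||% NA_character_,
              features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Read a fiber map written by [write_fiber_map()]
#'
#' @param path path to the GeoJSON-style file.
#' @return a `fiber_map`.
#' @export
read_fiber_map <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection"))
    stop("not a fiber-map FeatureCollection: ", path)
  fibers <- lapply(obj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    p <- f$properties
    rods <- if (length(p$rod_points))
      do.call(rbind, lapply(p$rod_points, unlist)) else matrix(numeric(0), ncol = 2)
    list(id = p$id, polygon = ring, has_rods = isTRUE(p$has_rods),
         rod_points = rods,
         pattern = if (is.null(p$pattern)) NA_character_ else p$pattern,
         necrotic = isTRUE(p$necrotic), regenerating = isTRUE(p$regenerating),
         atrophic_filled = isTRUE(p$atrophic_filled))
  })
  structure(list(section_bounds = unlist(obj$section_bounds),
                 group = if (is.null(obj$group) || is.na(obj$group)) NULL else obj$group,
                 fibers = fibers),
            class = "fiber_map")
}
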
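# Stereological sampling, fiber metrics, rod-pattern classification and
# group statistics.

test_that("frame size selection follows the expected-count rule", {
  # density 2.5e-4 fibers/um^2: 100 um frame expects 2.5 fibers, 200 um
  # expects 10, 400 um expects 40 -> the 200 um frame is selected
  map <- toy_fiber_map(rep(list(square_fiber(1, 50, 50)), 25000),
                       bounds = c(0, 0, 10000, 10000))
  plan <- plan_sampling(map, seed = 1)
  expect_identical(plan$frame_size, 200)
  # 10000 x 10000 section at the 2000 um spacing cap -> 5 x 5 = 25 sites
  expect_identical(plan$spacing, 2000)
  expect_identical(nrow(plan$site_origins), 25L)
  expect_identical(plan_sampling(map, seed = 1), plan)
  expect_false(identical(plan_sampling(map, seed = 2)$offset_x, plan$offset_x))
  expect_true(plan$offset_x >= 0 && plan$offset_x < plan$spacing)
})

test_that("too sparse sections are rejected with advice", {
  map <- toy_fiber_map(rep(list(square_fiber(1, 50, 50)), 10),
                       bounds = c(0, 0, 10000, 10000))
  expect_error(plan_sampling(map), "unsupported")
})

test_that("fibers are sampled by the half-open centroid rule", {
  # frame [100, 200) x [100, 200): centre inside, right/top edges excluded
  fibers <- list(square_fiber(1, 150, 150),   # strictly inside
                 square_fiber(2, 200, 150),   # centroid on right edge
                 square_fiber(3, 150, 200),   # centroid on top edge
                 square_fiber(4, 100, 100),   # on left/bottom corner: included
                 square_fiber(5, 300, 300))   # outside
  map <- toy_fiber_map(fibers)
  plan <- structure(list(frame_size = 100, spacing = 500, offset_x = 100,
                         offset_y = 100,
                         site_origins = matrix(c(100, 100), 1,
                                               dimnames = list(NULL, c("x", "y")))),
                    class = "sampling_plan")
  got <- vapply(sample_fibers(map, plan), `[[`, numeric(1), "id")
  expect_setequal(got, c(1, 4))
})

test_that("exhaustive tiling with zero offset reproduces the census exactly", {
  cp <- cohort_params()
  m <- generate_section(cp, "iNM", seed = 21, section_um = c(1500, 1500))
  s <- 250
  org <- as.matrix(expand.grid(x = seq(0, 1500 - s, s), y = seq(0, 1500 - s, s)))
  plan <- structure(list(frame_size = s, spacing = s, offset_x = 0, offset_y = 0,
                         site_origins = org), class = "sampling_plan")
  sampled <- sample_fibers(m, plan)
  expect_identical(length(sampled), length(m$fibers))
  expect_setequal(vapply(sampled, `[[`, integer(1), "id"),
                  vapply(m$fibers, `[[`, integer(1), "id"))
  census <- summarize_sample(m$fibers)
  tiled <- summarize_sample(sampled)
  expect_identical(tiled$prop_rod_fibers, census$prop_rod_fibers)
  expect_identical(tiled$size_ratio, census$size_ratio)
})

test_that("minimum Feret diameter matches known shapes and the angular oracle", {
  expect_equal(min_cross_sectional_diameter(regular_polygon(64, 10)), 20,
               tolerance = 0.1)
  rect <- rbind(c(0, 0), c(30, 0), c(30, 10), c(0, 10))
  expect_equal(min_cross_sectional_diameter(rect), 10, tolerance = 1e-12)
  set.seed(404)
  for (i in 1:50) {
    poly <- random_convex_poly(sample(6:20, 1), scale = runif(2, 0.5, 3))
    got <- min_cross_sectional_diameter(poly)
    ref <- feret_oracle(poly)
    expect_lt(abs(got - ref) / ref, 1e-6)
  }
  expect_error(min_cross_sectional_diameter(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("rod distribution classification follows the band/core rule", {
  poly <- regular_polygon(48, 50)
  centroidal <- list(polygon = poly, has_rods = TRUE,
                     rod_points = matrix(rep(c(0, 0), 5), ncol = 2, byrow = TRUE))
  expect_identical(classify_rod_distribution(centroidal), "central")

  th <- seq(0, 2 * pi, length.out = 13)[-13]
  r_eq <- sqrt(rodomics:::poly_area(poly) / pi)
  rim <- cbind((r_eq * 0.95) * cos(th), (r_eq * 0.95) * sin(th))
  sub <- list(polygon = poly, has_rods = TRUE, rod_points = rim)
  expect_identical(classify_rod_distribution(sub), "subsarcolemmal")

  set.seed(5)
  unif <- list(polygon = poly, has_rods = TRUE,
               rod_points = rodomics:::sample_in_poly(200, poly))
  expect_identical(classify_rod_distribution(unif), "diffuse")

  expect_error(classify_rod_distribution(
    list(polygon = poly, has_rods = FALSE,
         rod_points = matrix(numeric(0), ncol = 2))), "no rods")
})

test_that("generated rod patterns are recovered by the classifier", {
  cp <- cohort_params()
  agree <- n <- 0
  for (g in c("iNM", "SLONM")) {
    m <- generate_section(cp, g, seed = 31, section_um = c(1500, 1500))
    for (f in m$fibers) {
      if (!f$has_rods) next
      n <- n + 1
      agree <- agree + (classify_rod_distribution(f) == f$pattern)
    }
  }
  expect_gt(n, 100)
  expect_gte(agree / n, 0.95)
})

test_that("sample summaries compute the documented metrics", {
  rod_pts <- matrix(c(0, 0), 1)
  mk <- function(id, half, rods) square_fiber(id, 500, 500, half = half,
                                              has_rods = rods,
                                              rod_points = if (rods) rod_pts else matrix(numeric(0), ncol = 2))
  fibers <- c(lapply(1:4, function(i) mk(i, 14, TRUE)),   # rod+ diameter 28
              lapply(5:10, function(i) mk(i, 12.5, FALSE))) # rod- diameter 25
  s <- summarize_sample(fibers)
  expect_identical(s$prop_rod_fibers, 0.4)
  expect_equal(s$mean_diam_rod, 28)
  expect_equal(s$mean_diam_norod, 25)
  expect_equal(s$size_ratio, 1.12)

  rodfree <- summarize_sample(lapply(1:5, function(i) mk(i, 10, FALSE)))
  expect_identical(rodfree$prop_rod_fibers, 0)
  expect_true(is.na(rodfree$size_ratio))
  expect_error(summarize_sample(list()), "no fibers")
})

test_that("atrophic rod-filled fibers require both the size and rod-count cutoffs", {
  many_rods <- matrix(runif(50, -2, 2), ncol = 2)
  fibers <- list(
    square_fiber(1, 100, 100, half = 3, has_rods = TRUE, rod_points = many_rods),
    square_fiber(2, 300, 100, half = 20, has_rods = TRUE, rod_points = many_rods),
    square_fiber(3, 500, 100, half = 3, has_rods = TRUE,
                 rod_points = matrix(c(0, 0), 1)),
    square_fiber(4, 700, 100, half = 20, has_rods = FALSE),
    square_fiber(5, 900, 100, half = 20, has_rods = FALSE))
  s <- summarize_sample(fibers, atrophy_diam_cutoff = 10,
                        filled_rod_count_cutoff = 20)
  expect_equal(s$prop_atrophic_filled, 1 / 3)  # only fiber 1: small AND packed
})

test_that("group comparisons use pooled t and chi-square without correction", {
  mk_sum <- function(prop, ratio, necrotic) {
    structure(list(n_fibers_sampled = 100L, prop_rod_fibers = prop,
                   mean_diam_rod = 30, mean_diam_norod = 30 / ratio,
                   size_ratio = ratio, prop_atrophic_filled = 0,
                   distribution_labels = "diffuse",
                   has_necrotic = necrotic, has_regenerating = FALSE,
                   has_atrophic_filled = FALSE),
              class = "morphometry_summary")
  }
  a <- list(mk_sum(0.4, 1.1, FALSE), mk_sum(0.5, 1.2, FALSE))
  b <- list(mk_sum(0.4, 1.1, FALSE), mk_sum(0.5, 1.2, FALSE))
  cmp <- compare_groups(a, b)
  prop_row <- cmp[cmp$metric == "prop_rod_fibers", ]
  expect_equal(prop_row$statistic, 0)
  expect_equal(prop_row$p, 1)

  # necrotic-fiber presence 1/9 vs 8/13: hand chi-square n(ad-bc)^2 / products
  a9 <- lapply(1:9, function(i) mk_sum(0.5, 1.1, i <= 1))
  b13 <- lapply(1:13, function(i) mk_sum(0.1, 0.6, i <= 8))
  cmp2 <- compare_groups(a9, b13)
  row <- cmp2[cmp2$metric == "has_necrotic", ]
  a_ <- 1; b_ <- 8; c_ <- 8; d_ <- 5  # present/absent per group
  hand <- 22 * (a_ * d_ - b_ * c_)^2 /
    ((a_ + b_) * (c_ + d_) * (a_ + c_) * (b_ + d_))
  expect_equal(row$statistic, hand, tolerance = 1e-10)
  expect_equal(row$statistic, 5.59, tolerance = 0.01)
  expect_true(row$p < 0.05)
  expect_identical(row$test, "chi-square")
})

test_that("the t statistic matches the pooled-variance oracle", {
  mk_sum <- function(prop) {
    structure(list(n_fibers_sampled = 100L, prop_rod_fibers = prop,
                   mean_diam_rod = 30, mean_diam_norod = 27,
                   size_ratio = 30 / 27, prop_atrophic_filled = 0,
                   distribution_labels = "diffuse",
                   has_necrotic = FALSE, has_regenerating = FALSE,
                   has_atrophic_filled = FALSE),
              class = "morphometry_summary")
  }
  pa <- c(0.42, 0.55, 0.61, 0.48)
  pb <- c(0.10, 0.15, 0.08)
  cmp <- compare_groups(lapply(pa, mk_sum), lapply(pb, mk_sum))
  trow <- cmp[cmp$metric == "prop_rod_fibers", ]
  # t.test reports mean(a) - mean(b); the oracle is b - a, so negate
  expect_equal(trow$statistic, -pooled_t_oracle(pa, pb), tolerance = 1e-12)
  expect_true(trow$significant)
})

test_that("zero pooled variance reports a missing p value", {
  mk <- function(prop) structure(list(n_fibers_sampled = 10L,
                                      prop_rod_fibers = prop,
                                      mean_diam_rod = NA_real_,
                                      mean_diam_norod = 25, size_ratio = NA_real_,
                                      prop_atrophic_filled = 0,
                                      distribution_labels = character(0),
                                      has_necrotic = FALSE,
                                      has_regenerating = FALSE,
                                      has_atrophic_filled = FALSE),
                                 class = "morphometry_summary")
  cmp <- compare_groups(list(mk(0.3), mk(0.3)), list(mk(0.3), mk(0.3)))
  row <- cmp[cmp$metric == "prop_rod_fibers", ]
  expect_equal(row$statistic, 0)
  expect_true(is.na(row$p))
})
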
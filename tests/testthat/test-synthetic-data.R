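# Generators: seeded determinism, marginal calibration, degenerate settings,
# geometric invariants of the fiber maps, serialization round trip.

test_that("generate_section is deterministic under a fixed seed", {
  cp <- cohort_params(seed = 7)
  m1 <- generate_section(cp, "iNM", seed = 7, section_um = c(800, 800))
  m2 <- generate_section(cp, "iNM", seed = 7, section_um = c(800, 800))
  expect_identical(m1, m2)
  m3 <- generate_section(cp, "iNM", seed = 8, section_um = c(800, 800))
  expect_false(identical(m1, m3))
})

test_that("zero rod prevalence yields a rod-free section", {
  cp <- cohort_params(rod_prevalence_by_group = c(g = 0),
                      size_ratio_by_group = c(g = 1),
                      distribution_mix_by_group = list(
                        g = c(diffuse = 1, central = 0, subsarcolemmal = 0)),
                      lesion_rates = list(
                        g = c(necrotic = 0, regenerating = 0, atrophic_filled = 0)))
  m <- generate_section(cp, "g", seed = 1, section_um = c(900, 900))
  expect_false(any(vapply(m$fibers, `[[`, logical(1), "has_rods")))
  expect_true(all(vapply(m$fibers, function(f) nrow(f$rod_points) == 0, logical(1))))
})

test_that("empirical rod prevalence matches the setting within 3 binomial SE", {
  cp <- cohort_params()
  m <- generate_section(cp, "iNM", seed = 11, section_um = c(3000, 3000),
                        fiber_pitch_um = 65)
  has <- vapply(m$fibers, `[[`, logical(1), "has_rods")
  expect_gt(length(has), 1500)
  se <- sqrt(0.53 * 0.47 / length(has))
  expect_lt(abs(mean(has) - 0.53), 3 * se)
})

test_that("fiber maps satisfy their geometric invariants", {
  cp <- cohort_params()
  m <- generate_section(cp, "SLONM", seed = 3, section_um = c(1200, 1200))
  b <- m$section_bounds
  for (f in m$fibers) {
    expect_true(all(f$polygon[, 1] >= b[1] - 1e-9 & f$polygon[, 1] <= b[3] + 1e-9))
    expect_true(all(f$polygon[, 2] >= b[2] - 1e-9 & f$polygon[, 2] <= b[4] + 1e-9))
    expect_identical(f$has_rods, nrow(f$rod_points) > 0)
    if (f$has_rods)
      expect_true(all(rodomics:::points_in_poly(f$rod_points, f$polygon)))
  }
  # non-overlap: total fiber area cannot exceed the section area
  areas <- vapply(m$fibers, function(f) rodomics:::poly_area(f$polygon), numeric(1))
  expect_lt(sum(areas), (b[3] - b[1]) * (b[4] - b[2]))
})

test_that("fiber maps round-trip through the GeoJSON dialect", {
  cp <- cohort_params()
  m <- generate_section(cp, "iNM", seed = 5, section_um = c(700, 700))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_fiber_map(m, path)
  m2 <- read_fiber_map(path)
  expect_identical(length(m2$fibers), length(m$fibers))
  expect_equal(m2$section_bounds, m$section_bounds)
  i <- which(vapply(m$fibers, `[[`, logical(1), "has_rods"))[1]
  expect_equal(m2$fibers[[i]]$polygon, m$fibers[[i]]$polygon, tolerance = 1e-4)
  expect_equal(m2$fibers[[i]]$rod_points, m$fibers[[i]]$rod_points, tolerance = 1e-4)
  expect_identical(m2$fibers[[i]]$pattern, m$fibers[[i]]$pattern)
  # a second write of the re-read map is byte-identical (fixed precision)
  path2 <- withr::local_tempfile(fileext = ".geojson")
  write_fiber_map(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("intensity generator: censoring and planting degenerate correctly", {
  op0 <- omics_params(n_features = 300, n_per_group = 4, censor_quantile = 0,
                      frac_affected = 0, seed = 2)
  sim0 <- generate_intensity_matrix(op0)
  expect_false(anyNA(sim0$intensities))
  expect_identical(nrow(sim0$truth), 0L)
  expect_identical(generate_intensity_matrix(op0), sim0)

  op <- omics_params(n_features = 500, n_per_group = 10, censor_quantile = 0.1,
                     frac_affected = 0, seed = 4)
  sim <- generate_intensity_matrix(op)
  miss <- is.na(sim$intensities)
  # left-censoring: latent values under missing cells are low on average
  expect_lt(mean(sim$latent[miss]), mean(sim$latent))
  # marginal calibration of the missing rate (3 binomial SE)
  n_cells <- length(miss)
  expect_lt(abs(mean(miss) - 0.1), 3 * sqrt(0.1 * 0.9 / n_cells))
})

test_that("planted intensity effects have the stated size and direction", {
  op <- omics_params(n_features = 1000, n_per_group = 10, censor_quantile = 0,
                     frac_affected = 0.05, effect_log2fc = 2, seed = 9)
  sim <- generate_intensity_matrix(op)
  g2 <- sim$groups == levels(sim$groups)[2]
  lat <- sim$latent
  fc <- rowMeans(lat[, g2]) - rowMeans(lat[, !g2])
  est <- unname(fc[match(sim$truth$feature, rownames(lat))])
  expect_equal(est, sim$truth$true_log2fc, tolerance = 0.5)
  expect_equal(nrow(sim$truth), 50L)
})

test_that("count generator: Poisson limit, determinism, planted rate ratio", {
  op1 <- omics_params(n_features = 40, n_per_group = 30, dispersion = 1,
                      frac_affected = 0, total_counts_per_sample = 50000, seed = 6)
  cs <- generate_count_table(op1)
  expect_identical(generate_count_table(op1), cs)
  # variance/mean ratio per family across replicates concentrates near 1
  vm <- apply(cs$counts, 1, var) / rowMeans(cs$counts)
  expect_lt(abs(median(vm) - 1), 0.35)

  over <- generate_count_table(omics_params(n_features = 40, n_per_group = 30,
                                            dispersion = 6, frac_affected = 0,
                                            seed = 6))
  vm_over <- apply(over$counts, 1, var) / rowMeans(over$counts)
  expect_gt(median(vm_over), median(vm) + 1)

  # Monte-Carlo over replicated tables: planted 2^2 = 4-fold rate ratio
  ratios <- vapply(1:200, function(s) {
    op <- omics_params(n_features = 10, n_per_group = 3, dispersion = 1,
                       frac_affected = 0.1, effect_log2fc = 2,
                       total_counts_per_sample = 2e5, seed = s)
    cs <- generate_count_table(op)
    f <- cs$truth$feature[1]
    g2 <- cs$groups == levels(cs$groups)[2]
    rate <- cs$counts[f, ] / cs$totals
    r <- mean(rate[g2]) / mean(rate[!g2])
    if (cs$truth$true_log2fc[1] < 0) 1 / r else r
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  expect_gt(length(ratios), 190)
  expect_lt(abs(mean(ratios) - 4), 3 * sd(ratios) / sqrt(length(ratios)) + 0.1)
})

test_that("negative and invalid generator settings are rejected", {
  expect_error(omics_params(dispersion = 0.5), "dispersion")
  expect_error(omics_params(censor_quantile = 1), "censor")
  expect_error(cohort_params(rod_prevalence_by_group = c(iNM = 1.2, SLONM = 0.1)),
               "prevalence|names")
  expect_error(generate_section(cohort_params(), "iNM", section_um = c(-1, 100)),
               "positive")
  expect_error(generate_intensity_matrix(omics_params(n_per_group = 1)),
               "n_per_group")
})

test_that("paired omics plants exactly the requested shared targets", {
  op <- omics_params(n_features = 400, n_per_group = 5, frac_affected = 0.05,
                     effect_log2fc = 3, seed = 13)
  p0 <- generate_paired_omics(op, n_shared_targets = 0)
  prot_set <- p0$truth$feature[p0$truth$arm == "protein"]
  rna_set <- p0$truth$feature[p0$truth$arm == "rna"]
  expect_length(intersect(prot_set, rna_set), 0)

  p3 <- generate_paired_omics(op, n_shared_targets = 3)
  tr <- p3$truth
  shared <- intersect(tr$feature[tr$arm == "protein"], tr$feature[tr$arm == "rna"])
  expect_setequal(shared, p3$shared)
  expect_length(shared, 3)
  for (f in shared) {
    expect_identical(tr$true_log2fc[tr$feature == f & tr$arm == "protein"],
                     tr$true_log2fc[tr$feature == f & tr$arm == "rna"])
  }
  expect_identical(generate_paired_omics(op, 3), p3)
  expect_error(generate_paired_omics(op, n_shared_targets = 1000), "exceeds")
})
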
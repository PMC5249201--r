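test_that("sections are reproducible and hit the requested baseline fraction", {
  p <- small_section(seed = 71)
  a <- simulate_section(p)
  b <- simulate_section(p)
  expect_identical(a$truth$pixels, b$truth$pixels)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$exclusion$pixels, b$exclusion$pixels)
  expect_equal(a$truth_map$density, b$truth_map$density)

  # lesion-free truth mass reproduces the baseline septal fraction
  for (seed in 72:74) {
    sec <- simulate_section(small_section(seed = seed), render_rgb = FALSE)
    expect_lt(abs(mean(sec$truth$pixels) - 0.25), 0.01)
    expect_lt(abs(mean_density(sec$truth_map) - 0.25), 0.02)
  }
})

test_that("lesion coverage drives the high-density tile fraction", {
  sec <- simulate_section(section_params(width_um = 800, height_um = 800,
                                         lesion_coverage = 0.3,
                                         lesion_density = 0.9,
                                         lesion_radius_um = 40,
                                         n_vessels = 0L, seed = 75),
                          render_rgb = FALSE)
  expect_lt(abs(sec$coverage_achieved - 0.3), 0.05)
  d <- sec$truth_map$density[sec$truth_map$included]
  # pixel-count oracle on the generated truth: tiles at or above 0.55
  expect_lt(abs(mean(d >= 0.55) - 0.3), 0.05)

  expect_error(simulate_section(small_section(lesion_coverage = 0.95,
                                              lesion_radius_um = 2,
                                              seed = 76),
                                render_rgb = FALSE),
               "not reachable")
})

test_that("vessels are recorded in the exclusion mask and excluded from tiles", {
  sec <- simulate_section(section_params(width_um = 500, height_um = 500,
                                         n_vessels = 1L, seed = 77),
                          render_rgb = FALSE)
  expect_gt(sum(sec$exclusion$pixels), 0)
  # the exclusion disc must be wider than the 200 um criterion
  diam_um <- sqrt(sum(sec$exclusion$pixels) / pi) * 2 * sec$exclusion$pixel_size_um
  expect_gt(diam_um, 200)
  # no included tile overlaps the exclusion domain
  excl_red <- block_reduce_fraction(sec$exclusion, 4L)
  s <- sec$truth_map$grid$tile_side_px
  inc <- sec$truth_map$included
  for (i in which(inc[, 1])) {  # spot-check first tile column
    rows <- ((i - 1) * s + 1):(i * s)
    expect_true(all(excl_red$pixels[rows, 1:s] == 0))
  }
})

test_that("studies are reproducible and respond to dose", {
  sp <- study_params(n_control = 3L, n_per_dose = 3L, doses = c(0.5, 1),
                     section = small_section(), master_seed = 7)
  s1 <- simulate_study(sp)
  s2 <- simulate_study(sp)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$calibration$threshold_class,
                   s2$calibration$threshold_class)

  expect_true(all(diff(group_means(s1$table, "Dm")) > 0))
  expect_true(all(s1$calibration$control_mean_freq[
    s1$calibration$threshold_class:20] < s1$params$cutoff))
})

test_that("noise-free covariates are monotone in lesion burden", {
  sp <- study_params(n_control = 3L, n_per_dose = 3L, doses = c(0.25, 0.5, 1),
                     covariate_noise = list(ashcroft = 0, microct = 0,
                                            cdyn = 0, fvc = 0, lww = 0, bw = 0),
                     section = small_section(), master_seed = 9)
  st <- simulate_study(sp)
  tab <- st$table
  # perfect monotone links up to the ordinal rounding of the Ashcroft score
  expect_gt(correlate(tab, "HDFm", "ashcroft_score")$r, 0.9)
  expect_equal(cor(tab$coverage, tab$microct_hu_peak, method = "spearman"), 1)
  expect_equal(cor(tab$coverage, tab$cdyn, method = "spearman"), -1)
  expect_equal(cor(tab$coverage, tab$fvc, method = "spearman"), -1)
})

test_that("group-mean HDFm increases with dose across Monte-Carlo seeds", {
  for (seed in 1:20) {
    st <- simulate_study(study_params(n_control = 4L, n_per_dose = 6L,
                                      section = small_section(),
                                      master_seed = seed))
    hd <- group_means(st$table, "HDFm")
    expect_true(all(diff(hd) > 0), label = sprintf("seed %d monotone", seed))
  }
})
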
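test_that("luminance thresholding follows the scalar oracle", {
  p200 <- seg_params(luminance_threshold = 200)
  expect_true(all(segment_tissue(flat_section(3, 3, c(255, 255, 255)),
                                 p200)$pixels == 0L))

  img <- flat_section(4, 4, c(250, 250, 250))
  img$pixels[2, 3, ] <- c(60, 40, 90)   # luma 0.299*60+0.587*40+0.114*90 = 51.7
  m <- segment_tissue(img, p200)
  expect_identical(which(m$pixels == 1L), 10L)  # column-major index of (2,3)
  expect_equal(sum(m$pixels), 1L)
  # same pixel rejected by a threshold below its luminance
  expect_true(all(segment_tissue(img, seg_params(luminance_threshold = 40))$pixels == 0L))
})

test_that("segmentation is monotone in threshold and skips white sentinels", {
  set.seed(21)
  px <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), c(20L, 20L, 3L))
  px[1:3, 1:3, ] <- 255                      # erased region
  img <- section_image(px, 1)
  thrs <- c(40, 90, 140, 200, 254)
  masks <- lapply(thrs, function(t)
    segment_tissue(img, seg_params(luminance_threshold = t))$pixels)
  for (i in seq_along(thrs)[-1])
    expect_true(all(masks[[i]] >= masks[[i - 1]]))
  for (m in masks) expect_true(all(m[1:3, 1:3] == 0L))
})

test_that("soft fraction is a clamped ramp consistent with the binary mask", {
  p200 <- seg_params(luminance_threshold = 200)
  expect_equal(soft_tissue_fraction(flat_section(2, 2, c(0, 0, 0)),
                                    p200)$pixels[1, 1], 1.0)
  # luminance exactly at the threshold -> 0
  expect_equal(soft_tissue_fraction(flat_section(2, 2, c(200, 200, 200)),
                                    p200)$pixels[1, 1], 0.0)
  expect_equal(soft_tissue_fraction(flat_section(2, 2, c(100, 100, 100)),
                                    p200)$pixels[1, 1], 0.5)

  set.seed(22)
  px <- array(sample(0:255, 15 * 15 * 3, replace = TRUE), c(15L, 15L, 3L))
  img <- section_image(px, 1)
  hard <- segment_tissue(img, p200)$pixels
  soft <- soft_tissue_fraction(img, p200)$pixels
  expect_true(all(soft >= 0 & soft <= 1))
  expect_true(all(soft[hard == 1L] > 0))
})

test_that("footprint closes lumens, fills small holes and drops specks", {
  pitch <- 3.632
  pars <- seg_params(footprint_closing_radius_px = 0,
                     footprint_min_hole_px = 1000)  # > the 452 px test lumen
  # solid disk is a fixed point
  disk <- matrix(0L, 50, 50)
  d2 <- outer((1:50 - 25)^2, (1:50 - 25)^2, `+`)
  disk[d2 <= 15^2] <- 1L
  fp <- lung_footprint(binary_mask(disk, pitch), pars)
  expect_identical(fp$pixels, disk)

  # thin ring: the enclosed lumen (< min hole) is filled into the footprint
  ring <- matrix(0L, 50, 50)
  ring[d2 <= 15^2 & d2 >= 12^2] <- 1L
  lumen <- d2 < 12^2
  fp2 <- lung_footprint(binary_mask(ring, pitch), pars)
  expect_true(all(fp2$pixels[lumen] == 1L))
  # flood-fill oracle: filled footprint = ring + its interior
  expect_equal(fp2$pixels, matrix(as.integer(ring | lumen), 50L))

  # specks below the 0.1% component floor vanish (2 px in 200x200 = 40 px floor)
  specks <- matrix(0L, 200, 200)
  specks[10, 10:11] <- 1L; specks[100, 150:151] <- 1L
  fp3 <- lung_footprint(binary_mask(specks, pitch),
                        seg_params(footprint_closing_radius_px = 0,
                                   footprint_min_hole_px = 0))
  expect_true(all(fp3$pixels == 0L))

  expect_error(lung_footprint(binary_mask(matrix(0L, 5, 5), pitch), pars),
               "empty tissue")
})

test_that("inclusion is footprint minus exclusion", {
  fp <- binary_mask(matrix(1L, 6, 6), 1, "footprint")
  expect_true(all(inclusion_mask(fp, binary_mask(matrix(0L, 6, 6), 1,
                                                 "exclusion"))$pixels == 1L))
  expect_true(all(inclusion_mask(fp, binary_mask(matrix(1L, 6, 6), 1,
                                                 "exclusion"))$pixels == 0L))

  # disjoint rectangles: per-pixel boolean oracle
  fpx <- matrix(0L, 8, 8); fpx[1:4, 1:4] <- 1L
  epx <- matrix(0L, 8, 8); epx[6:8, 6:8] <- 1L
  inc <- inclusion_mask(binary_mask(fpx, 1, "footprint"),
                        binary_mask(epx, 1, "exclusion"))
  oracle <- matrix(0L, 8, 8)
  for (i in 1:8) for (j in 1:8) oracle[i, j] <- as.integer(fpx[i, j] == 1L && epx[i, j] == 0L)
  expect_identical(inc$pixels, oracle)
  expect_true(all(inc$pixels <= fpx))

  expect_error(inclusion_mask(fp, binary_mask(matrix(0L, 3, 3), 1, "exclusion")),
               "dimensions")
})

test_that("Otsu segmentation of a synthetic section recovers the truth mask", {
  sec <- simulate_section(section_params(width_um = 600, height_um = 600,
                                         lesion_coverage = 0.1,
                                         lesion_radius_um = 50, seed = 5))
  got <- segment_tissue(sec$image)$pixels
  truth <- sec$truth$pixels
  jaccard <- sum(got & truth) / sum(got | truth)
  expect_gt(jaccard, 0.95)
})
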
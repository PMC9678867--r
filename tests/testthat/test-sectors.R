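test_that("four quadrant sectors of a circle have equal areas", {
  ell <- cell_ellipse(101, 101, 60, 60)
  part <- partition_ellipse(ell, c(201, 201), n_sectors = 4)
  areas <- tabulate(part$labels[part$labels >= 0] + 1L, 4)
  expect_true(all(abs(areas - pi * 60^2 / 4) / (pi * 60^2 / 4) < 0.01))
})

test_that("sector labels partition the ellipse exactly", {
  ell <- cell_ellipse(90, 120, 70, 35, orientation_deg = 33)
  part <- partition_ellipse(ell, c(256, 256))
  inside <- ellipse_mask(ell, c(256, 256))
  expect_equal(sum(part$labels >= 0), sum(inside))
  expect_true(all(part$labels[inside] >= 0 & part$labels[inside] < 72))
  expect_true(all(part$labels[!inside] == -1L))
  areas <- tabulate(part$labels[inside] + 1L, 72)
  expect_equal(sum(areas), sum(inside))
})

test_that("pixels on a sector ray go to the higher sector", {
  # pixel exactly to the right of the centroid lies on the 0-degree ray
  ell <- cell_ellipse(11, 11, 8, 8)
  part <- partition_ellipse(ell, c(21, 21), n_sectors = 4)
  expect_equal(part$labels[11, 15], 0L)   # angle 0 -> sector 0 (half-open)
  expect_equal(part$labels[7, 11], 1L)    # angle 90 (y up) -> sector 1
  expect_equal(part$labels[11, 7], 2L)    # angle 180 -> sector 2
  expect_equal(part$labels[15, 11], 3L)   # angle 270 -> sector 3
})

test_that("ellipse outside the image is rejected", {
  ell <- cell_ellipse(500, 500, 20, 10)
  expect_error(partition_ellipse(ell, c(100, 100)), "outside")
})

test_that("uniform saturation gives sigma 1 and flat f_sigma", {
  ell <- cell_ellipse(101, 101, 60, 40, orientation_deg = 20)
  part <- partition_ellipse(ell, c(201, 201))
  inside <- ellipse_mask(ell, c(201, 201))
  pm <- patch_mask(inside, domain = inside,
                   centroid = c(101, 101))
  prof <- sector_sigma(part, pm)
  expect_true(all(prof$sigma == 1))
  expect_equal(prof$f_sigma, rep(1 / 72, 72))
  expect_equal(sum(prof$area_bright_px), sum(inside))
})

test_that("a delta patch lands in a single sector", {
  ell <- cell_ellipse(101, 101, 60, 40)
  part <- partition_ellipse(ell, c(201, 201))
  m <- matrix(FALSE, 201, 201)
  m[101, 130:134] <- TRUE; m[100, 130:134] <- TRUE  # small clump at angle ~0-2
  pm <- patch_mask(m, domain = ellipse_mask(ell, c(201, 201)),
                   centroid = c(101, 101))
  prof <- sector_sigma(part, pm)
  expect_equal(sum(prof$f_sigma > 0), 1)  # whole clump in the first sector
  expect_equal(prof$f_sigma[1], 1)
  expect_equal(sum(prof$f_sigma), 1, tolerance = 1e-9)
})

test_that("sigma estimates the bright fraction and stays within [0, 1]", {
  set.seed(17)
  ell <- cell_ellipse(151, 151, 110, 80)
  part <- partition_ellipse(ell, c(301, 301))
  inside <- ellipse_mask(ell, c(301, 301))
  bright <- inside & (matrix(runif(301^2), 301, 301) < 0.5)
  pm <- patch_mask(bright, domain = inside, centroid = c(151, 151))
  prof <- sector_sigma(part, pm)
  expect_true(all(prof$sigma >= 0 & prof$sigma <= 1))
  expect_true(all(abs(prof$sigma - 0.5) <= 0.1))
  # mean sigma weighted by area equals the global bright fraction exactly
  expect_equal(sum(prof$area_bright_px) / sum(prof$area_total_px),
               sum(bright) / sum(inside))
  expect_equal(sum(prof$f_sigma), 1, tolerance = 1e-9)
})

test_that("rotating ellipse and mask by one sector shifts the profile by one bin", {
  shape <- c(301, 301)
  mk_wedge_profile <- function(orient) {
    ell <- cell_ellipse(151, 151, 100, 100, orientation_deg = 0)
    # bright wedge between 10 and 40 degrees in a frame rotated by `orient`
    x <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
    y <- matrix(rep(seq_len(shape[1]), times = shape[2]), shape[1])
    ang <- (atan2(-(y - 151), x - 151) * 180 / pi - orient) %% 360
    inside <- ellipse_mask(ell, shape)
    wedge <- inside & ang >= 10 & ang < 40
    part <- partition_ellipse(cell_ellipse(151, 151, 100, 100, orient),
                              shape)
    sector_sigma(part, patch_mask(wedge, domain = inside,
                                  centroid = c(151, 151)))
  }
  p0 <- mk_wedge_profile(0)
  p5 <- mk_wedge_profile(5)
  # the same wedge seen in a frame rotated with the ellipse: identical sigma
  # up to discretization of the wedge edges (half the L1 distance counts
  # each misplaced pixel once)
  misassigned <- sum(abs(p5$area_bright_px - p0$area_bright_px)) / 2
  expect_lte(misassigned / sum(p0$area_bright_px), 0.02)
})

test_that("profile overlay aligns profiles and rejects mismatched sector counts", {
  ell <- cell_ellipse(101, 101, 60, 40)
  part <- partition_ellipse(ell, c(201, 201))
  inside <- ellipse_mask(ell, c(201, 201))
  pm <- patch_mask(inside, domain = inside, centroid = c(101, 101))
  prof <- sector_sigma(part, pm)
  ov <- profile_overlay(prof, prof)
  expect_equal(ov$f_sigma_1, ov$f_sigma_2)

  part4 <- partition_ellipse(ell, c(201, 201), n_sectors = 8)
  prof4 <- sector_sigma(part4, pm)
  expect_error(profile_overlay(prof, prof4), "sector counts")
})

test_that("mean sector density decreases from attaching to expanding cells", {
  # cohort geometry matters here: attaching cells are small, so the same
  # amount of actin fills a larger fraction of their contact-area
  cells <- generate_cohort(c(3, 0, 3), seed = 19)
  rep <- run_cohort(cells)
  ms <- vapply(rep$cells$profile, function(p) mean(p$sigma), 1.0)
  expect_gt(mean(ms[1:3]), mean(ms[4:6]))
})
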
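test_that("binarization is strictly greater-than at the threshold", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 0.25        # exactly at threshold: excluded
  m[2, 2] <- 0.2500001   # just above: included
  m[3, 3] <- 0.8
  m[4, 4] <- 0.3
  domain <- matrix(TRUE, 4, 4)
  pm <- binarize_patches(m, domain, centroid = c(2.5, 2.5))
  expect_false(pm$mask[1, 1])
  expect_true(pm$mask[2, 2])
  expect_equal(sum(pm$mask), 3)

  # inclusive variant picks up the boundary pixel
  pm2 <- binarize_patches(m, domain, centroid = c(2.5, 2.5), strict = FALSE)
  expect_true(pm2$mask[1, 1])

  expect_error(binarize_patches(matrix(0, 4, 4), domain, c(2.5, 2.5)),
               "no patches above threshold")

  # saturated domain: mask equals domain
  dom <- matrix(FALSE, 4, 4); dom[2:3, 2:3] <- TRUE
  pm3 <- binarize_patches(matrix(1, 4, 4), dom, c(2.5, 2.5))
  expect_equal(pm3$mask, dom)
})

test_that("hand-computed moment oracle is reproduced exactly", {
  # bright pixels at offsets (+-2, 0) and (0, +-1) from the centroid
  m <- matrix(FALSE, 7, 7)
  m[4, 2] <- TRUE; m[4, 6] <- TRUE  # (+-2, 0)
  m[3, 4] <- TRUE; m[5, 4] <- TRUE  # (0, +-1)
  ms <- central_moments(patch_mask(m, centroid = c(4, 4)))
  expect_identical(ms$mu20, 8)
  expect_identical(ms$mu02, 2)
  expect_identical(ms$mu11, 0)
  expect_identical(ms$phi1, 10)
  expect_identical(ms$phi2, 36)
  expect_equal(ms$lambda1, 32 * pi)
  expect_equal(ms$lambda2, 8 * pi)
  expect_equal(elongation_tirfm(ms), 1)
})

test_that("isotropic cross gives zero elongation", {
  m <- matrix(FALSE, 5, 5)
  m[3, 2] <- TRUE; m[3, 4] <- TRUE; m[2, 3] <- TRUE; m[4, 3] <- TRUE
  ms <- central_moments(patch_mask(m, centroid = c(3, 3)))
  expect_equal(ms$phi2, 0)
  expect_equal(ms$lambda1, ms$lambda2)
  expect_equal(elongation_tirfm(ms), 0)
})

test_that("collinear masks raise the degenerate error", {
  m <- matrix(FALSE, 5, 5)
  m[3, c(1, 5)] <- TRUE
  expect_error(central_moments(patch_mask(m, centroid = c(3, 3))),
               "degenerate")
  m[3, 2:4] <- TRUE  # still one row
  expect_error(central_moments(patch_mask(m, centroid = c(3, 3))),
               "degenerate")
})

test_that("production moments match the double-loop oracle on random masks", {
  set.seed(42)
  for (trial in seq_len(100)) {
    shape <- c(sample(8:24, 1), sample(8:24, 1))
    m <- matrix(runif(prod(shape)) < 0.3, shape[1], shape[2])
    if (sum(m) < 3) next
    centroid <- c(runif(1, 1, shape[2]), runif(1, 1, shape[1]))
    bf <- brute_force_moments(m, centroid)
    ms <- tryCatch(central_moments(patch_mask(m, centroid = centroid,
                                              domain = matrix(TRUE, shape[1], shape[2]))),
                   error = function(e) NULL)
    if (is.null(ms)) next  # degenerate draw
    expect_equal(ms$mu20, bf$mu20, tolerance = 1e-9)
    expect_equal(ms$mu02, bf$mu02, tolerance = 1e-9)
    expect_equal(ms$mu11, bf$mu11, tolerance = 1e-9)
    expect_equal(elongation_tirfm(ms), bf$e, tolerance = 1e-9)
  }
})

test_that("elongation is translation invariant exactly", {
  set.seed(5)
  m <- rasterize_points(runif(200, 20, 60), runif(200, 25, 45), c(200, 200))
  e0 <- mask_elongation(m)
  shifted <- matrix(FALSE, 200, 200)
  idx <- which(m, arr.ind = TRUE)
  shifted[cbind(idx[, 1] + 90, idx[, 2] + 110)] <- TRUE
  expect_identical(mask_elongation(shifted), e0)
})

test_that("elongation is rotation invariant within 0.03", {
  mask <- make_ellipse_mask(40, 15, shape = c(201, 201))
  e0 <- mask_elongation(mask)
  for (ang in c(15, 37, 90)) {
    er <- mask_elongation(rotate_mask_nn(mask, ang))
    expect_lt(abs(er - e0), 0.03)
  }
})

test_that("elongation is invariant under 2x nearest-neighbour upscaling", {
  mask <- make_ellipse_mask(35, 12, shape = c(151, 151))
  up <- kronecker(mask, matrix(TRUE, 2, 2))
  expect_lt(abs(mask_elongation(up) - mask_elongation(mask)), 0.02)
})

test_that("filled-ellipse elongation approaches the analytic log2(a/b)", {
  for (r in c(1, 2, 3, 4)) {
    mask <- make_ellipse_mask(60, 60 / r, shape = c(241, 241))
    expect_lt(abs(mask_elongation(mask) - log2(r)), 0.02)
  }
})

test_that("median elongation increases with the axial ratio of a Gaussian cloud", {
  set.seed(99)
  meds <- vapply(c(1, 2, 4, 8), function(r) {
    es <- vapply(seq_len(7), function(i) {
      u <- rnorm(500, 0, 20 * sqrt(r))
      v <- rnorm(500, 0, 20 / sqrt(r))
      mask_elongation(rasterize_points(250 + u, 250 + v, c(500, 500)))
    }, 1.0)
    stats::median(es)
  }, 1.0)
  expect_true(all(diff(meds) > 0))
})

test_that("stage classification uses the configured band edges", {
  expect_equal(as.character(classify_stage(0.72)$stage), "I_attaching")
  expect_equal(as.character(classify_stage(1.32)$stage), "II_spreading")
  expect_equal(as.character(classify_stage(1.95)$stage), "III_expanding")
  # boundary semantics: I iff e <= lower, III iff e >= upper
  expect_equal(as.character(classify_stage(1.0)$stage), "I_attaching")
  expect_equal(as.character(classify_stage(1.65)$stage), "III_expanding")
  # custom edges
  expect_equal(as.character(classify_stage(1.2, c(0.5, 1.1))$stage),
               "III_expanding")
  expect_error(classify_stage(1, c(2, 1)), "increasing")
})
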
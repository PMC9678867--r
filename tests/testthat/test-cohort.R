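test_that("pearson_correlation matches closed-form values and validates input", {
  expect_equal(pearson_correlation(1:5, 1:5), 1)
  expect_equal(pearson_correlation(1:5, -(1:5)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 4)), 0.9820,
               tolerance = 1e-4)
  expect_error(pearson_correlation(1:3, 1:4), "length")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "zero variance")
})

test_that("one-way ANOVA matches hand computation and conventions", {
  # SSB = 1.5 (df 1), SSW = 4 (df 4) -> F = 1.5
  res <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$statistic, 1.5)
  expect_equal(res$p.value, pf(1.5, 1, 4, lower.tail = FALSE))
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)

  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  degen <- anova_oneway(list(c(0, 0, 0, 0), c(1, 1, 1, 1)))
  expect_equal(degen$statistic, Inf)
  expect_equal(degen$p.value, 0)

  expect_error(anova_oneway(list(1:3)), "at least 2 groups")
  expect_error(anova_oneway(list(1:3, 5)), "at least 2 values")
})

test_that("correlation and ANOVA agree with textbook brute force on random input", {
  set.seed(314)
  for (trial in seq_len(100)) {
    x <- rnorm(sample(4:20, 1))
    y <- rnorm(length(x)) + 0.3 * x
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_correlation(x, y), num / den, tolerance = 1e-10)

    g <- lapply(seq_len(sample(2:4, 1)),
                function(i) rnorm(sample(2:8, 1), mean = i * 0.2))
    grand <- mean(unlist(g))
    ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 1.0))
    ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1.0))
    dfb <- length(g) - 1
    dfw <- length(unlist(g)) - length(g)
    f_ref <- (ssb / dfb) / (ssw / dfw)
    res <- anova_oneway(g)
    expect_equal(res$statistic, f_ref, tolerance = 1e-10)
    expect_equal(res$p.value, pf(f_ref, dfb, dfw, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("run_cell produces a complete record on a valid pair", {
  cell <- generate_cell(synth_config(stage = "II", seed = 21,
                                     image_size = c(320, 320),
                                     a_px = 85, b_px = 55))
  rec <- run_cell(cell$bfm, cell$tirfm, cell_id = "ok_cell")
  expect_true(is.na(rec$error))
  expect_equal(rec$cell_id, "ok_cell")
  expect_gt(rec$e_tirfm, 0)
  expect_gt(rec$n_bright_px, 0)
  expect_s3_class(rec$profile[[1]], "sector_profile")
  expect_equal(nrow(rec$profile[[1]]), 72)
  # moment bookkeeping is self-consistent
  expect_equal(rec$phi1, rec$mu20 + rec$mu02)
  expect_equal(rec$phi2, (rec$mu20 - rec$mu02)^2 + 4 * rec$mu11^2)
})

test_that("per-cell failures are contained, never fatal", {
  blank <- raw_image(matrix(10L, 64, 64), 8)
  tirfm <- raw_image(matrix(10L, 64, 64), 8)
  rec <- run_cell(blank, tirfm, cell_id = "blank")
  expect_match(rec$error, "no cell found")
  expect_true(is.na(rec$e_bfm))

  # a valid cell whose TIRF channel is flat: binarization finds nothing
  cell <- generate_cell(synth_config(stage = "I", seed = 2,
                                     image_size = c(256, 256),
                                     a_px = 70, b_px = 45))
  flat <- raw_image(matrix(0L, 256, 256), 8)
  rec2 <- run_cell(cell$bfm, flat, cell_id = "flat")
  expect_match(rec2$error, "no patches above threshold")
  expect_false(is.na(rec2$e_bfm))  # segmentation part still succeeded

  rec3 <- run_cell(cell$bfm, raw_image(matrix(0L, 32, 32), 8))
  expect_match(rec3$error, "different dimensions")
})

test_that("cohort report aggregates per-cell records and statistics", {
  base <- synth_config(image_size = c(256, 256), a_px = 70, b_px = 45)
  cells <- generate_cohort(c(3, 3, 3), base_cfg = base, seed = 11)
  rep <- run_cohort(cells)
  expect_s3_class(rep, "cohort_report")
  td <- tidy(rep)
  expect_equal(nrow(td), 9)
  expect_true(all(is.na(td$error)))
  expect_equal(sum(rep$n_per_stage), 9)
  gl <- glance(rep)
  expect_equal(gl$n_cells, 9L)
  expect_true(gl$pearson_r >= -1 && gl$pearson_r <= 1)
  expect_true(all(diff(rep$stage_summary$mean_e_tirfm) > 0))
})

test_that("report files are byte-identical across reruns", {
  base <- synth_config(image_size = c(256, 256), a_px = 70, b_px = 45)
  run_once <- function(dir) {
    cells <- generate_cohort(c(2, 0, 2), base_cfg = base, seed = 13)
    write_cohort_report(run_cohort(cells), dir)
    dir
  }
  d1 <- run_once(withr::local_tempdir())
  d2 <- run_once(withr::local_tempdir())
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("config files round-trip through YAML and JSON", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(threshold = 0.3, n_sectors = 36,
                        band_edges = c(0.9, 1.7)), path)
  cfg <- read_config(path)
  expect_equal(cfg$threshold, 0.3)
  expect_equal(cfg$n_sectors, 36L)
  expect_equal(cfg$band_edges, c(0.9, 1.7))
  expect_equal(cfg$n_bins, 20L)  # untouched default

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(threshold = 0.2), jpath, auto_unbox = TRUE)
  expect_equal(read_config(jpath)$threshold, 0.2)

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(thresh = 0.3), bad)
  expect_error(read_config(bad), "unknown config keys")
})
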
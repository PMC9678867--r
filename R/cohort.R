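#' Analysis pipeline configuration
#'
#' One flat list holding every tunable constant of the pipeline; nothing in
#' the analysis logic is hard-coded. The defaults are the method's standard
#' operating point.
#'
#' @param threshold Normalized-intensity binarization cutoff (default 0.25).
#' @param n_sectors Number of equal-angle sectors (default 72).
#' @param band_edges Stage-classification edges `c(lower, upper)`
#'   (default `c(1.0, 1.65)`).
#' @param n_bins Intensity-histogram bin count (default 20).
#' @param pixel_size_nm Physical pixel size (default 22).
#' @param centroid_mode Moment origin: `"ellipse"` (fitted-ellipse centroid,
#'   default) or `"mask"` (bright-mask centre of mass).
#' @param sector_domain Domain whose bright pixels enter the sector profile:
#'   `"ellipse"` (default) or `"boundary"` (the traced cell mask).
#' @param strict_threshold Use strict `>` at the threshold (default `TRUE`).
#' @param ellipse_method Ellipse fit: `"moments"` (default) or `"contour"`.
#' @param boundary_polarity Passed to [detect_boundary()] (default
#'   `"auto"`).
#' @param min_area_px Minimum cell area for segmentation (default 200).
#'
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = 0.25,
                            n_sectors = 72,
                            band_edges = c(1.0, 1.65),
                            n_bins = 20,
                            pixel_size_nm = 22,
                            centroid_mode = c("ellipse", "mask"),
                            sector_domain = c("ellipse", "boundary"),
                            strict_threshold = TRUE,
                            ellipse_method = c("moments", "contour"),
                            boundary_polarity = c("auto", "bright", "dark"),
                            min_area_px = 200) {
  structure(
    list(threshold = threshold, n_sectors = as.integer(n_sectors),
         band_edges = band_edges, n_bins = as.integer(n_bins),
         pixel_size_nm = pixel_size_nm,
         centroid_mode = match.arg(centroid_mode),
         sector_domain = match.arg(sector_domain),
         strict_threshold = isTRUE(strict_threshold),
         ellipse_method = match.arg(ellipse_method),
         boundary_polarity = match.arg(boundary_polarity),
         min_area_px = as.integer(min_area_px)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys missing from the file keep their [pipeline_config()] defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be YAML or JSON", call. = FALSE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

empty_cell_row <- function(cell_id) {
  tibble::tibble(
    cell_id = cell_id,
    e_bfm = NA_real_, e_tirfm = NA_real_,
    stage = factor(NA_character_, levels = stage_levels()),
    centroid_x = NA_real_, centroid_y = NA_real_,
    a_px = NA_real_, b_px = NA_real_, orientation_deg = NA_real_,
    mu20 = NA_real_, mu02 = NA_real_, mu11 = NA_real_,
    phi1 = NA_real_, phi2 = NA_real_,
    n_bright_px = NA_integer_, threshold = NA_real_,
    frac_bright = NA_real_,
    profile = list(NULL),
    error = NA_character_
  )
}

#' Run the full pipeline on one image pair
#'
#' Executes normalize, boundary detection, ellipse fit, footprint elongation,
#' binarization, central moments, patch elongation, stage classification and
#' the sector profile, end to end. A failure at any stage is captured into
#' the record's `error` field so that batch runs never abort on a single bad
#' cell.
#'
#' @param bfm,tirfm [raw_image()] objects or file paths of the bright-field
#'   and TIRF frames (same dimensions).
#' @param config A [pipeline_config()].
#' @param cell_id Identifier recorded in the output row.
#'
#' @return A one-row tibble with per-cell quantities (`e_bfm`, `e_tirfm`,
#'   `stage`, ellipse parameters, moments, `frac_bright` — fraction of
#'   in-cell pixels with normalized intensity in \[0.75, 1\]), a `profile`
#'   list-column holding the [sector_sigma()] tibble, and `error` (`NA` on
#'   success).
#' @export
run_cell <- function(bfm, tirfm, config = pipeline_config(),
                     cell_id = "cell") {
  row <- empty_cell_row(cell_id)
  tryCatch({
    if (is.character(bfm)) bfm <- load_image(bfm, config$pixel_size_nm)
    if (is.character(tirfm)) tirfm <- load_image(tirfm, config$pixel_size_nm)
    if (!identical(dim(bfm$pixels), dim(tirfm$pixels))) {
      stop("BFM and TIRFM images have different dimensions", call. = FALSE)
    }

    bfm_n <- normalize_intensity(bfm)
    boundary <- detect_boundary(bfm_n, min_area_px = config$min_area_px,
                                polarity = config$boundary_polarity)
    ellipse <- fit_ellipse(boundary, method = config$ellipse_method)
    row$e_bfm <- elongation_bfm(ellipse)
    row$centroid_x <- ellipse$centroid_x
    row$centroid_y <- ellipse$centroid_y
    row$a_px <- ellipse$a; row$b_px <- ellipse$b
    row$orientation_deg <- ellipse$orientation_deg

    # normalize the TIRF frame over the cell's own dynamic range
    tirfm_n <- normalize_intensity(tirfm, roi = boundary$mask)
    hist <- intensity_histogram(tirfm_n, roi = boundary$mask,
                                n_bins = config$n_bins)
    row$frac_bright <- attr(hist, "frac_bright")

    centroid <- c(ellipse$centroid_x, ellipse$centroid_y)
    patches <- binarize_patches(tirfm_n, domain = boundary$mask,
                                centroid = centroid,
                                threshold = config$threshold,
                                strict = config$strict_threshold)
    if (config$centroid_mode == "mask") {
      idx <- which(patches$mask, arr.ind = TRUE)
      patches$centroid <- c(mean(idx[, 2]), mean(idx[, 1]))
    }
    m <- central_moments(patches)
    row$mu20 <- m$mu20; row$mu02 <- m$mu02; row$mu11 <- m$mu11
    row$phi1 <- m$phi1; row$phi2 <- m$phi2
    row$n_bright_px <- m$n_px
    row$threshold <- config$threshold
    row$e_tirfm <- elongation_tirfm(m)
    call <- classify_stage(row$e_tirfm, config$band_edges)
    row$stage <- call$stage

    part <- partition_ellipse(ellipse, dim(bfm$pixels),
                              n_sectors = config$n_sectors)
    sector_patches <- if (config$sector_domain == "boundary") {
      patches
    } else {
      pm <- patches
      pm$mask <- pm$mask & (part$labels >= 0L)
      pm
    }
    row$profile <- list(sector_sigma(part, sector_patches))
    row
  }, error = function(e) {
    row$error <- conditionMessage(e)
    row
  })
}

#' Run the pipeline over a cohort of image pairs
#'
#' @param cells Either the output of [generate_cohort()], or a data
#'   frame/tibble with columns `bfm`, `tirfm` (paths or [raw_image()]
#'   list-columns) and optionally `cell_id`.
#' @param config A [pipeline_config()].
#'
#' @return An object of class `cohort_report`: list with `cells` (per-cell
#'   tibble including a `truth_stage` column when ground truth is known),
#'   `pearson_r` (correlation of `e_bfm` and `e_tirfm`), `anova` (one-row
#'   tibble `statistic`, `p.value`, `df_between`, `df_within` for
#'   `e_tirfm` grouped by called stage), `n_per_stage`, and `stage_summary`
#'   (mean and sd of `e_tirfm` per called stage).
#' @export
run_cohort <- function(cells, config = pipeline_config()) {
  if (is.data.frame(cells)) {
    ids <- if ("cell_id" %in% names(cells)) cells$cell_id else
      sprintf("cell_%03d", seq_len(nrow(cells)))
    rows <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
      run_cell(cells$bfm[[i]], cells$tirfm[[i]], config, cell_id = ids[i])
    })
    truth <- NULL
  } else {
    rows <- purrr::map_dfr(cells, function(cell) {
      run_cell(cell$bfm, cell$tirfm, config, cell_id = cell$cell_id)
    })
    truth <- purrr::map_chr(cells, function(cell) cell$truth$stage %||% NA_character_)
  }
  if (!is.null(truth)) {
    rows$truth_stage <- factor(paste0(
      truth, c(I = "_attaching", II = "_spreading", III = "_expanding")[truth]),
      levels = stage_levels())
  }
  ok <- rows[is.na(rows$error), ]

  pearson_r <- if (nrow(ok) >= 3L &&
                   sd(ok$e_bfm) > 0 && sd(ok$e_tirfm) > 0) {
    pearson_correlation(ok$e_bfm, ok$e_tirfm)
  } else NA_real_

  groups <- split(ok$e_tirfm, droplevels(ok$stage))
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  anova <- if (length(groups) >= 2L) anova_oneway(groups) else NULL

  n_per_stage <- table(factor(ok$stage, levels = stage_levels()))
  stage_summary <- ok |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_e_tirfm = mean(.data$e_tirfm),
                     sd_e_tirfm = sd(.data$e_tirfm),
                     mean_e_bfm = mean(.data$e_bfm),
                     .groups = "drop")

  structure(
    list(cells = rows, pearson_r = pearson_r, anova = anova,
         n_per_stage = as.integer(n_per_stage),
         stage_summary = stage_summary, config = config),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  n_ok <- sum(is.na(x$cells$error))
  cat(sprintf("<cohort_report> %d cells (%d analysed)\n",
              nrow(x$cells), n_ok))
  cat(sprintf("  stage counts (I/II/III): %s\n",
              paste(x$n_per_stage, collapse = "/")))
  if (!is.na(x$pearson_r)) {
    cat(sprintf("  Pearson r(E_BFM, E_TIRFM) = %.3f\n", x$pearson_r))
  }
  if (!is.null(x$anova)) {
    cat(sprintf("  one-way ANOVA across stages: F = %.3g, p = %.3g\n",
                x$anova$statistic, x$anova$p.value))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collect a cohort of image pairs from a directory
#'
#' Pairs `*_bfm.tif` with `*_tirfm.tif` files sharing a prefix (the layout
#' written by [write_cohort()]).
#'
#' @param dir Directory containing the image pairs.
#' @return A tibble with columns `cell_id`, `bfm`, `tirfm` (file paths),
#'   ready for [run_cohort()].
#' @export
cohort_from_dir <- function(dir) {
  bfm <- sort(list.files(dir, pattern = "_bfm\\.(tif|tiff|png)$",
                         full.names = TRUE))
  if (length(bfm) == 0L) {
    stop(sprintf("no *_bfm image files found in %s", dir), call. = FALSE)
  }
  ids <- sub("_bfm\\.[^.]+$", "", basename(bfm))
  tirfm <- file.path(dirname(bfm),
                     sub("_bfm\\.", "_tirfm.", basename(bfm)))
  missing <- !file.exists(tirfm)
  if (any(missing)) {
    stop(sprintf("missing TIRFM mate for: %s",
                 paste(ids[missing], collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(cell_id = ids, bfm = bfm, tirfm = tirfm)
}

#' Pearson correlation coefficient
#'
#' Thin validated wrapper around [stats::cor()] for the footprint-vs-patch
#' elongation correlation.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  cor(x, y)
}

#' Classical one-way ANOVA
#'
#' Equal-variance one-way analysis of variance via
#' [stats::oneway.test()]. When every group has zero internal variance but
#' the group means differ, the F statistic is reported as `Inf` with
#' `p = 0` (the documented degenerate convention).
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return One-row tibble with `statistic` (F), `p.value`, `df_between`,
#'   `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2L)) stop("every group needs at least 2 values",
                            call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  grand <- mean(values)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1.0))
  ssb <- sum(sizes * (vapply(groups, mean, 1.0) - grand)^2)
  if (ssw == 0) {
    if (ssb == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
    f <- unname(ft$statistic)
    p <- ft$p.value
  }
  tibble::tibble(statistic = f, p.value = p,
                 df_between = df_b, df_within = df_w)
}

#' Write cohort report files
#'
#' Writes `cells.csv` (per-cell records), one `profile_<cell_id>.csv` per
#' analysed cell, `stage_summary.csv` (mean and sd of the elongation score
#' per called stage) and `cohort_stats.json` (correlation, ANOVA, counts).
#' Output is byte-stable across reruns of the same cohort and configuration.
#'
#' @param report A `cohort_report` from [run_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- report$cells
  for (i in seq_len(nrow(cells))) {
    prof <- cells$profile[[i]]
    if (!is.null(prof)) {
      write_profile(prof, file.path(dir, sprintf("profile_%s.csv",
                                                 cells$cell_id[i])))
    }
  }
  flat <- cells[, setdiff(names(cells), "profile")]
  flat$stage <- as.character(flat$stage)
  write.csv(as.data.frame(flat), file.path(dir, "cells.csv"),
            row.names = FALSE)
  ss <- report$stage_summary
  ss$stage <- as.character(ss$stage)
  write.csv(as.data.frame(ss), file.path(dir, "stage_summary.csv"),
            row.names = FALSE)
  stats <- list(
    n_cells = nrow(cells),
    n_analysed = sum(is.na(cells$error)),
    n_per_stage = report$n_per_stage,
    pearson_r = report$pearson_r
  )
  if (!is.null(report$anova)) {
    stats$anova_f <- report$anova$statistic
    stats$anova_p <- report$anova$p.value
  }
  jsonlite::write_json(stats, file.path(dir, "cohort_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
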
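#' Configuration for the synthetic cell-image generator
#'
#' Describes one synthetic bright-field / TIRF image pair: an elliptical cell
#' footprint plus bright F-actin-like patches whose spatial dispersion and
#' anisotropy emulate the three adhesion stages — stage I (attaching): a
#' central, near-isotropic clump; stage II (spreading): intermediate
#' dispersion; stage III (expanding): patches scattered over the whole
#' contact-area along a polarization axis. Stage presets fix
#' `(dispersion, anisotropy)` at I (0.35, 1), II (0.7, 2.5), III (1.0, 4);
#' passing either argument explicitly overrides the preset.
#'
#' @param image_size `c(rows, cols)`, default `c(512, 512)`.
#' @param a_px,b_px Ellipse semi-axes in pixels (defaults 120 and 80).
#' @param orientation_deg Major-axis orientation, degrees (default 25).
#' @param stage `"I"`, `"II"` or `"III"` (default `"II"`).
#' @param n_patches Number of patch centres (default 150).
#' @param patch_sigma_px Gaussian spot width of one rendered patch
#'   (default 3; the minor semi-axis must exceed `4 * patch_sigma_px`).
#' @param dispersion Fraction of the ellipse radius over which patch centres
#'   scatter, in (0, 1\]; `NULL` takes the stage preset.
#' @param anisotropy Axial ratio (>= 1) of the patch-placement distribution;
#'   `NULL` takes the stage preset.
#' @param noise_sd Additive Gaussian camera noise, in normalized intensity
#'   units (default 0.02).
#' @param bit_depth Camera bit depth for quantization (default 8).
#' @param seed Integer RNG seed (default 1).
#'
#' @return An object of class `synth_config` (a named list).
#' @export
synth_config <- function(image_size = c(512, 512),
                         a_px = 120, b_px = 80,
                         orientation_deg = 25,
                         stage = c("II", "I", "III"),
                         n_patches = 150,
                         patch_sigma_px = 3,
                         dispersion = NULL,
                         anisotropy = NULL,
                         noise_sd = 0.02,
                         bit_depth = 8,
                         seed = 1) {
  stage <- match.arg(stage)
  preset <- stage_presets()[[stage]]
  if (is.null(dispersion)) dispersion <- preset[["dispersion"]]
  if (is.null(anisotropy)) anisotropy <- preset[["anisotropy"]]
  if (a_px < b_px) stop("`a_px` must be >= `b_px`", call. = FALSE)
  if (b_px <= 4 * patch_sigma_px) {
    stop("`b_px` must exceed 4 * patch_sigma_px", call. = FALSE)
  }
  if (dispersion <= 0 || dispersion > 1) {
    stop("`dispersion` must lie in (0, 1]", call. = FALSE)
  }
  if (anisotropy < 1) stop("`anisotropy` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (n_patches < 1) stop("`n_patches` must be positive", call. = FALSE)
  structure(
    list(image_size = as.integer(image_size), a_px = a_px, b_px = b_px,
         orientation_deg = orientation_deg, stage = stage,
         n_patches = as.integer(n_patches),
         patch_sigma_px = patch_sigma_px,
         dispersion = dispersion, anisotropy = anisotropy,
         noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Adhesion-stage presets of the generator
#'
#' @return Named list mapping stage `"I"`/`"II"`/`"III"` to
#'   `c(dispersion, anisotropy)`.
#' @export
stage_presets <- function() {
  list(I   = c(dispersion = 0.35, anisotropy = 1),
       II  = c(dispersion = 0.70, anisotropy = 2.5),
       III = c(dispersion = 1.00, anisotropy = 4))
}

# Internal placement calibration, frozen after one calibration pass: patch
# centres scatter along each ellipse axis with
#   s_u = 0.5 * dispersion * a
#   s_v = 0.5 * dispersion * b / d(anisotropy),
#   d(anisotropy) = C0 + C1 * (anisotropy - 1)^Q
# i.e. the dispersion is a fraction of each semi-axis and the anisotropy
# compresses the minor-axis spread. The affine-power form of d compensates
# the elongation lost to truncation at the ellipse boundary for widely
# dispersed stages; C0, C1 and Q were chosen so the three stage presets land
# in the elongation bands 0.72 +/- 0.16, 1.32 +/- 0.20 and 1.95 +/- 0.17 at
# the default geometry.
synth_calibration <- function() {
  list(c0 = 1.17, c1 = 0.354, q = 1.65, margin = 0.97)
}

# Sample n patch centres in the ellipse frame by rejection from a truncated
# anisotropic Gaussian; guaranteed inside the (slightly shrunk) ellipse.
sample_patch_centres <- function(n, a, b, dispersion, anisotropy) {
  cal <- synth_calibration()
  d <- cal$c0 + cal$c1 * (anisotropy - 1)^cal$q
  s_u <- 0.5 * dispersion * a
  s_v <- 0.5 * dispersion * b / d
  am <- a * cal$margin; bm <- b * cal$margin
  u <- numeric(0); v <- numeric(0)
  guard <- 0L
  while (length(u) < n) {
    m <- 4L * (n - length(u)) + 16L
    uu <- rnorm(m, 0, s_u); vv <- rnorm(m, 0, s_v)
    keep <- (uu / am)^2 + (vv / bm)^2 < 1
    u <- c(u, uu[keep]); v <- c(v, vv[keep])
    guard <- guard + 1L
    if (guard > 1000L) stop("patch-centre sampling failed to converge",
                            call. = FALSE)
  }
  cbind(u = u[seq_len(n)], v = v[seq_len(n)])
}

# Add a Gaussian spot of the given amplitude/width at (x0, y0) into `img`
# (matrix, row = y), touching only a local window.
add_spot <- function(img, x0, y0, amplitude, sigma) {
  w <- ceiling(3.5 * sigma)
  rows <- max(1L, floor(y0) - w):min(nrow(img), ceiling(y0) + w)
  cols <- max(1L, floor(x0) - w):min(ncol(img), ceiling(x0) + w)
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  dy2 <- (rows - y0)^2
  dx2 <- (cols - x0)^2
  img[rows, cols] <- img[rows, cols] +
    amplitude * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  img
}

quantize <- function(v, bit_depth) {
  v[v < 0] <- 0; v[v > 1] <- 1
  round(v * (2^bit_depth - 1))
}

#' Generate one synthetic bright-field / TIRF image pair
#'
#' Renders a bright-field frame (bright elliptical cell footprint on a darker
#' background, plus additive Gaussian noise) and a TIRF frame (sum of
#' Gaussian spots at patch centres drawn from a truncated anisotropic
#' Gaussian aligned with the ellipse axes, plus noise), both quantized to the
#' configured bit depth. The same seed reproduces bit-identical images.
#' Shot noise and evanescent-field depth decay are deliberately not
#' modelled: the analysis this generator exercises discards intensity values
#' at the binarization step.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements `bfm` and `tirfm` ([raw_image()] pair) and
#'   `truth`: a list holding the ground-truth `ellipse` ([cell_ellipse()]),
#'   `stage`, `patch_centres` (tibble of image-coordinate `x`, `y`) and
#'   `expected_e_bfm`.
#' @export
generate_cell <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  ell <- cell_ellipse(cx, cy, cfg$a_px, cfg$b_px, cfg$orientation_deg)
  inside <- ellipse_mask(ell, c(nr, nc))

  # bright-field: cell at 0.75, background 0.25 (contrast >= 5 * noise_sd)
  bfm <- matrix(0.25, nr, nc)
  bfm[inside] <- 0.75
  bfm <- bfm + rnorm(nr * nc, 0, cfg$noise_sd)

  phi <- cfg$orientation_deg * pi / 180
  for (attempt in seq_len(10L)) {
    uv <- sample_patch_centres(cfg$n_patches, cfg$a_px, cfg$b_px,
                               cfg$dispersion, cfg$anisotropy)
    px <- cx + uv[, "u"] * cos(phi) - uv[, "v"] * sin(phi)
    py <- cy - (uv[, "u"] * sin(phi) + uv[, "v"] * cos(phi))
    ok <- px >= 1 & px <= nc & py >= 1 & py <= nr
    if (sum(ok) >= min(3L, cfg$n_patches)) break
    if (attempt == 10L) {
      stop("could not place at least 3 patches inside the image",
           call. = FALSE)
    }
  }
  px <- px[ok]; py <- py[ok]

  tirfm <- matrix(0, nr, nc)
  amp <- runif(length(px), 0.7, 1)
  for (i in seq_along(px)) {
    tirfm <- add_spot(tirfm, px[i], py[i], amp[i], cfg$patch_sigma_px)
  }
  tirfm <- tirfm + rnorm(nr * nc, 0, cfg$noise_sd)

  list(
    bfm = raw_image(quantize(bfm, cfg$bit_depth), cfg$bit_depth),
    tirfm = raw_image(quantize(tirfm, cfg$bit_depth), cfg$bit_depth),
    truth = list(
      ellipse = ell,
      stage = cfg$stage,
      patch_centres = tibble::tibble(x = px, y = py),
      expected_e_bfm = log2(cfg$a_px / cfg$b_px)
    )
  )
}

# Stage-dependent geometry ranges for cohort cells: attaching cells are
# small and near-circular, expanding cells large and elongated. Sizes are
# stated for a 512 px frame and scaled with the configured frame size.
cohort_geometry <- function(stage) {
  switch(stage,
    I   = list(a = runif(1, 45, 62),   ratio = runif(1, 1.05, 1.35)),
    II  = list(a = runif(1, 80, 110),  ratio = runif(1, 1.3, 1.7)),
    III = list(a = runif(1, 110, 140), ratio = runif(1, 2.2, 3.0))
  )
}

#' Generate a seeded cohort of synthetic cells
#'
#' Produces `sum(n_per_stage)` image pairs with per-cell seeds derived
#' deterministically from the cohort seed. Cell geometry co-varies with
#' stage (attaching cells near-circular, expanding cells elongated), so the
#' cohort reproduces the qualitative coupling between footprint elongation
#' and patch-distribution elongation seen in real adherent cells.
#'
#' @param n_per_stage Integer triple `c(nI, nII, nIII)`; default
#'   `c(17, 19, 12)`, a 48-cell cohort.
#' @param base_cfg Template [synth_config()] supplying image size, patch
#'   rendering and noise parameters.
#' @param seed Cohort seed (integer).
#' @return A list of cells; each element is the [generate_cell()] output
#'   plus a `cell_id` field.
#' @export
generate_cohort <- function(n_per_stage = c(17, 19, 12),
                            base_cfg = synth_config(),
                            seed = 1) {
  stopifnot(length(n_per_stage) == 3L, all(n_per_stage >= 0))
  stages <- rep(c("I", "II", "III"), times = n_per_stage)
  n <- length(stages)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n)
  geoms <- lapply(stages, cohort_geometry)
  orients <- runif(n, -90, 90)
  scale <- min(base_cfg$image_size) / 512
  purrr::map(seq_len(n), function(i) {
    g <- geoms[[i]]
    cfg <- synth_config(
      image_size = base_cfg$image_size,
      a_px = g$a * scale, b_px = g$a * scale / g$ratio,
      orientation_deg = orients[i],
      stage = stages[i],
      n_patches = base_cfg$n_patches,
      patch_sigma_px = base_cfg$patch_sigma_px,
      noise_sd = base_cfg$noise_sd,
      bit_depth = base_cfg$bit_depth,
      seed = cell_seeds[i]
    )
    cell <- generate_cell(cfg)
    cell$cell_id <- sprintf("cell_%03d", i)
    cell
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes `cell_<id>_bfm.tif` / `cell_<id>_tirfm.tif` pairs and a
#' `ground_truth.csv` table (cell_id, stage, a_px, b_px, orientation_deg,
#' expected_e_bfm).
#'
#' @param cells Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The ground-truth tibble, invisibly.
#' @export
write_cohort <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- purrr::map_dfr(cells, function(cell) {
    write_image(cell$bfm, file.path(dir, paste0(cell$cell_id, "_bfm.tif")))
    write_image(cell$tirfm, file.path(dir, paste0(cell$cell_id, "_tirfm.tif")))
    e <- cell$truth$ellipse
    tibble::tibble(cell_id = cell$cell_id, stage = cell$truth$stage,
                   a_px = e$a, b_px = e$b,
                   orientation_deg = e$orientation_deg,
                   expected_e_bfm = cell$truth$expected_e_bfm)
  })
  write.csv(as.data.frame(truth), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(truth)
}
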
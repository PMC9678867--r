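#' Normalized intensity image
#'
#' Internal constructor for a single-channel image with intensities mapped to
#' the unit interval; houses the I(x, y) field every downstream moment and
#' sector computation consumes.
#'
#' @param pixels Numeric matrix with values in \[0, 1\].
#' @param source_bit_depth Bit depth of the image the values came from.
#' @return An object of class `norm_image`.
#' @keywords internal
norm_image <- function(pixels, source_bit_depth = NA_integer_) {
  stopifnot(is.matrix(pixels), min(pixels) >= 0, max(pixels) <= 1)
  structure(list(pixels = pixels,
                 source_bit_depth = as.integer(source_bit_depth)),
            class = "norm_image")
}

#' @export
print.norm_image <- function(x, ...) {
  cat(sprintf("<norm_image> %d x %d px, range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.norm_image <- function(x) dim(x$pixels)

#' Min-max normalize image intensity to \[0, 1\]
#'
#' Maps camera counts to normalized intensity
#' `I_norm = (I - I_min) / (I_max - I_min)`. When a region of interest is
#' supplied the min and max are taken over the ROI only (so that the cell's
#' own dynamic range spans the full unit interval) and values outside the ROI
#' are clipped to \[0, 1\]. A constant image maps to all zeros, so downstream
#' thresholding yields an empty patch mask with a clear error rather than NaN
#' propagation.
#'
#' The map is idempotent on non-constant input and invariant to affine
#' rescaling of camera counts (gain and offset).
#'
#' @param img A [raw_image()], a `norm_image`, or a numeric matrix.
#' @param roi Optional logical matrix of the same shape selecting the region
#'   over which the min and max are computed; needs at least 2 `TRUE` pixels.
#'
#' @return A `norm_image`.
#' @export
normalize_intensity <- function(img, roi = NULL) {
  px <- as_pixel_matrix(img)
  bd <- if (inherits(img, "raw_image")) img$bit_depth else
    if (inherits(img, "norm_image")) img$source_bit_depth else NA_integer_
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(px))) {
      stop("`roi` must have the same shape as the image", call. = FALSE)
    }
    roi <- roi > 0
    if (sum(roi) < 2L) {
      stop("`roi` must contain at least 2 pixels", call. = FALSE)
    }
    lo <- min(px[roi]); hi <- max(px[roi])
  } else {
    lo <- min(px); hi <- max(px)
  }
  if (hi > lo) {
    out <- (px - lo) / (hi - lo)
    out[out < 0] <- 0
    out[out > 1] <- 1
  } else {
    out <- matrix(0, nrow(px), ncol(px))
  }
  norm_image(out, source_bit_depth = bd)
}

#' Per-pixel normalized-intensity histogram
#'
#' Tabulates the distribution of normalized intensity over a region of
#' interest using equal-width bins on \[0, 1\] (left-closed, right-open,
#' except the last bin which is closed at 1). Also reports the aggregate
#' fraction of pixels in the bright band \[0.75, 1\], which discriminates the
#' early (attaching) adhesion stage with its concentrated, bright actin clump
#' from the later, dispersed stages. With `n_bins = 4` the bins reproduce the
#' coarse 0.25-wide intensity bands conventionally used for such summaries.
#'
#' @param img A `norm_image` (or matrix of values in \[0, 1\]).
#' @param roi Logical matrix selecting the pixels to tabulate (same shape as
#'   the image, at least one `TRUE` pixel).
#' @param n_bins Number of equal-width bins (default 20).
#'
#' @return A tibble of class `intensity_histogram` with columns `bin_lo`,
#'   `bin_hi` and `frequency` (fractions summing to 1), plus attributes
#'   `n_pixels` and `frac_bright` (fraction of ROI pixels in \[0.75, 1\]).
#' @export
intensity_histogram <- function(img, roi, n_bins = 20) {
  px <- as_pixel_matrix(img)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  if (!identical(dim(roi), dim(px))) {
    stop("`roi` must have the same shape as the image", call. = FALSE)
  }
  roi <- roi > 0
  if (!any(roi)) stop("`roi` is empty", call. = FALSE)
  v <- px[roi]
  if (any(v < 0) || any(v > 1)) {
    stop("histogram input must be normalized to [0, 1]", call. = FALSE)
  }
  # left-closed bins [k/n, (k+1)/n); v = 1 falls in the last bin
  idx <- pmin(floor(v * n_bins) + 1L, n_bins)
  freq <- tabulate(idx, nbins = n_bins) / length(v)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  out <- tibble::tibble(
    bin_lo = edges[-(n_bins + 1L)],
    bin_hi = edges[-1L],
    frequency = freq
  )
  attr(out, "n_pixels") <- length(v)
  attr(out, "frac_bright") <- mean(v >= 0.75)
  class(out) <- c("intensity_histogram", class(out))
  out
}
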
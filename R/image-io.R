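#' Raw microscopy image
#'
#' A single-channel image of integer camera counts together with its bit depth
#' and the physical pixel size. This is the entry container for both
#' bright-field (BFM) and TIRF fluorescence (TIRFM) frames.
#'
#' @param pixels Integer-valued matrix of camera counts (rows = y, cols = x).
#' @param bit_depth Camera bit depth, 8 or 16.
#' @param pixel_size_nm Physical edge length of one mapped pixel in
#'   nanometres. The default 22 nm corresponds to a high-magnification TIRF
#'   setup where one camera pixel maps to about 22 x 22 nm on the specimen.
#'
#' @return An object of class `raw_image` with fields `pixels`, `bit_depth`
#'   and `pixel_size_nm`.
#' @export
raw_image <- function(pixels, bit_depth, pixel_size_nm = 22) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("image must have at least 2 rows and 2 columns", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1)) {
    stop("pixel values must lie in [0, 2^bit_depth - 1]", call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a positive scalar", call. = FALSE)
  }
  structure(
    list(pixels = pixels, bit_depth = bit_depth,
         pixel_size_nm = pixel_size_nm),
    class = "raw_image"
  )
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %d x %d px, %d-bit, %.3g nm/px\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size_nm))
  invisible(x)
}

#' @export
dim.raw_image <- function(x) dim(x$pixels)

#' Read a microscopy image from disk
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG into a [raw_image()]. RGB (or
#' any multi-channel) input is collapsed to luminance by the per-pixel channel
#' mean; the cameras this package targets are monochrome, so colour files are
#' treated as a user convenience.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_nm Physical pixel size in nanometres (metadata carried
#'   through the pipeline; default 22).
#'
#' @return A [raw_image()] with bit depth inferred from the file.
#' @export
load_image <- function(path, pixel_size_nm = 22) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found: %s", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE)
    bit_depth <- as.integer(info$bits.per.sample[[1]])
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    bit_depth <- as.integer(attr(px, "info")$bit.depth)
    px <- px * (2^bit_depth - 1)
  } else {
    stop(sprintf("unsupported image format '%s' for %s (need TIFF or PNG)",
                 ext, path), call. = FALSE)
  }
  if (length(dim(px)) == 3L) px <- apply(px, c(1L, 2L), mean)
  px <- round(unclass(px))
  if (length(px) == 0L || is.null(dim(px))) {
    stop(sprintf("zero-sized image: %s", path), call. = FALSE)
  }
  raw_image(px, bit_depth = bit_depth, pixel_size_nm = pixel_size_nm)
}

#' Write a raw image to TIFF
#'
#' @param img A [raw_image()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "raw_image"))
  tiff::writeTIFF(img$pixels / (2^img$bit_depth - 1), path,
                  bits.per.sample = img$bit_depth, compression = "none")
  invisible(path)
}

# Accept raw_image / norm_image / bare matrix and return the pixel matrix.
as_pixel_matrix <- function(img) {
  if (inherits(img, "raw_image") || inherits(img, "norm_image")) {
    img$pixels
  } else if (is.matrix(img) && is.numeric(img)) {
    img
  } else {
    stop("expected a raw_image, norm_image or numeric matrix", call. = FALSE)
  }
}
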
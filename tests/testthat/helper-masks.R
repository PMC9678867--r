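# Shared fixture builders and independent oracles.

# Filled binary ellipse mask with pixel centres at integer coordinates.
make_ellipse_mask <- function(a, b, orientation_deg = 0, shape = NULL,
                              centre = NULL) {
  if (is.null(shape)) {
    half <- ceiling(a) + 4L
    shape <- c(2L * half + 1L, 2L * half + 1L)
  }
  if (is.null(centre)) centre <- (rev(shape) + 1) / 2  # (x, y)
  ell <- cell_ellipse(centre[1], centre[2], a, b, orientation_deg)
  ellipse_mask(ell, shape)
}

# Independent double-loop moment oracle: explicit iteration over every
# matrix element, accumulating the binary-weighted central second moments.
brute_force_moments <- function(mask, centroid) {
  mu20 <- 0; mu02 <- 0; mu11 <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        dx <- j - centroid[1]
        dy <- -(i - centroid[2])
        mu20 <- mu20 + dx * dx
        mu02 <- mu02 + dy * dy
        mu11 <- mu11 + dx * dy
      }
    }
  }
  phi1 <- mu20 + mu02
  phi2 <- (mu20 - mu02)^2 + 4 * mu11^2
  list(mu20 = mu20, mu02 = mu02, mu11 = mu11, phi1 = phi1, phi2 = phi2,
       e = 0.5 * log2((phi1 + sqrt(phi2)) / (phi1 - sqrt(phi2))))
}

# Nearest-neighbour mask rotation about the image centre (pads the canvas so
# nothing is clipped).
rotate_mask_nn <- function(mask, angle_deg) {
  img <- EBImage::rotate(EBImage::Image(mask * 1), angle_deg,
                         filter = "none", bg.col = 0)
  as.matrix(img) > 0.5
}

# Mask of a pixelated point cloud (x, y in image coordinates).
rasterize_points <- function(x, y, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  i <- round(y); j <- round(x)
  keep <- i >= 1 & i <= shape[1] & j >= 1 & j <= shape[2]
  m[cbind(i[keep], j[keep])] <- TRUE
  m
}

# Elongation of a mask in one call, centring moments on the mask COM.
mask_elongation <- function(mask) {
  elongation_tirfm(central_moments(patch_mask(mask)))
}
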
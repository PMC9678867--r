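#' Detect the cell boundary in a bright-field image
#'
#' Segments the single dominant cell in a bright-field frame and traces its
#' outer contour. The recipe is deliberately parameter-light: Gaussian blur
#' (sigma 2 px), Otsu threshold, morphological closing (disc radius 3), hole
#' filling, then the largest connected component. Cells may appear darker or
#' brighter than the background depending on focus; with
#' `polarity = "auto"` both Otsu sides are segmented and the side whose
#' largest component is more compact (smaller perimeter^2 / area) is kept.
#'
#' @param bfm A `norm_image` bright-field frame (see
#'   [normalize_intensity()]), or a numeric matrix in \[0, 1\].
#' @param min_area_px Minimum component area in pixels for a valid cell
#'   (default 200); smaller components raise a "no cell found" error.
#' @param polarity `"auto"`, `"bright"` (cell brighter than background) or
#'   `"dark"`.
#' @param blur_sigma Gaussian pre-blur width in pixels (default 2).
#'
#' @return An object of class `cell_boundary`: a list with `polygon` (tibble
#'   of ordered contour vertices `x`, `y`), `mask` (logical matrix of the
#'   filled region) and `border_flag` (`TRUE` when the component touches at
#'   least half of the image border, signalling a probably-clipped cell).
#' @export
detect_boundary <- function(bfm, min_area_px = 200, polarity = c("auto", "bright", "dark"),
                            blur_sigma = 2) {
  polarity <- match.arg(polarity)
  px <- as_pixel_matrix(bfm)
  if (diff(range(px)) < .Machine$double.eps) {
    stop("no cell found: image is constant", call. = FALSE)
  }
  g <- EBImage::gblur(EBImage::Image(px), sigma = blur_sigma)
  thr <- EBImage::otsu(g, range = range(px))

  candidate <- function(side_mask) {
    m <- EBImage::closing(side_mask, EBImage::makeBrush(7, "disc"))
    m <- EBImage::fillHull(m)
    lab <- EBImage::bwlabel(m)
    n <- max(lab)
    if (n == 0) return(NULL)
    areas <- tabulate(as.integer(lab)[as.integer(lab) > 0], nbins = n)
    k <- which.max(areas)
    mask <- as.matrix(lab) == k
    # 4-connected perimeter: mask pixels with at least one outside neighbour
    pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
    pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
    core <- pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
    nb <- pad[1:nrow(mask), 2:(ncol(mask) + 1L)] &
      pad[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)] &
      pad[2:(nrow(mask) + 1L), 1:ncol(mask)] &
      pad[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
    perim <- sum(core & !nb)
    list(mask = mask, lab = lab, k = k, area = areas[k],
         compactness = perim^2 / areas[k])
  }

  cands <- switch(polarity,
    bright = list(candidate(g > thr)),
    dark   = list(candidate(g < thr)),
    auto   = list(candidate(g > thr), candidate(g < thr))
  )
  cands <- Filter(function(cc) !is.null(cc) && cc$area >= min_area_px, cands)
  # discard a side that swallowed essentially the whole frame
  cands <- Filter(function(cc) cc$area < 0.9 * length(px), cands)
  if (length(cands) == 0L) {
    stop(sprintf("no cell found: no connected component with area >= %d px",
                 as.integer(min_area_px)), call. = FALSE)
  }
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "compactness"))]]

  mask <- best$mask
  nr <- nrow(mask); nc <- ncol(mask)
  border <- c(mask[1, ], mask[nr, ], mask[, 1], mask[, nc])
  border_flag <- mean(border) >= 0.5
  if (border_flag) {
    warning("cell touches >= 50% of the image border; boundary may be clipped",
            call. = FALSE)
  }

  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  # ocontour returns 0-based (dim1, dim2) = (row, col); convert to 1-based (x, y)
  polygon <- tibble::tibble(x = oc[, 2] + 1, y = oc[, 1] + 1)

  structure(list(polygon = polygon, mask = mask, border_flag = border_flag),
            class = "cell_boundary")
}

#' @export
print.cell_boundary <- function(x, ...) {
  cat(sprintf("<cell_boundary> area %d px, %d contour vertices%s\n",
              sum(x$mask), nrow(x$polygon),
              if (x$border_flag) " (touches border)" else ""))
  invisible(x)
}

#' Construct a cell ellipse
#'
#' Container for the ellipse fitted to the cell's contact-area boundary:
#' centroid, semi-axes (`a >= b`, pixels) and orientation of the major axis
#' in degrees counter-clockwise from the image +x axis (mathematical frame,
#' wrapped to \[-90, 90)).
#'
#' @param centroid_x,centroid_y Centroid in pixel coordinates.
#' @param a,b Semi-major and semi-minor axis lengths in pixels.
#' @param orientation_deg Major-axis orientation in degrees.
#' @return An object of class `cell_ellipse`.
#' @export
cell_ellipse <- function(centroid_x, centroid_y, a, b, orientation_deg = 0) {
  if (!(a > 0 && b > 0)) stop("semi-axes must be positive", call. = FALSE)
  if (a < b) stop("`a` must be >= `b`", call. = FALSE)
  orientation_deg <- ((orientation_deg + 90) %% 180) - 90
  structure(
    list(centroid_x = centroid_x, centroid_y = centroid_y,
         a = a, b = b, orientation_deg = orientation_deg),
    class = "cell_ellipse"
  )
}

#' @export
print.cell_ellipse <- function(x, ...) {
  cat(sprintf(
    "<cell_ellipse> centre (%.1f, %.1f), a = %.1f px, b = %.1f px, %.1f deg\n",
    x$centroid_x, x$centroid_y, x$a, x$b, x$orientation_deg))
  invisible(x)
}

#' Fit an ellipse to a cell boundary
#'
#' The default `"moments"` method is the equivalent-ellipse fit: the centroid
#' is the centre of mass of the filled mask and the semi-axes derive from the
#' eigenvalues of the pixel-coordinate covariance matrix (`a = 2 sqrt(l_max)`,
#' `b = 2 sqrt(l_min)`), with the orientation given by the principal
#' eigenvector. This matches the moment-based framework of the downstream
#' elongation score and is unconditionally stable. The `"contour"` method is
#' a direct least-squares conic fit to the traced boundary vertices, provided
#' to quantify sensitivity to the choice of fitting target.
#'
#' @param boundary A `cell_boundary` from [detect_boundary()] (or a logical
#'   mask matrix, taken as the filled region).
#' @param method `"moments"` (default) or `"contour"`.
#'
#' @return A [cell_ellipse()].
#' @export
fit_ellipse <- function(boundary, method = c("moments", "contour")) {
  method <- match.arg(method)
  if (inherits(boundary, "cell_boundary")) {
    mask <- boundary$mask
    poly <- boundary$polygon
  } else if (is.matrix(boundary)) {
    mask <- boundary > 0
    poly <- NULL
  } else {
    stop("`boundary` must be a cell_boundary or a mask matrix", call. = FALSE)
  }
  if (method == "contour") {
    if (is.null(poly)) stop("contour method needs a traced polygon", call. = FALSE)
    return(fit_ellipse_conic(poly$x, poly$y))
  }
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 5L) stop("degenerate boundary: mask too small", call. = FALSE)
  x <- idx[, 2]; y <- idx[, 1]
  xbar <- mean(x); ybar <- mean(y)
  dx <- x - xbar
  dy <- -(y - ybar)  # mathematical frame (y up)
  cxx <- mean(dx * dx); cyy <- mean(dy * dy); cxy <- mean(dx * dy)
  tr <- cxx + cyy
  det_ <- cxx * cyy - cxy * cxy
  disc <- sqrt(max(tr * tr / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l2 <= 1e-12 * max(l1, 1)) {
    stop("degenerate boundary: zero minor eigenvalue", call. = FALSE)
  }
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  cell_ellipse(xbar, ybar, a = 2 * sqrt(l1), b = 2 * sqrt(l2),
               orientation_deg = theta)
}

# Direct least-squares ellipse fit to contour points (conic with the
# ellipse-specific constraint 4AC - B^2 = 1), solved as a generalized
# eigenproblem on the design-matrix scatter.
fit_ellipse_conic <- function(x, y) {
  x0 <- mean(x); y0 <- mean(y)
  xs <- x - x0; ys <- -(y - y0)
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop("degenerate boundary: conic fit failed", call. = FALSE)
  a1 <- vecs[, ok[1]]
  par <- c(a1, Tm %*% a1)  # A B C D E F for centred coords
  A <- par[1]; B <- par[2]; C <- par[3]; D <- par[4]; E <- par[5]; F <- par[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # translate to the conic centre: x' M x' = k with M = [[A, B/2], [B/2, C]]
  k <- -(F + (D * cx + E * cy) / 2)
  M <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(M, symmetric = TRUE)
  if (any(eg$values * k <= 0)) {
    stop("degenerate boundary: conic fit failed", call. = FALSE)
  }
  axes <- sqrt(k / eg$values)          # descending eigenvalue -> minor first
  vmaj <- eg$vectors[, which.min(eg$values)]
  theta <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  cell_ellipse(x0 + cx, y0 - cy, a = max(axes), b = min(axes),
               orientation_deg = theta)
}

#' Geometric elongation of the cell footprint
#'
#' The dimensionless elongation of the fitted contact-area ellipse,
#' `E_BFM = log2(a / b)`: 0 for a circular footprint, 1 when the major axis
#' is twice the minor, and 2 or more for a highly polarized cell.
#'
#' @param ellipse A [cell_ellipse()].
#' @return Elongation value (non-negative scalar).
#' @export
elongation_bfm <- function(ellipse) {
  stopifnot(inherits(ellipse, "cell_ellipse"))
  log2(ellipse$a / ellipse$b)
}

#' Rasterize an ellipse to a logical mask
#'
#' Pixels whose centres fall inside (or on) the ellipse are `TRUE`.
#'
#' @param ellipse A [cell_ellipse()].
#' @param shape Image dimensions `c(rows, cols)`.
#' @return Logical matrix.
#' @export
ellipse_mask <- function(ellipse, shape) {
  stopifnot(inherits(ellipse, "cell_ellipse"), length(shape) == 2L)
  uv <- ellipse_frame_coords(ellipse, shape)
  (uv$u / ellipse$a)^2 + (uv$v / ellipse$b)^2 <= 1
}

# Per-pixel coordinates in the ellipse frame (u along the major axis, v along
# the minor, mathematical orientation), as matrices of the given shape.
ellipse_frame_coords <- function(ellipse, shape) {
  nr <- shape[1]; nc <- shape[2]
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  dx <- x - ellipse$centroid_x
  dy <- -(y - ellipse$centroid_y)
  phi <- ellipse$orientation_deg * pi / 180
  list(u = dx * cos(phi) + dy * sin(phi),
       v = -dx * sin(phi) + dy * cos(phi))
}
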
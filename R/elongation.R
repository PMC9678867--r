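#' Binary F-actin patch mask
#'
#' Container for the binarized TIRF image restricted to the analysis domain,
#' together with the cell centroid used for moment centering. Binarization is
#' the step that makes the elongation score intensity-independent: every
#' supra-threshold pixel counts as 1 regardless of its brightness, because in
#' TIRF the evanescent excitation decays with fluorophore depth and per-pixel
#' intensity is therefore not proportional to fluorophore count.
#'
#' @param mask Logical matrix, `TRUE` for bright elements.
#' @param domain Logical matrix of the analysis region (cell mask or fitted
#'   ellipse); defaults to `mask` itself. `mask` outside `domain` is dropped.
#' @param centroid Numeric `c(x, y)` used as the moment origin; defaults to
#'   the mask centre of mass.
#' @param threshold The normalized-intensity threshold that produced the mask
#'   (metadata; `NA` for directly-constructed masks).
#'
#' @return An object of class `patch_mask`.
#' @export
patch_mask <- function(mask, domain = NULL, centroid = NULL, threshold = NA_real_) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (is.null(domain)) domain <- mask
  stopifnot(identical(dim(domain), dim(mask)))
  domain <- domain > 0
  mask <- mask & domain
  if (!any(mask)) stop("no patches above threshold", call. = FALSE)
  if (is.null(centroid)) {
    idx <- which(mask, arr.ind = TRUE)
    centroid <- c(mean(idx[, 2]), mean(idx[, 1]))
  }
  stopifnot(is.numeric(centroid), length(centroid) == 2L)
  structure(list(mask = mask, domain = domain,
                 centroid = as.numeric(centroid), threshold = threshold),
            class = "patch_mask")
}

#' @export
print.patch_mask <- function(x, ...) {
  cat(sprintf(
    "<patch_mask> %d bright px / %d domain px, origin (%.1f, %.1f)\n",
    sum(x$mask), sum(x$domain), x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Binarize a TIRF image into a patch mask
#'
#' Any element whose normalized intensity is strictly greater than the
#' threshold (default 0.25) is set to 1 and the rest to 0, restricted to the
#' analysis domain. The strict inequality is the convention of the method;
#' `strict = FALSE` switches to `>=` for sensitivity checks.
#'
#' @param tirfm A `norm_image` (see [normalize_intensity()]) or matrix of
#'   values in \[0, 1\].
#' @param domain Logical matrix: cell-boundary mask or rasterized ellipse.
#' @param centroid Numeric `c(x, y)` cell centroid for moment centering
#'   (typically the fitted-ellipse centroid).
#' @param threshold Normalized-intensity cutoff in (0, 1), default 0.25.
#' @param strict Use strict `>` (default) or `>=`.
#'
#' @return A [patch_mask()].
#' @export
binarize_patches <- function(tirfm, domain, centroid, threshold = 0.25,
                             strict = TRUE) {
  px <- as_pixel_matrix(tirfm)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(identical(dim(domain), dim(px)))
  domain <- domain > 0
  if (!any(domain)) stop("`domain` is empty", call. = FALSE)
  bright <- if (strict) px > threshold else px >= threshold
  patch_mask(bright, domain = domain, centroid = centroid,
             threshold = threshold)
}

#' Central second moments and Hu invariants of a patch mask
#'
#' Computes the binary-intensity central second moments about the cell
#' centroid,
#' \deqn{\mu_{20} = \sum (x - \bar x)^2, \quad
#'       \mu_{02} = \sum (y - \bar y)^2, \quad
#'       \mu_{11} = \sum (x - \bar x)(y - \bar y),}
#' the sums running over bright pixels, and from them the rotation-invariant
#' combinations \eqn{\phi_1 = \mu_{20} + \mu_{02}},
#' \eqn{\phi_2 = (\mu_{20} - \mu_{02})^2 + 4 \mu_{11}^2} and the principal
#' pair \eqn{\lambda_{1,2} = 2\pi(\phi_1 \pm \sqrt{\phi_2})}. Coordinates use
#' the mathematical frame (y negated), which leaves \eqn{\mu_{20}},
#' \eqn{\mu_{02}} and both invariants unchanged and flips only the sign of
#' \eqn{\mu_{11}}.
#'
#' \eqn{\phi_1 - \sqrt{\phi_2}} suffers catastrophic cancellation for
#' near-collinear masks, so \eqn{\lambda_2} below `1e-9 * lambda1` is treated
#' as zero and reported as a degenerate patch distribution.
#'
#' @param patches A [patch_mask()].
#' @return An object of class `moment_set` with fields `mu20`, `mu02`,
#'   `mu11`, `phi1`, `phi2`, `lambda1`, `lambda2`, `n_px` and `centroid`.
#' @export
central_moments <- function(patches) {
  stopifnot(inherits(patches, "patch_mask"))
  idx <- which(patches$mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) {
    stop("degenerate patch distribution: fewer than 3 bright pixels",
         call. = FALSE)
  }
  dx <- idx[, 2] - patches$centroid[1]
  dy <- -(idx[, 1] - patches$centroid[2])
  mu20 <- sum(dx * dx)
  mu02 <- sum(dy * dy)
  mu11 <- sum(dx * dy)
  phi1 <- mu20 + mu02
  phi2 <- (mu20 - mu02)^2 + 4 * mu11^2
  rt <- sqrt(phi2)
  lambda1 <- 2 * pi * (phi1 + rt)
  lambda2 <- 2 * pi * (phi1 - rt)
  if (lambda2 < 1e-9 * lambda1) {
    stop("degenerate patch distribution: bright pixels are collinear",
         call. = FALSE)
  }
  structure(
    list(mu20 = mu20, mu02 = mu02, mu11 = mu11,
         phi1 = phi1, phi2 = phi2,
         lambda1 = lambda1, lambda2 = lambda2,
         n_px = nrow(idx), centroid = patches$centroid),
    class = "moment_set"
  )
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf(
    "<moment_set> n = %d px; phi1 = %.4g, phi2 = %.4g; E = %.3f\n",
    x$n_px, x$phi1, x$phi2, elongation_tirfm(x)))
  invisible(x)
}

#' Elongation score of the patch distribution
#'
#' The intensity-independent elongation of the binarized F-actin patch
#' distribution,
#' \deqn{E_{TIRFM} = \log_2 \sqrt{\lambda_1 / \lambda_2}
#'     = \tfrac12 \log_2 \frac{\phi_1 + \sqrt{\phi_2}}{\phi_1 - \sqrt{\phi_2}},}
#' where the \eqn{2\pi} factors cancel. The score is 0 for an isotropic
#' distribution, about 1 when the principal spread doubles the transverse
#' one, and 2 or more for a highly polarized cell. It is invariant to
#' translation, rotation and uniform scaling of the mask.
#'
#' @param m A `moment_set` from [central_moments()].
#' @return Elongation value (non-negative scalar).
#' @export
elongation_tirfm <- function(m) {
  stopifnot(inherits(m, "moment_set"))
  if (m$lambda2 <= 0) {
    stop("degenerate patch distribution: lambda2 = 0", call. = FALSE)
  }
  0.5 * log2(m$lambda1 / m$lambda2)
}

#' Classify the cell adhesion stage from the elongation score
#'
#' Maps an elongation value to one of the three adhesion stages: `I_attaching`
#' (round cell, centrally clumped actin), `II_spreading`, or `III_expanding`
#' (polarized cell, peripheral dispersed actin). The default band edges
#' (1.0, 1.65) place stage I at `E <= 1`, stage III at `E >= 1.65` and
#' stage II between; both edges are configurable since published stage means
#' (about 0.7 / 1.3 / 1.95) support a range of sensible cutoffs.
#'
#' @param e Elongation value (scalar), or a `moment_set`.
#' @param band_edges Strictly increasing positive pair `c(lower, upper)`.
#' @return A one-row tibble of class `stage_call` with columns `stage`
#'   (factor `I_attaching`/`II_spreading`/`III_expanding`), `e_tirfm`,
#'   `edge_lower`, `edge_upper`.
#' @export
classify_stage <- function(e, band_edges = c(1.0, 1.65)) {
  if (inherits(e, "moment_set")) e <- elongation_tirfm(e)
  stopifnot(is.numeric(e), length(e) == 1L)
  if (length(band_edges) != 2L || band_edges[1] >= band_edges[2] ||
      any(band_edges <= 0)) {
    stop("`band_edges` must be a strictly increasing positive pair",
         call. = FALSE)
  }
  stage <- if (e <= band_edges[1]) "I_attaching"
    else if (e >= band_edges[2]) "III_expanding"
    else "II_spreading"
  out <- tibble::tibble(
    stage = factor(stage, levels = stage_levels()),
    e_tirfm = e,
    edge_lower = band_edges[1],
    edge_upper = band_edges[2]
  )
  class(out) <- c("stage_call", class(out))
  out
}

stage_levels <- function() c("I_attaching", "II_spreading", "III_expanding")
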
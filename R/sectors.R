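#' Partition a fitted ellipse into equal-angle sectors
#'
#' Divides the ellipse interior into `n_sectors` sectors of equal central
#' angle. Each in-ellipse pixel centre is labelled
#' `k = floor(angle / delta)` with `delta = 360 / n_sectors`, where the angle
#' is measured counter-clockwise from the ellipse major axis (default) or
#' from the image +x axis, wrapped to \[0, 360). Bins are half-open, so a
#' pixel exactly on a sector ray belongs to the higher sector.
#'
#' @param ellipse A [cell_ellipse()].
#' @param shape Image dimensions `c(rows, cols)`.
#' @param n_sectors Number of sectors (default 72, i.e. 5-degree sectors).
#' @param frame `"ellipse"` (angles from the major axis, default) or
#'   `"image"` (angles from the image +x axis in the mathematical frame).
#'
#' @return An object of class `sector_partition`: list with `labels`
#'   (integer matrix, sector index in \[0, n_sectors) inside the ellipse,
#'   -1 outside), `n_sectors`, `theta_deg` (per-sector central angles) and
#'   the `ellipse`.
#' @export
partition_ellipse <- function(ellipse, shape, n_sectors = 72,
                              frame = c("ellipse", "image")) {
  frame <- match.arg(frame)
  stopifnot(inherits(ellipse, "cell_ellipse"))
  n_sectors <- as.integer(n_sectors)
  if (n_sectors < 4L) stop("`n_sectors` must be >= 4", call. = FALSE)
  uv <- ellipse_frame_coords(ellipse, shape)
  inside <- (uv$u / ellipse$a)^2 + (uv$v / ellipse$b)^2 <= 1
  if (!any(inside)) {
    stop("ellipse lies fully outside the image", call. = FALSE)
  }
  if (frame == "ellipse") {
    ang <- atan2(uv$v, uv$u)
  } else {
    phi <- ellipse$orientation_deg * pi / 180
    # rotate back to the image-axis frame
    ang <- atan2(uv$u * sin(phi) + uv$v * cos(phi),
                 uv$u * cos(phi) - uv$v * sin(phi))
  }
  deg <- (ang * 180 / pi) %% 360
  delta <- 360 / n_sectors
  lab <- pmin(floor(deg / delta), n_sectors - 1L)
  labels <- matrix(-1L, shape[1], shape[2])
  labels[inside] <- as.integer(lab[inside])
  structure(
    list(labels = labels, n_sectors = n_sectors,
         theta_deg = (seq_len(n_sectors) - 0.5) * delta,
         ellipse = ellipse, frame = frame),
    class = "sector_partition"
  )
}

#' @export
print.sector_partition <- function(x, ...) {
  cat(sprintf("<sector_partition> %d sectors over %d in-ellipse px\n",
              x$n_sectors, sum(x$labels >= 0)))
  invisible(x)
}

#' Per-sector surface density of bright patches
#'
#' For each sector the bright in-ellipse area `A_L` is divided by the sector
#' area `A_T` to give the surface density `sigma = A_L / A_T` (a fraction in
#' \[0, 1\] independent of sector size), and the sigma profile is normalized
#' to the probability distribution `f_sigma = sigma / sum(sigma)` over
#' sectors. Sectors of zero area (possible for tiny ellipses at coarse
#' resolution) get `sigma = 0` and are flagged rather than producing NaN.
#'
#' @param partition A `sector_partition` from [partition_ellipse()].
#' @param patches A [patch_mask()] of the same image shape.
#'
#' @return A tibble of class `sector_profile` with columns `sector` (0-based
#'   index), `theta_deg`, `area_total_px`, `area_bright_px`, `sigma`,
#'   `f_sigma` and `zero_area` (flag). Attributes: `n_bright_outside`
#'   (bright pixels falling outside the ellipse, excluded from the profile)
#'   and `n_sectors`.
#' @export
sector_sigma <- function(partition, patches) {
  stopifnot(inherits(partition, "sector_partition"),
            inherits(patches, "patch_mask"))
  lab <- partition$labels
  if (!identical(dim(lab), dim(patches$mask))) {
    stop("partition and patch mask shapes disagree", call. = FALSE)
  }
  n <- partition$n_sectors
  inside <- lab >= 0L
  a_t <- tabulate(lab[inside] + 1L, nbins = n)
  bright_in <- patches$mask & inside
  a_l <- tabulate(lab[bright_in] + 1L, nbins = n)
  zero_area <- a_t == 0L
  sigma <- ifelse(zero_area, 0, a_l / pmax(a_t, 1L))
  if (sum(sigma) <= 0) {
    stop("empty profile: no bright pixels inside the ellipse", call. = FALSE)
  }
  out <- tibble::tibble(
    sector = 0:(n - 1L),
    theta_deg = partition$theta_deg,
    area_total_px = as.integer(a_t),
    area_bright_px = as.integer(a_l),
    sigma = sigma,
    f_sigma = sigma / sum(sigma),
    zero_area = zero_area
  )
  attr(out, "n_bright_outside") <- sum(patches$mask & !inside)
  attr(out, "n_sectors") <- n
  class(out) <- c("sector_profile", class(out))
  out
}

#' Overlay two sector profiles
#'
#' Aligns two profiles with the same sector count into one table for joint
#' plotting or export (e.g. an attaching-stage cell against an
#' expanding-stage cell). No resampling is performed.
#'
#' @param p1,p2 `sector_profile` tibbles with equal `n_sectors`.
#' @param labels Character pair naming the two profiles.
#' @return A tibble with columns `sector`, `theta_deg`, `f_sigma_1`,
#'   `f_sigma_2` (attribute `labels` carries the names).
#' @export
profile_overlay <- function(p1, p2, labels = c("cell_1", "cell_2")) {
  stopifnot(inherits(p1, "sector_profile"), inherits(p2, "sector_profile"))
  if (!identical(attr(p1, "n_sectors"), attr(p2, "n_sectors"))) {
    stop("profiles have different sector counts", call. = FALSE)
  }
  out <- tibble::tibble(
    sector = p1$sector,
    theta_deg = p1$theta_deg,
    f_sigma_1 = p1$f_sigma,
    f_sigma_2 = p2$f_sigma
  )
  attr(out, "labels") <- labels
  class(out) <- c("profile_overlay", class(out))
  out
}

#' Write a sector profile to CSV
#'
#' @param profile A `sector_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sector_profile"))
  df <- as.data.frame(profile)[, c("sector", "theta_deg", "area_total_px",
                                   "area_bright_px", "sigma", "f_sigma")]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
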
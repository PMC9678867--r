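#' Polar plot of a sector profile
#'
#' Draws the normalized surface-density distribution `f_sigma(theta)` of
#' bright patches over the ellipse sectors as a polar line, the standard way
#' of displaying how the patch distribution concentrates (attaching cells)
#' or disperses along the polarization axis (expanding cells).
#'
#' @param object A `sector_profile` from [sector_sigma()].
#' @param value Column to plot: `"f_sigma"` (default) or `"sigma"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sector_profile <- function(object, value = c("f_sigma", "sigma"),
                                    ...) {
  value <- match.arg(value)
  df <- tibble::as_tibble(object)
  # close the polygon
  df2 <- rbind(df, df[1, ])
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$theta_deg,
                                    y = .data[[value]])) +
    ggplot2::geom_path() +
    ggplot2::coord_polar(theta = "x", start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = expression(theta ~ "(deg, from major axis)"),
                  y = value) +
    ggplot2::theme_minimal()
}

#' Overlay plot of two sector profiles
#'
#' @param object A `profile_overlay` from [profile_overlay()].
#' @param ... Unused.
#' @return A ggplot object (polar overlay of the two `f_sigma` profiles).
#' @exportS3Method ggplot2::autoplot
autoplot.profile_overlay <- function(object, ...) {
  labels <- attr(object, "labels")
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(cols = c("f_sigma_1", "f_sigma_2"),
                        names_to = "which", values_to = "f_sigma") |>
    dplyr::mutate(which = factor(.data$which,
                                 levels = c("f_sigma_1", "f_sigma_2"),
                                 labels = labels))
  df <- dplyr::bind_rows(df, df[df$theta_deg == min(df$theta_deg), ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta_deg, y = .data$f_sigma,
                                   colour = .data$which)) +
    ggplot2::geom_path() +
    ggplot2::coord_polar(theta = "x", start = -pi / 2, direction = -1) +
    ggplot2::labs(x = expression(theta ~ "(deg)"), y = "f_sigma",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cohort scatter of the two elongation scores
#'
#' Plots the patch-distribution elongation against the footprint elongation
#' for every analysed cell, coloured by called adhesion stage, with the
#' classification band edges as horizontal lines.
#'
#' @param object A `cohort_report` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.na(df$error), ]
  edges <- object$config$band_edges
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e_bfm, y = .data$e_tirfm,
                                   colour = .data$stage)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = edges, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(E[BFM]), y = expression(E[TIRFM]),
                  colour = "stage") +
    ggplot2::theme_minimal()
}

#' Bar plot of a normalized-intensity histogram
#'
#' @param object An `intensity_histogram` from [intensity_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.intensity_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                   y = .data$frequency)) +
    ggplot2::geom_col(width = df$bin_hi[1] - df$bin_lo[1]) +
    ggplot2::labs(x = "normalized intensity", y = "pixel fraction") +
    ggplot2::theme_minimal()
}
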
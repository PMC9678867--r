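#' Tidy a fitted cell ellipse
#'
#' @param x A [cell_ellipse()].
#' @param ... Unused.
#' @return One-row tibble with the ellipse parameters and `e_bfm`.
#' @exportS3Method generics::tidy
tidy.cell_ellipse <- function(x, ...) {
  tibble::tibble(
    centroid_x = x$centroid_x, centroid_y = x$centroid_y,
    a_px = x$a, b_px = x$b, orientation_deg = x$orientation_deg,
    e_bfm = elongation_bfm(x)
  )
}

#' Tidy a moment set
#'
#' @param x A `moment_set` from [central_moments()].
#' @param ... Unused.
#' @return One-row tibble with the second moments, Hu invariants, principal
#'   pair and the elongation score.
#' @exportS3Method generics::tidy
tidy.moment_set <- function(x, ...) {
  tibble::tibble(
    mu20 = x$mu20, mu02 = x$mu02, mu11 = x$mu11,
    phi1 = x$phi1, phi2 = x$phi2,
    lambda1 = x$lambda1, lambda2 = x$lambda2,
    n_bright_px = x$n_px,
    e_tirfm = elongation_tirfm(x)
  )
}

#' Per-cell records of a cohort report
#'
#' @param x A `cohort_report` from [run_cohort()].
#' @param ... Unused.
#' @return The per-cell tibble (without the `profile` list-column).
#' @exportS3Method generics::tidy
tidy.cohort_report <- function(x, ...) {
  x$cells[, setdiff(names(x$cells), "profile")]
}

#' One-row summary of a cohort report
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return One-row tibble: cell counts, stage counts, Pearson correlation
#'   between the two elongation scores, and the one-way ANOVA statistic and
#'   p-value across called stages.
#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_analysed = sum(is.na(x$cells$error)),
    n_stage_i = x$n_per_stage[1],
    n_stage_ii = x$n_per_stage[2],
    n_stage_iii = x$n_per_stage[3],
    pearson_r = x$pearson_r,
    anova_f = if (!is.null(x$anova)) x$anova$statistic else NA_real_,
    anova_p = if (!is.null(x$anova)) x$anova$p.value else NA_real_
  )
}
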
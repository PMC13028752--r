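#' Deformability index of a single cell
#'
#' The deformability index of a cell with extent `L_X` along the flow axis and
#' `L_Y` transverse to it is `DI = (L_X - L_Y) / (L_X + L_Y)`: 0 for a circle,
#' approaching 1 for extreme elongation, and scale-free (independent of
#' magnification or pixel size). A negative value signals `L_X < L_Y`; the
#' pipelines orient axes so accepted cells have `L_X >= L_Y`.
#'
#' @param l_x,l_y Positive cell extents (same units). Vectorized.
#' @return `(l_x - l_y) / (l_x + l_y)`.
#' @export
#' @examples
#' deformability_index(9, 6)  # 0.2
deformability_index <- function(l_x, l_y) {
  if (any(l_x <= 0) || any(l_y <= 0)) {
    stop("cell extents must be positive", call. = FALSE)
  }
  (l_x - l_y) / (l_x + l_y)
}

#' Convert wall shear stress to wall shear rate
#'
#' For a Newtonian suspension the wall shear rate is stress over viscosity.
#' With stress in dyn/cm2 (= 0.1 Pa) and viscosity in mPa.s (= 1e-3 Pa.s) the
#' unit conversion gives `rate = 100 * stress / viscosity` in 1/s. The default
#' viscosity 1.12 mPa.s is that of RBCs diluted in Dextran 70 at 37 C.
#'
#' @param stress_dyn_cm2 Wall shear stress, dyn/cm2 (> 0). Vectorized.
#' @param viscosity_mPas Suspension viscosity, mPa.s (> 0).
#' @return Shear rate in 1/s.
#' @seealso [report_shear_rate()] for the conventional rounded display form.
#' @export
#' @examples
#' stress_to_rate(5, 1.12)  # 446.4 1/s
stress_to_rate <- function(stress_dyn_cm2, viscosity_mPas = 1.12) {
  if (any(stress_dyn_cm2 <= 0) || any(viscosity_mPas <= 0)) {
    stop("stress and viscosity must be positive", call. = FALSE)
  }
  100 * stress_dyn_cm2 / viscosity_mPas
}

#' Rounded shear rate for reporting
#'
#' Shear rates are conventionally reported to the nearest integer, with one
#' decimal kept below 10 1/s.
#'
#' @param rate_s1 Shear rate(s), 1/s.
#' @return Rounded rate(s).
#' @export
report_shear_rate <- function(rate_s1) {
  ifelse(rate_s1 < 10, round(rate_s1, 1), round(rate_s1))
}

#' Summarize accepted cells of one image
#'
#' Sums the per-cell deformability indices into `di_total` and averages them
#' into `di_mean`. An image with no accepted cells yields `di_mean = NA` and
#' `empty = TRUE` rather than an error, so background-only frames survive
#' batch processing.
#'
#' @param cells Data frame of accepted cells with a `di` column (e.g. the
#'   accepted subset of a pipeline's cell table); may have zero rows.
#' @param stress_dyn_cm2,viscosity_mPas Flow condition, used to attach the
#'   shear rate.
#' @param donor_id,group Donor metadata carried through to the summary.
#' @return A one-row tibble: `donor_id`, `group`, `stress_dyn_cm2`,
#'   `shear_rate_s1`, `n_cells`, `di_total`, `di_mean`, `empty`.
#' @export
summarize_image <- function(cells,
                            stress_dyn_cm2 = NA_real_,
                            viscosity_mPas = 1.12,
                            donor_id = NA_character_,
                            group = NA_character_) {
  di <- if (nrow(cells) > 0) cells$di else numeric(0)
  n <- length(di)
  tibble::tibble(
    donor_id = donor_id,
    group = group,
    stress_dyn_cm2 = stress_dyn_cm2,
    shear_rate_s1 = if (is.na(stress_dyn_cm2)) NA_real_ else
      stress_to_rate(stress_dyn_cm2, viscosity_mPas),
    n_cells = n,
    di_total = sum(di),
    di_mean = if (n > 0) sum(di) / n else NA_real_,
    empty = n == 0L
  )
}

#' Aggregate image summaries into a donor profile
#'
#' Pools all accepted cells of one donor across the images taken at each flow
#' condition and reports the pooled (cell-weighted) mean DI per condition:
#' an image contributing 10 cells weighs ten times an image contributing one,
#' which matches aggregating every cell's DI before averaging. An
#' image-weighted alternative (mean of per-image means) is available via
#' `weighting`. Conditions covered by fewer than `min_images` images trigger
#' a warning, since the acquisition protocol expects at least five frames per
#' shear step.
#'
#' @param summaries Data frame of per-image summaries as returned by
#'   [summarize_image()] (row-bound), all for the same donor.
#' @param weighting `"cells"` (pooled, default) or `"images"`.
#' @param min_images Minimum images per condition before warning.
#' @return A tibble with one row per flow condition: `donor_id`, `group`,
#'   `stress_dyn_cm2`, `shear_rate_s1`, `n_images`, `n_cells`, `di_mean`,
#'   ordered by increasing shear.
#' @export
aggregate_donor <- function(summaries, weighting = c("cells", "images"),
                            min_images = 5L) {
  weighting <- match.arg(weighting)
  ids <- unique(summaries$donor_id)
  if (length(ids) != 1L) {
    stop("`summaries` must all belong to one donor, got: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  out <- summaries |>
    dplyr::group_by(.data$donor_id, .data$group, .data$stress_dyn_cm2,
                    .data$shear_rate_s1) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      n_cells = sum(.data$n_cells),
      di_mean = if (weighting == "cells") {
        if (sum(.data$n_cells) > 0) sum(.data$di_total) / sum(.data$n_cells)
        else NA_real_
      } else {
        mean(.data$di_mean, na.rm = TRUE)
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$stress_dyn_cm2)
  short <- out$n_images < min_images
  if (any(short)) {
    warning(sprintf(
      "%d flow condition(s) have fewer than %d images", sum(short), min_images
    ), call. = FALSE)
  }
  out
}
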
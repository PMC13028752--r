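#' Pipeline configuration
#'
#' All tunable parameters of the two image pipelines in one place. Defaults
#' follow the published processing protocol where one exists (DoG sigmas,
#' top-hat element, Otsu scale factor, area window, DI cap, cell-size
#' criteria) and otherwise are declared package defaults. The contrast
#' stretch anchors its upper percentile at 99.9 so that, at realistic cell
#' densities (a fraction of a percent of pixels), it lands inside the cell
#' intensity range and the background stays compact after stretching; the
#' post-stretch Gaussian sigma of 0.5 px regularizes the binarization
#' without blurring 10-px cells enough to bias their measured axes.
#'
#' @param kernel_length Sine-window kernel length in samples (>= 1).
#' @param gaussian_sigma_sinewin Isotropic Gaussian sigma (px) applied after
#'   contrast enhancement in the sine-window pipeline.
#' @param contrast_percentiles Length-2 vector: percentiles of the residual
#'   mapped to 0 and 255 during contrast stretching.
#' @param diameter_range_px Equivalent-circle diameter window (px) for object
#'   detection in the sine-window pipeline.
#' @param lx_range,ly_range Acceptance windows for the major (flow-axis) and
#'   minor extents of a cell, in `criteria_units`.
#' @param elongation_fraction Minimum relative elongation: a cell is accepted
#'   only if `L_X - L_Y >= elongation_fraction * L_X`.
#' @param dog_sigma1,dog_sigma2 Narrow and wide Gaussian sigmas (px) of the
#'   Difference-of-Gaussians band-pass (`dog_sigma1 < dog_sigma2`).
#' @param tophat_length_px Length (px) of the horizontal line structuring
#'   element for the white top-hat; even values are promoted to the next odd
#'   number so the element is symmetric.
#' @param otsu_factor Scale factor applied to the Otsu threshold before
#'   binarization in the DoG pipeline.
#' @param area_range_px Inclusive component-area window (px) retained by the
#'   DoG pipeline.
#' @param di_cap Maximum deformability index; larger values are rejected as
#'   segmentation artifacts.
#' @param max_foreground_fraction Plausibility guard for binarization:
#'   isolated cells occupy at most a few percent of a frame, so if a
#'   threshold marks more than this fraction of pixels as foreground the
#'   image is treated as carrying no detectable objects (prevents spurious
#'   detections on frames that contain only background texture).
#' @param criteria_units Units in which `lx_range`/`ly_range` are expressed:
#'   `"pixels"` (as printed in the protocol) or `"micrometers"`. At
#'   0.6 um/px the pixel reading (4-9 px, i.e. 2.4-5.4 um) is smaller than an
#'   elongated RBC, so the micrometre reading is provided as a switch.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(kernel_length = 100L,
                            gaussian_sigma_sinewin = 0.5,
                            contrast_percentiles = c(1, 99.9),
                            diameter_range_px = c(3, 50),
                            lx_range = c(4, 9),
                            ly_range = c(2.5, 7),
                            elongation_fraction = 0.2,
                            dog_sigma1 = 0.7,
                            dog_sigma2 = 16,
                            tophat_length_px = 45L,
                            otsu_factor = 1.06,
                            area_range_px = c(50, 130),
                            di_cap = 0.35,
                            max_foreground_fraction = 0.15,
                            criteria_units = c("pixels", "micrometers")) {
  criteria_units <- match.arg(criteria_units)
  stopifnot(
    kernel_length >= 1,
    gaussian_sigma_sinewin >= 0,
    length(contrast_percentiles) == 2, diff(contrast_percentiles) > 0,
    contrast_percentiles[1] >= 0, contrast_percentiles[2] <= 100,
    length(diameter_range_px) == 2, diff(diameter_range_px) >= 0,
    length(lx_range) == 2, diff(lx_range) >= 0,
    length(ly_range) == 2, diff(ly_range) >= 0,
    elongation_fraction >= 0,
    dog_sigma1 > 0, dog_sigma2 > dog_sigma1,
    tophat_length_px >= 1,
    otsu_factor > 0,
    length(area_range_px) == 2, diff(area_range_px) >= 0,
    di_cap > 0,
    max_foreground_fraction > 0, max_foreground_fraction <= 1
  )
  structure(
    list(
      kernel_length = as.integer(kernel_length),
      gaussian_sigma_sinewin = gaussian_sigma_sinewin,
      contrast_percentiles = contrast_percentiles,
      diameter_range_px = diameter_range_px,
      lx_range = lx_range,
      ly_range = ly_range,
      elongation_fraction = elongation_fraction,
      dog_sigma1 = dog_sigma1,
      dog_sigma2 = dog_sigma2,
      tophat_length_px = as.integer(tophat_length_px),
      otsu_factor = otsu_factor,
      area_range_px = area_range_px,
      di_cap = di_cap,
      max_foreground_fraction = max_foreground_fraction,
      criteria_units = criteria_units
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " - ")))
  }
  invisible(x)
}
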
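#' Published reference DI profiles
#'
#' Group-mean deformability-index profiles (mean and SD over donors, 7 shear
#' steps) reported by a published microfluidic study of healthy and untreated
#' CLL donors, one column per analysis pipeline. The `sinewin` column is the
#' study's sine-window/ellipse-fit workflow and `dog` its
#' Difference-of-Gaussians workflow. Bundled as calibration input for
#' [fit_saturating_di()] / [cohort_model()] defaults and as a realism anchor
#' for synthetic cohorts; raw per-donor data are not public.
#'
#' @return A tibble with columns `pipeline` (`"sinewin"`/`"dog"`), `group`
#'   (`"healthy"`/`"cll"`), `stress_dyn_cm2`, `shear_rate_s1`, `di_mean`,
#'   `di_sd`.
#' @export
reference_di_profiles <- function() {
  rate <- c(89, 178, 268, 357, 446, 535, 625)
  tau <- 1:7
  tibble::tibble(
    pipeline = rep(c("dog", "sinewin"), each = 14L),
    group = rep(rep(c("healthy", "cll"), each = 7L), 2L),
    stress_dyn_cm2 = rep(tau, 4L),
    shear_rate_s1 = rep(rate, 4L),
    di_mean = c(
      0.157, 0.176, 0.191, 0.200, 0.205, 0.202, 0.204,  # dog, healthy
      0.136, 0.151, 0.156, 0.159, 0.175, 0.181, 0.182,  # dog, cll
      0.236, 0.271, 0.284, 0.293, 0.307, 0.291, 0.293,  # sinewin, healthy
      0.201, 0.212, 0.221, 0.228, 0.233, 0.233, 0.219   # sinewin, cll
    ),
    di_sd = c(
      0.011, 0.011, 0.010, 0.014, 0.010, 0.018, 0.013,
      0.014, 0.014, 0.009, 0.008, 0.007, 0.005, 0.014,
      0.029, 0.022, 0.020, 0.017, 0.016, 0.025, 0.024,
      0.023, 0.020, 0.018, 0.019, 0.019, 0.020, 0.029
    )
  )
}

#' Published reference mixed-effects statistics
#'
#' Fixed-effect F statistics and Satterthwaite degrees of freedom reported by
#' the same published study's linear mixed-effects analysis of DI (random
#' donor intercept; group, shear rate and their interaction as fixed
#' effects), one set per analysis pipeline. Bundled so effect sizes
#' ([partial_eta_squared()]) can be recomputed from the printed test
#' statistics.
#'
#' @return A tibble with columns `pipeline`, `effect`, `df1`, `df2`, `f`.
#' @export
reference_mixed_effects <- function() {
  tibble::tibble(
    pipeline = rep(c("sinewin", "dog"), each = 3L),
    effect = rep(c("group", "shear_rate", "group:shear_rate"), 2L),
    df1 = rep(c(1, 6, 6), 2L),
    df2 = c(20, 120, 120, 20.1, 119.2, 119.2),
    f = c(93.56, 35.22, 8.488, 61.72, 49.38, 2.86)
  )
}
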
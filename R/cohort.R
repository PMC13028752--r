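#' Saturating cohort model for shear-dependent deformability
#'
#' Describes how a donor population's mean DI responds to wall shear stress:
#' a saturating (Michaelis-Menten-like) curve
#' `DI(tau) = DI_max * tau / (tau_half + tau)` per group, a Gaussian random
#' intercept per donor, and Gaussian within-donor residual noise. The
#' saturating form reflects the physiology: RBC elongation rises with shear
#' and approaches a maximal value at high stress.
#'
#' Default curve parameters are least-squares fits of that form to published
#' group-mean DI profiles of healthy and CLL donors (7 shear steps,
#' 1-7 dyn/cm2), so synthetic cohorts resemble realistic effect sizes; the
#' default cohort sizes (13 healthy, 9 CLL) match the same study design.
#'
#' @param di_max Named vector of asymptotic DI per group.
#' @param tau_half Named vector of half-saturation stress (dyn/cm2) per group.
#' @param donor_sd SD of the donor random intercept.
#' @param residual_sd SD of within-donor measurement noise.
#' @param n_donors Named vector of donors per group.
#' @param stress_levels Applied wall shear stresses, dyn/cm2 (increasing).
#' @param viscosity_mPas Suspension viscosity used to attach shear rates.
#' @return A `cohort_model` list.
#' @export
cohort_model <- function(di_max = c(healthy = 0.2173, cll = 0.1873),
                         tau_half = c(healthy = 0.4024, cll = 0.4373),
                         donor_sd = 0.010,
                         residual_sd = 0.005,
                         n_donors = c(healthy = 13L, cll = 9L),
                         stress_levels = 1:7,
                         viscosity_mPas = 1.12) {
  stopifnot(
    all(di_max > 0), all(di_max < 1), all(tau_half > 0),
    donor_sd >= 0, residual_sd >= 0, all(n_donors >= 1),
    all(stress_levels > 0), !is.unsorted(stress_levels, strictly = TRUE),
    identical(sort(names(di_max)), sort(names(tau_half))),
    identical(sort(names(di_max)), sort(names(n_donors)))
  )
  structure(
    list(di_max = di_max, tau_half = tau_half, donor_sd = donor_sd,
         residual_sd = residual_sd, n_donors = n_donors,
         stress_levels = stress_levels, viscosity_mPas = viscosity_mPas),
    class = "cohort_model"
  )
}

#' Expected DI at a given shear stress
#'
#' Evaluates the noise-free saturating response of a [cohort_model()] group:
#' `DI_max * tau / (tau_half + tau)`.
#'
#' @param stress_dyn_cm2 Wall shear stress, dyn/cm2 (> 0). Vectorized.
#' @param model A [cohort_model()].
#' @param group Group label present in the model.
#' @return Expected DI value(s).
#' @export
#' @examples
#' m <- cohort_model()
#' expected_di(m$tau_half[["healthy"]], m, "healthy")  # DI_max / 2
expected_di <- function(stress_dyn_cm2, model = cohort_model(),
                        group = "healthy") {
  if (any(stress_dyn_cm2 <= 0)) stop("stress must be positive", call. = FALSE)
  if (!group %in% names(model$di_max)) {
    stop(sprintf("unknown group '%s' (model has: %s)", group,
                 paste(names(model$di_max), collapse = ", ")), call. = FALSE)
  }
  model$di_max[[group]] * stress_dyn_cm2 /
    (model$tau_half[[group]] + stress_dyn_cm2)
}

#' Generate a synthetic donor cohort of DI measurements
#'
#' Draws one DI value per donor and shear step:
#' `DI = expected_di(tau) + donor intercept + residual noise`, clipped to
#' \[0.01, 0.99\]. Deterministic given `seed`.
#'
#' @param model A [cohort_model()].
#' @param seed Integer RNG seed.
#' @return A tibble with columns `donor_id`, `group`, `stress_dyn_cm2`,
#'   `shear_rate_s1`, `di_mean` (one row per donor x shear step).
#' @export
generate_cohort <- function(model = cohort_model(), seed = 1L) {
  groups <- names(model$n_donors)
  with_seed(seed, {
    rows <- purrr::map(groups, function(g) {
      n <- model$n_donors[[g]]
      intercepts <- stats::rnorm(n, 0, model$donor_sd)
      purrr::map(seq_len(n), function(i) {
        tau <- model$stress_levels
        di <- expected_di(tau, model, g) + intercepts[i] +
          stats::rnorm(length(tau), 0, model$residual_sd)
        tibble::tibble(
          donor_id = sprintf("%s_%02d", g, i),
          group = g,
          stress_dyn_cm2 = tau,
          shear_rate_s1 = stress_to_rate(tau, model$viscosity_mPas),
          di_mean = pmin(pmax(di, 0.01), 0.99)
        )
      })
    })
    dplyr::bind_rows(rows)
  })
}

#' Fit the saturating DI model to a stress-response profile
#'
#' Least-squares (Levenberg-Marquardt) fit of
#' `DI = DI_max * tau / (tau_half + tau)` to observed `(stress, DI)` pairs.
#' Used to calibrate [cohort_model()] parameters against measured or
#' published group-mean profiles.
#'
#' @param stress_dyn_cm2 Applied stresses, dyn/cm2.
#' @param di Observed mean DI at each stress.
#' @return A one-row tibble: `di_max`, `tau_half`, `max_abs_resid`.
#' @export
fit_saturating_di <- function(stress_dyn_cm2, di) {
  stopifnot(length(stress_dyn_cm2) == length(di), length(di) >= 3)
  dat <- data.frame(tau = stress_dyn_cm2, di = di)
  fit <- minpack.lm::nlsLM(
    di ~ dmax * tau / (k + tau),
    data = dat,
    start = list(dmax = max(di), k = stats::median(dat$tau) / 4)
  )
  co <- stats::coef(fit)
  pred <- co[["dmax"]] * dat$tau / (co[["k"]] + dat$tau)
  tibble::tibble(
    di_max = co[["dmax"]],
    tau_half = co[["k"]],
    max_abs_resid = max(abs(pred - dat$di))
  )
}
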
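#' Partial eta squared of a fixed effect
#'
#' Effect-size measure for a fixed effect tested with an F statistic:
#' `F * df1 / (F * df1 + df2)`, the proportion of variance attributable to
#' the effect net of the other model terms. With Satterthwaite-approximated
#' denominator degrees of freedom this reproduces the effect sizes reported
#' alongside mixed-model F tests.
#'
#' @param f F statistic (>= 0). Vectorized.
#' @param df1 Numerator degrees of freedom (>= 1).
#' @param df2 Denominator degrees of freedom (> 0), possibly fractional.
#' @return Partial eta squared in \[0, 1).
#' @export
#' @examples
#' partial_eta_squared(93.56, 1, 20)  # 0.82 at 2 decimals
partial_eta_squared <- function(f, df1, df2) {
  if (any(f < 0)) stop("F must be non-negative", call. = FALSE)
  if (any(df1 < 1) || any(df2 <= 0)) {
    stop("invalid degrees of freedom", call. = FALSE)
  }
  f * df1 / (f * df1 + df2)
}

#' Linear mixed-effects model of shear-dependent deformability
#'
#' Fits the repeated-measures model used to compare donor groups: a random
#' intercept per donor, with group, shear level and their interaction as
#' fixed effects; shear enters as a categorical factor (each applied shear
#' step is its own level), so the shear main effect has `levels - 1`
#' numerator degrees of freedom. The model is fitted by REML; each fixed
#' effect is tested with a Type III F test whose denominator degrees of
#' freedom use the Satterthwaite approximation, and effect sizes are
#' [partial_eta_squared()] of those tests.
#'
#' @param cohort Data frame with columns `donor_id`, `group`, a shear column
#'   (`stress_dyn_cm2` or `shear_rate_s1`) and a response column.
#' @param response Name of the response column (default `"di_mean"`).
#' @param shear Name of the shear column (default `"stress_dyn_cm2"`).
#' @return An object of class `rbcdi_mixed`: a list with `effects` (tibble:
#'   `effect`, `df1`, `df2`, `f`, `p_value`, `eta2p`), `model` (the
#'   underlying `lmerModLmerTest` fit), `n_obs`, `n_donors`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_mixed_model <- function(cohort, response = "di_mean",
                            shear = "stress_dyn_cm2") {
  needed <- c("donor_id", "group", shear, response)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- data.frame(
    donor_id = factor(cohort$donor_id),
    group = factor(cohort$group),
    shear = factor(cohort[[shear]]),
    y = cohort[[response]]
  )
  donors_per_group <- tapply(dat$donor_id, dat$group,
                             function(d) length(unique(d)))
  if (any(donors_per_group < 2)) {
    stop("each group needs at least 2 donors", call. = FALSE)
  }
  if (nlevels(dat$shear) < 2) {
    stop("need at least 2 shear levels", call. = FALSE)
  }
  fit <- lmerTest::lmer(y ~ group * shear + (1 | donor_id), data = dat,
                        REML = TRUE)
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  effects <- tibble::tibble(
    effect = sub("shear", "shear_rate", rownames(an)),
    df1 = an$NumDF,
    df2 = an$DenDF,
    f = an$`F value`,
    p_value = an$`Pr(>F)`
  )
  effects$eta2p <- partial_eta_squared(effects$f, effects$df1, effects$df2)
  structure(
    list(effects = effects, model = fit,
         n_obs = nrow(dat), n_donors = length(unique(dat$donor_id))),
    class = "rbcdi_mixed"
  )
}

#' @export
print.rbcdi_mixed <- function(x, ...) {
  cat(sprintf("<rbcdi_mixed> %d observations, %d donors\n", x$n_obs, x$n_donors))
  print(x$effects)
  invisible(x)
}

#' @rdname fit_mixed_model
#' @param x An `rbcdi_mixed` object.
#' @param ... Unused.
#' @export
tidy.rbcdi_mixed <- function(x, ...) x$effects

#' @rdname fit_mixed_model
#' @export
glance.rbcdi_mixed <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_donors = x$n_donors,
    sigma = stats::sigma(x$model),
    donor_sd = sqrt(unname(unlist(lme4::VarCorr(x$model)))[1]),
    logLik = as.numeric(stats::logLik(x$model)),
    REMLcrit = lme4::REMLcrit(x$model)
  )
}

#' @rdname fit_mixed_model
#' @param object An `rbcdi_mixed` object.
#' @export
autoplot.rbcdi_mixed <- function(object, ...) {
  eff <- object$effects
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$effect, y = .data$eta2p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("F = %.2f\np = %.3g", .data$f, .data$p_value)),
      vjust = -0.3, size = 3
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "partial eta squared",
                  title = "Fixed-effect sizes (mixed model)") +
    ggplot2::theme_minimal()
}
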
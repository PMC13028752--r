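#' Bland-Altman agreement between two measurement methods
#'
#' Quantifies agreement between paired measurements of the same quantity by
#' two methods: differences `d = x - y` give the mean bias, the 95% limits
#' of agreement `bias +/- 1.96 * SD(d)` (sample SD, the classic definition),
#' the fraction of pairs inside the limits, and a proportional-bias check by
#' ordinary least squares of `d` on the pair means `(x + y) / 2` with a
#' two-sided t test on the slope. By convention `x` is the sine-window
#' pipeline and `y` the DoG pipeline, so a positive bias means the
#' sine-window route reads higher.
#'
#' @param x,y Paired numeric vectors of equal length, `n >= 3`.
#' @return An object of class `rbcdi_agreement` wrapping a one-row tibble
#'   (`bias`, `sd_diff`, `loa_low`, `loa_high`, `pct_within`,
#'   `prop_bias_slope`, `prop_bias_p`, `n`); supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  within <- mean(d >= loa[1] & d <= loa[2])
  if (max(m) > min(m)) {
    fit <- stats::lm(d ~ m)
    # a perfect fit (e.g. constant differences) is legitimate here; its
    # slope test is reported as NA below rather than via lm's warning
    sm <- suppressWarnings(stats::coef(summary(fit)))
    slope <- sm[2, "Estimate"]
    slope_p <- if (is.finite(sm[2, "Std. Error"]) && sm[2, "Std. Error"] > 0) {
      sm[2, "Pr(>|t|)"]
    } else {
      NA_real_
    }
  } else {
    slope <- NA_real_
    slope_p <- NA_real_
  }
  res <- tibble::tibble(
    bias = bias, sd_diff = sd_d, loa_low = loa[1], loa_high = loa[2],
    pct_within = within, prop_bias_slope = slope, prop_bias_p = slope_p,
    n = n
  )
  structure(list(result = res, differences = d, means = m),
            class = "rbcdi_agreement")
}

#' @export
print.rbcdi_agreement <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<rbcdi_agreement> n = %d\n  bias %.4f, 95%% LoA [%.4f, %.4f], %.0f%% within\n",
    r$n, r$bias, r$loa_low, r$loa_high, 100 * r$pct_within
  ))
  invisible(x)
}

#' @rdname bland_altman
#' @param x,object An `rbcdi_agreement` object.
#' @param ... Unused.
#' @export
tidy.rbcdi_agreement <- function(x, ...) x$result

#' @rdname bland_altman
#' @export
glance.rbcdi_agreement <- function(x, ...) {
  x$result[, c("bias", "loa_low", "loa_high", "n")]
}

#' @rdname bland_altman
#' @export
autoplot.rbcdi_agreement <- function(object, ...) {
  r <- object$result
  df <- tibble::tibble(mean = object$means, difference = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = r$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(r$loa_low, r$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "mean of paired DI", y = "difference (sinewin - dog)",
      title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
                      r$bias, r$loa_low, r$loa_high)
    ) +
    ggplot2::theme_minimal()
}
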
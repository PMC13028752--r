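test_that("Shapiro-Wilk wrapper rejects degenerate input and detects non-normality", {
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "between 3 and 5000")

  set.seed(1)
  expect_lt(shapiro_wilk(runif(500))$p_value, 0.01)

  # type-I error near nominal for normal data
  set.seed(2)
  rej <- mean(replicate(1000, shapiro_wilk(rnorm(50))$p_value < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Mann-Whitney exact path enumerates correctly and is symmetric", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$method, "normal_approx")  # ties force the approximation

  # swapping groups preserves p and reflects U
  set.seed(5)
  for (i in 1:20) {
    a <- sample(100, sample(3:8, 1)) / 10
    b <- sample(1000, sample(3:12, 1)) / 101
    ab <- mann_whitney(a, b); ba <- mann_whitney(b, a)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    expect_equal(ab$u, length(a) * length(b) - ba$u)
  }

  # exact path agrees with the reference exact test on untied samples
  set.seed(6)
  for (i in 1:30) {
    a <- runif(sample(3:8, 1))
    b <- runif(sample(3:8, 1))
    ours <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$method, "exact")
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("Pearson wrapper matches its closed form and affine invariance", {
  x <- c(2, 5, 9, 11)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)

  r <- pearson(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-9)

  set.seed(3)
  u <- rnorm(30); v <- rnorm(30)
  expect_equal(pearson(3 * u + 7, v)$r, pearson(u, v)$r, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("partial eta squared reproduces published effect sizes", {
  expect_equal(round(partial_eta_squared(93.56, 1, 20), 2), 0.82)
  expect_equal(round(partial_eta_squared(35.22, 6, 120), 2), 0.64)
  expect_equal(partial_eta_squared(0, 3, 50), 0)
  expect_error(partial_eta_squared(-1, 1, 10), "non-negative")
  expect_error(partial_eta_squared(1, 0, 10), "degrees of freedom")

  ref <- reference_mixed_effects()
  eta <- round(partial_eta_squared(ref$f, ref$df1, ref$df2), 2)
  # five of the six published values match at two decimals; the sixth
  # (dog-pipeline group effect) rounds to 0.75 from the printed F and df
  # versus a published 0.76, a known rounding artefact of unprinted precision
  expect_equal(eta, c(0.82, 0.64, 0.30, 0.75, 0.71, 0.13))
})

test_that("mixed model detects generated group effects with Satterthwaite tests", {
  m <- cohort_model(di_max = c(healthy = 0.41, cll = 0.30),
                    tau_half = c(healthy = 0.4, cll = 0.4),
                    donor_sd = 0.01, residual_sd = 0.01,
                    n_donors = c(healthy = 10, cll = 10))
  fit <- fit_mixed_model(generate_cohort(m, seed = 7))
  eff <- tidy(fit)
  grp <- eff[eff$effect == "group", ]
  expect_lt(grp$p_value, 0.001)
  expect_gt(grp$eta2p, 0.5)
  expect_equal(eff$df1, c(1, 6, 6))  # categorical shear: levels - 1
  expect_equal(eff$eta2p,
               eff$f * eff$df1 / (eff$f * eff$df1 + eff$df2),
               tolerance = 1e-12)
  expect_equal(nrow(glance(fit)), 1L)

  single <- generate_cohort(
    cohort_model(n_donors = c(healthy = 1, cll = 5)), seed = 1
  )
  expect_error(fit_mixed_model(single), "at least 2 donors")
})

test_that("mixed model recovers generated group offsets within 2 SE", {
  m <- cohort_model(di_max = c(healthy = 0.30, cll = 0.24),
                    tau_half = c(healthy = 0.4, cll = 0.4),
                    donor_sd = 0.012, residual_sd = 0.008,
                    n_donors = c(healthy = 11, cll = 9))
  # true group difference in means over the 7 stress levels
  tau <- m$stress_levels
  delta <- mean(expected_di(tau, m, "healthy") - expected_di(tau, m, "cll"))
  hits <- vapply(1:100, function(s) {
    co <- generate_cohort(m, seed = 1000 + s)
    fit <- lmerTest::lmer(di_mean ~ group + factor(stress_dyn_cm2) +
                            (1 | donor_id), data = co)
    sm <- summary(fit)$coefficients
    est <- sm["grouphealthy", "Estimate"]  # healthy minus cll (cll = reference)
    se <- sm["grouphealthy", "Std. Error"]
    abs(est - delta) <= 2 * se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Bland-Altman agreement matches hand-computed limits", {
  x <- c(0.20, 0.25, 0.31, 0.40)
  y <- c(0.15, 0.18, 0.25, 0.30)
  res <- tidy(bland_altman(x, y))
  d <- x - y
  expect_equal(res$bias, mean(d))
  expect_equal(res$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(res$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(res$pct_within, 1)

  # self-agreement: zero bias, zero-width limits, no proportional bias
  set.seed(8)
  z <- runif(25, 0.1, 0.35)
  self <- tidy(bland_altman(z, z))
  expect_equal(self$bias, 0)
  expect_equal(self$loa_low, 0)
  expect_equal(self$loa_high, 0)
  expect_equal(self$prop_bias_slope, 0)

  shift <- tidy(bland_altman(z + 0.1, z))
  expect_equal(shift$bias, 0.1)
  expect_equal(shift$sd_diff, 0)
  expect_equal(shift$loa_low, 0.1)
  expect_equal(shift$loa_high, 0.1)

  expect_error(bland_altman(1:4, 1:5), "equal length")
})

test_that("result objects expose tidiers and plots", {
  set.seed(10)
  x <- runif(30, 0.1, 0.3); y <- x + rnorm(30, 0.05, 0.01)
  ba <- bland_altman(x, y)
  expect_s3_class(autoplot(ba), "ggplot")
  expect_equal(glance(ba)$n, 30)

  co <- generate_cohort(seed = 2)
  expect_s3_class(plot_di_profiles(co), "ggplot")
  fit <- fit_mixed_model(co)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(generate_image(n_cells = 3, height = 64, width = 64,
                                          seed = 1)$grid), "ggplot")
})
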
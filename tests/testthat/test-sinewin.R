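test_that("sine-window kernel is normalized, symmetric, and centre-peaked", {
  expect_equal(sine_window_kernel(1), 1)
  expect_equal(sine_window_kernel(3), c(1 / 6, 2 / 3, 1 / 6))
  for (n in c(2, 5, 10, 37, 100)) {
    w <- sine_window_kernel(n)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, rev(w))
    expect_true(all(w > 0))
    centre <- c(floor((n + 1) / 2), ceiling((n + 1) / 2))
    expect_true(which.max(w) %in% centre)  # maximum at the centre (pair if even)
  }
  expect_error(sine_window_kernel(0), "at least 1")
})

test_that("background suppression zeroes constants and linear ramps", {
  const <- intensity_grid(matrix(42, 32, 180))
  expect_lt(max(abs(as.matrix(suppress_background(const)))), 1e-9)

  ramp <- intensity_grid(matrix(rep(0.37 * seq_len(300) + 5, each = 24), 24, 300))
  res <- as.matrix(suppress_background(ramp))
  expect_lt(max(abs(res[, 51:250])), 1e-9)  # interior, >= n/2 from edges

  expect_error(suppress_background(intensity_grid(matrix(0, 4, 50))),
               "kernel longer")
})

test_that("residual energy concentrates at the cell", {
  flat <- intensity_grid(matrix(100, 200, 200))
  rc <- render_cells(flat, data.frame(center_x = 100, center_y = 100,
                                      a = 5, b = 4, theta_deg = 0,
                                      amplitude = 70))
  e <- as.matrix(suppress_background(rc$grid))^2
  xs <- matrix(seq_len(200), 200, 200, byrow = TRUE)
  ys <- matrix(seq_len(200), 200, 200)
  near <- (xs - 100)^2 + (ys - 100)^2 <= 20^2  # two cell diameters
  expect_gt(sum(e[near]) / sum(e), 0.9)
})

test_that("contrast enhancement rescales, warns on degenerate input, and preserves the mean under smoothing", {
  v <- matrix(seq(0, 255, length.out = 64 * 64), 64, 64)
  out <- enhance(v, c(0, 100), 0)
  expect_equal(as.matrix(out), v, tolerance = 1e-9)

  expect_warning(z <- enhance(matrix(5, 40, 40), c(1, 99), 1), "degenerate")
  expect_equal(as.matrix(z), matrix(0, 40, 40))

  r <- matrix(runif(50 * 50, 0, 255), 50, 50)
  m0 <- mean(as.matrix(enhance(r, c(0, 100), 0)))
  m1 <- mean(as.matrix(enhance(r, c(0, 100), 1)))
  expect_lt(abs(m0 - m1), 0.5)
})

test_that("object detection applies the equivalent-diameter window", {
  expect_length(detect_objects(matrix(0, 50, 50)), 0)

  blank <- matrix(0, 60, 60)
  disk <- raster_ellipse(3, 3, 0, 30, 30)
  blank[cbind(disk[, 2], disk[, 1])] <- 200
  comps <- detect_objects(blank)
  expect_length(comps, 1)
  expect_equal(nrow(comps[[1]]), nrow(disk))

  # a 2500-px component has equivalent diameter 56.4 > 50 and is rejected
  big <- matrix(0, 80, 80)
  big[15:64, 15:64] <- 200
  expect_length(detect_objects(big), 0)
})

test_that("ellipse fitting is exact on exact points and sound on rasters", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  f <- fit_ellipse(cbind(10 + 4.5 * cos(th), 20 + 3 * sin(th)), points = TRUE)
  expect_equal(f$major_diameter, 9, tolerance = 1e-6)
  expect_equal(f$minor_diameter, 6, tolerance = 1e-6)
  expect_equal(f$orientation_deg, 0, tolerance = 1e-6)
  expect_equal(f$center_x, 10, tolerance = 1e-6)

  circ <- fit_ellipse(cbind(5 + 2 * cos(th), 7 + 2 * sin(th)), points = TRUE)
  expect_equal(circ$major_diameter, 4, tolerance = 1e-6)
  expect_equal(circ$minor_diameter, 4, tolerance = 1e-6)

  # larger rotated raster: diameters within 10%, orientation within 3 degrees
  f2 <- fit_ellipse(raster_ellipse(9, 6, 30))
  expect_lt(abs(f2$major_diameter - 18) / 18, 0.1)
  expect_lt(abs(f2$minor_diameter - 12) / 12, 0.1)
  expect_lt(abs(f2$orientation_deg - 30), 3)

  # tiny raster (semi-axes 3 and 2 at 30 deg): too coarse to carry its
  # orientation -- its true second-moment ellipse, computed independently,
  # is at 45 deg with diameters 6.462 x 3.848; the fit must agree with that
  f3 <- fit_ellipse(raster_ellipse(3, 2, 30))
  expect_lt(abs(f3$major_diameter - 6.462) / 6, 0.1)
  expect_lt(abs(f3$minor_diameter - 3.848) / 4, 0.1)

  expect_error(fit_ellipse(cbind(1:2, 1:2)), "at least 3")
})

test_that("acceptance criteria follow the printed rules in order", {
  cfg <- pipeline_config()
  expect_true(accept_cell(8, 6, cfg)$accepted)
  r1 <- accept_cell(6, 5.5, cfg)
  expect_false(r1$accepted)
  expect_equal(r1$reason, "elongation_below_threshold")
  r2 <- accept_cell(10, 5, cfg)
  expect_false(r2$accepted)
  expect_equal(r2$reason, "lx_out_of_range")
  r3 <- accept_cell(6, 6.5, cfg)
  expect_equal(r3$reason, "not_elongated")

  # micrometre units rescale criterion (c)
  cfg_um <- pipeline_config(criteria_units = "micrometers")
  expect_true(accept_cell(12, 8, cfg_um, um_per_px = 0.6)$accepted)   # 7.2 x 4.8 um
  expect_false(accept_cell(12, 8, cfg, um_per_px = 0.6)$accepted)     # 12 px > 9

  # accepted cells imply DI >= 1/9 via criterion (b)
  lx <- runif(200, 4, 9)
  ly <- runif(200, 2.5, 7)
  acc <- accept_cell(lx, ly, cfg)$accepted
  di <- deformability_index(lx, ly)
  expect_true(all(di[acc] >= 1 / 9 - 1e-12))

  # tightening the elongation requirement never accepts more cells
  counts <- vapply(c(0.1, 0.2, 0.3, 0.4), function(ef) {
    sum(accept_cell(lx, ly, pipeline_config(elongation_fraction = ef))$accepted)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sinewin pipeline recovers known cells and rejects near-circular ones", {
  cfg <- pipeline_config(criteria_units = "micrometers")
  img <- generate_image(
    n_cells = 20, background = background_spec(noise_sd = 0),
    cell_ranges = list(a = c(4.0, 6.3), di = c(0.14, 0.30),
                       theta_deg = c(-15, 15), amplitude = c(60, 90)),
    seed = 31
  )
  rs <- run_sinewin(img$grid, cfg)
  acc <- rs$cells[rs$cells$accepted, ]
  expect_gte(nrow(acc), 18)
  tr <- match_truth(acc, img$truth)
  expect_lte(mean(abs(acc$di - tr$di)), 0.02)
  expect_equal(rs$summary$n_cells, nrow(acc))
  expect_equal(rs$summary$di_total, sum(acc$di))

  # near-circular cells (L_Y > 0.8 L_X) all fail criterion (b)
  round_img <- generate_image(
    n_cells = 15, background = background_spec(noise_sd = 0),
    cell_ranges = list(a = c(4.5, 6), di = c(0.01, 0.07),
                       theta_deg = c(-15, 15), amplitude = c(60, 90)),
    seed = 7
  )
  rr <- run_sinewin(round_img$grid, cfg)
  expect_equal(sum(rr$cells$accepted), 0)

  # pure background yields no accepted cells
  bg <- generate_image(n_cells = 0, seed = 13)
  expect_equal(sum(run_sinewin(bg$grid, cfg)$cells$accepted), 0)
})
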
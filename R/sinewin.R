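# The sine-window workflow: background suppression by subtracting a 1-D
# sine-window convolution along the flow axis, contrast enhancement, object
# detection, least-squares ellipse fitting, and the three cell-acceptance
# criteria.

#' Squared sine-window convolution kernel
#'
#' One-dimensional smoothing kernel built from the positive half cycle of a
#' sine: the half-cycle is sampled at `n` midpoints, squared, and normalized
#' to unit sum so convolution preserves overall image intensity. The window
#' is symmetric with its maximum at the centre. Midpoint sampling
#' (`sin^2(pi (k + 0.5) / n)`) avoids zero-valued endpoints that would waste
#' kernel support, and remains well defined at `n = 1`.
#'
#' @param n Kernel length in samples (>= 1). The default 100 is the length
#'   used to smooth streamline backgrounds at 0.6 um/px.
#' @return Numeric vector of `n` non-negative weights summing to one.
#' @export
#' @examples
#' sine_window_kernel(3)  # 1/6, 2/3, 1/6
sine_window_kernel <- function(n = 100L) {
  if (n < 1) stop("kernel length must be at least 1", call. = FALSE)
  w <- sin(pi * (seq_len(n) - 0.5) / n)^2
  w <- (w + rev(w)) / 2  # exact symmetry (floating-point sin is not)
  w / sum(w)
}

#' Suppress streamline background by sine-window subtraction
#'
#' Convolves every row with the kernel along the flow (X) axis with
#' edge-replicated boundaries, then subtracts the smoothed image from the
#' original. Streamline backgrounds vary smoothly along X, so the smoothing
#' reproduces them almost exactly and their residual vanishes, while compact
#' bright cells survive as positive residual. The residual may be negative.
#'
#' @param grid An [intensity_grid()] or matrix.
#' @param kernel Convolution weights, e.g. [sine_window_kernel()]; must not
#'   be longer than an image row.
#' @return An [intensity_grid()] of residuals (original minus smoothed).
#' @export
suppress_background <- function(grid, kernel = sine_window_kernel()) {
  grid <- as_grid(grid)
  filtered <- convolve_rows(grid$values, kernel)
  intensity_grid(grid$values - filtered, um_per_px = grid$um_per_px)
}

#' Contrast enhancement of a background-suppressed residual
#'
#' Linearly rescales the residual so that its lower/upper contrast
#' percentiles map to 0/255 (values outside are clipped), then applies an
#' isotropic Gaussian smoothing. A degenerate percentile range (both
#' percentiles at the same value, e.g. a constant residual) yields a zero
#' grid with a warning.
#'
#' @param grid An [intensity_grid()] or matrix.
#' @param contrast_percentiles Length-2 percentiles (0-100) mapped to 0/255.
#' @param gaussian_sigma Gaussian sigma in px; 0 disables smoothing.
#' @return An [intensity_grid()] on the \[0, 255\] scale.
#' @export
enhance <- function(grid, contrast_percentiles = c(1, 99), gaussian_sigma = 1.0) {
  grid <- as_grid(grid)
  stopifnot(length(contrast_percentiles) == 2,
            contrast_percentiles[1] >= 0, contrast_percentiles[2] <= 100,
            contrast_percentiles[1] < contrast_percentiles[2],
            gaussian_sigma >= 0)
  q <- stats::quantile(grid$values, contrast_percentiles / 100, names = FALSE)
  if (q[1] == q[2]) {
    warning("degenerate contrast range: returning zero grid", call. = FALSE)
    return(intensity_grid(matrix(0, nrow(grid$values), ncol(grid$values)),
                          um_per_px = grid$um_per_px))
  }
  v <- (grid$values - q[1]) / (q[2] - q[1]) * 255
  v <- pmin(pmax(v, 0), 255)
  v <- gaussian_blur(v, gaussian_sigma)
  intensity_grid(v, um_per_px = grid$um_per_px)
}

#' Detect candidate cell objects in an enhanced image
#'
#' Binarizes with [otsu_threshold()] (foreground at or above threshold),
#' labels 8-connected components, and keeps components whose
#' equivalent-circle diameter `2 sqrt(area / pi)` falls inside
#' `diameter_range_px`.
#'
#' @param grid An [intensity_grid()] or matrix (enhanced residual).
#' @param diameter_range_px Inclusive diameter window, px.
#' @param max_fg_fraction Foreground-fraction plausibility guard (see
#'   [pipeline_config()]); thresholds marking more than this fraction of the
#'   frame indicate background texture rather than isolated cells, and the
#'   detection returns empty.
#' @return A list of components, each a 2-column matrix of pixel coordinates
#'   (`x`, `y`); empty list when nothing qualifies.
#' @export
detect_objects <- function(grid, diameter_range_px = c(3, 50),
                           max_fg_fraction = 0.15) {
  grid <- as_grid(grid)
  v <- grid$values
  if (min(v) == max(v)) return(list())
  thr <- otsu_threshold(grid)
  fg <- v >= thr
  if (mean(fg) > max_fg_fraction) return(list())
  comps <- component_pixels(label_components(fg))
  keep <- vapply(comps, function(p) {
    d <- 2 * sqrt(nrow(p) / pi)
    d >= diameter_range_px[1] && d <= diameter_range_px[2]
  }, logical(1))
  unname(comps[keep])
}

# --- ellipse fitting ---------------------------------------------------------

# Outer contour of a filled pixel set: pixels with a 4-neighbour outside.
contour_pixels <- function(px) {
  key <- function(x, y) paste(x, y)
  inside <- new.env(hash = TRUE, size = nrow(px))
  for (i in seq_len(nrow(px))) assign(key(px[i, 1], px[i, 2]), TRUE, inside)
  on_contour <- vapply(seq_len(nrow(px)), function(i) {
    x <- px[i, 1]; y <- px[i, 2]
    !all(vapply(list(c(x + 1, y), c(x - 1, y), c(x, y + 1), c(x, y - 1)),
                function(n) exists(key(n[1], n[2]), inside), logical(1)))
  }, logical(1))
  px[on_contour, , drop = FALSE]
}

# Numerically stable direct least-squares ellipse fit (conic with the
# ellipse-specific constraint 4AC - B^2 = 1). Returns conic coefficients
# (A, B, C, D, E, F) or NULL when the fit is degenerate.
fit_conic <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my
  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1); s2 <- crossprod(d1, d2); s3 <- crossprod(d2)
  tmat <- tryCatch(-solve(s3, t(s2)), error = function(e) NULL)
  if (is.null(tmat)) return(NULL)
  m <- s1 + s2 %*% tmat
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  eg <- tryCatch(eigen(m), error = function(e) NULL)
  if (is.null(eg)) return(NULL)
  vecs <- Re(eg$vectors)
  vals <- Re(eg$values)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  # exactly one eigenvalue is positive for non-degenerate data; its
  # eigenvector is the constrained least-squares solution
  ok <- which(vals > 0 & cond > 0)
  if (length(ok) == 0L) ok <- which(cond > 0)
  if (length(ok) == 0L) return(NULL)
  a1 <- vecs[, ok[1]]
  coefs <- c(a1, tmat %*% a1)
  # undo the centering shift
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4] - 2 * A * mx - B * my
  E <- coefs[5] - 2 * C * my - B * mx
  F <- coefs[6] + A * mx^2 + B * mx * my + C * my^2 - coefs[4] * mx - coefs[5] * my
  c(A, B, C, D, E, F)
}

conic_to_ellipse <- function(co) {
  if (co[1] + co[3] < 0) co <- -co  # canonical sign: A + C > 0 for ellipses
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  den <- B^2 - 4 * A * C
  if (!is.finite(den) || den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + s)) / den
  ax2 <- -sqrt(num * (A + C - s)) / den
  if (!is.finite(ax1) || !is.finite(ax2) || ax1 <= 0 || ax2 <= 0) return(NULL)
  semi <- sort(c(ax1, ax2), decreasing = TRUE)
  # for near-zero cross terms atan2(C - A - s, B) is numerically unstable
  theta <- if (abs(B) > 1e-9 * (abs(A) + abs(C))) {
    atan2(C - A - s, B)
  } else if (A <= C) 0 else pi / 2
  theta <- theta * 180 / pi
  theta <- ((theta + 90) %% 180) - 90
  list(center_x = cx, center_y = cy,
       major_diameter = 2 * semi[1], minor_diameter = 2 * semi[2],
       orientation_deg = theta)
}

moment_ellipse <- function(px) {
  x <- px[, 1]; y <- px[, 2]
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  # +1/12 accounts for the unit extent of each pixel around its centre
  sxx <- sum((x - cx)^2) / n + 1 / 12
  syy <- sum((y - cy)^2) / n + 1 / 12
  sxy <- sum((x - cx) * (y - cy)) / n
  eg <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  semi <- 2 * sqrt(pmax(eg$values, 1e-12))
  v <- eg$vectors[, 1]
  theta <- atan2(v[2], v[1]) * 180 / pi
  theta <- ((theta + 90) %% 180) - 90
  list(center_x = cx, center_y = cy,
       major_diameter = 2 * semi[1], minor_diameter = 2 * semi[2],
       orientation_deg = theta)
}

#' Fit an equivalent ellipse to a cell
#'
#' Direct least-squares conic fitting to the cell's outer contour, the
#' classic route to an equivalent ellipse that captures anisotropic
#' elongation while smoothing local contour irregularities. When the conic
#' fit is degenerate (non-ellipse solution, ill conditioning, or fewer than 5
#' distinct contour points) the fit falls back to the second-order
#' central-moment ellipse of the full pixel set (same centroid and
#' covariance).
#'
#' @param px Either a 2-column matrix of filled component pixel coordinates
#'   (`x`, `y`; >= 3 pixels) or, with `points = TRUE`, arbitrary contour
#'   point coordinates to fit directly.
#' @param points If `TRUE`, treat `px` rows as exact contour points (no
#'   contour extraction, no moment correction for pixel extent).
#' @return A one-row tibble: `center_x`, `center_y`, `major_diameter`,
#'   `minor_diameter`, `orientation_deg` (degrees in (-90, 90\],
#'   major axis vs. X), `method` (`"conic"` or `"moments"`).
#' @export
fit_ellipse <- function(px, points = FALSE) {
  px <- as.matrix(px)
  if (nrow(px) < 3L) stop("need at least 3 pixels to fit an ellipse", call. = FALSE)
  contour <- if (points) px else contour_pixels(px)
  fit <- NULL
  # exact/subpixel contour points constrain a conic from 5 points on; the
  # quantized contour of a small raster does not -- below ~16 boundary
  # pixels the second-moment ellipse is the more faithful estimate
  min_pts <- if (points) 5L else 16L
  if (nrow(unique(contour)) >= min_pts) {
    co <- fit_conic(contour[, 1], contour[, 2])
    if (!is.null(co)) {
      fit <- conic_to_ellipse(co)
      # a sound fit circumscribes the pixel support by at most ~1 px; tiny
      # quantized contours under-constrain the conic and can yield huge
      # ellipses through the lattice points -- treat those as degenerate
      diag_len <- sqrt(diff(range(px[, 1]))^2 + diff(range(px[, 2]))^2)
      if (!is.null(fit) &&
          (fit$major_diameter / fit$minor_diameter > 1e4 ||
           fit$major_diameter > diag_len + 3)) {
        fit <- NULL
      }
    }
  }
  method <- "conic"
  if (is.null(fit)) {
    if (points) {
      fit <- moment_ellipse_points(px)
    } else {
      fit <- moment_ellipse(px)
    }
    method <- "moments"
  }
  tibble::tibble(
    center_x = fit$center_x, center_y = fit$center_y,
    major_diameter = fit$major_diameter, minor_diameter = fit$minor_diameter,
    orientation_deg = fit$orientation_deg, method = method
  )
}

# Subpixel iso-intensity contour of one detected object: linear
# interpolation of level crossings between adjacent pixels (horizontal and
# vertical), restricted to the object's bounding box plus a margin. The
# background residual is row-structured (streamline suppression acts along
# rows, leaving each affected row a shallow trough), so each patch row is
# first flattened by subtracting the median of its margin columns; the
# contour is then taken at half the object's peak above that baseline,
# tracking the cell's half-maximum boundary without the row-trough bias
# that would otherwise shrink the flow-axis extent.
object_contour <- function(values, px, margin = 3L) {
  h <- nrow(values); w <- ncol(values)
  x0 <- max(1L, min(px[, 1]) - margin); x1 <- min(w, max(px[, 1]) + margin)
  y0 <- max(1L, min(px[, 2]) - margin); y1 <- min(h, max(px[, 2]) + margin)
  patch <- values[y0:y1, x0:x1, drop = FALSE]
  mw <- min(margin, (ncol(patch) - 1L) %/% 2L)
  if (mw >= 1L) {
    side <- cbind(patch[, seq_len(mw), drop = FALSE],
                  patch[, (ncol(patch) - mw + 1L):ncol(patch), drop = FALSE])
    patch <- patch - apply(side, 1L, stats::median)
  }
  peak <- max(patch[cbind(px[, 2] - y0 + 1L, px[, 1] - x0 + 1L)])
  level <- peak / 2
  if (!is.finite(level) || peak <= 0) return(NULL)
  d <- patch - level
  pts <- NULL
  # horizontal crossings
  a <- d[, -ncol(d), drop = FALSE]; b <- d[, -1, drop = FALSE]
  cross <- which(a * b < 0, arr.ind = TRUE)
  if (nrow(cross) > 0) {
    frac <- a[cross] / (a[cross] - b[cross])
    pts <- rbind(pts, cbind(x = x0 - 1 + cross[, 2] + frac,
                            y = y0 - 1 + cross[, 1]))
  }
  # vertical crossings
  a <- d[-nrow(d), , drop = FALSE]; b <- d[-1, , drop = FALSE]
  cross <- which(a * b < 0, arr.ind = TRUE)
  if (nrow(cross) > 0) {
    frac <- a[cross] / (a[cross] - b[cross])
    pts <- rbind(pts, cbind(x = x0 - 1 + cross[, 2],
                            y = y0 - 1 + cross[, 1] + frac))
  }
  if (is.null(pts) || nrow(pts) < 6) return(NULL)
  # keep crossings near the object (discard other structures in the patch)
  lim2 <- (max(diff(range(px[, 1])), diff(range(px[, 2]))) / 2 + margin)^2
  cx <- mean(range(px[, 1])); cy <- mean(range(px[, 2]))
  pts[(pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 <= lim2, , drop = FALSE]
}

# moment ellipse of exact points (no pixel-extent correction); for point
# clouds on an ellipse boundary the RMS radius relation is r^2 = (a^2+b^2)/2,
# handled adequately by the covariance ellipse at fallback quality.
moment_ellipse_points <- function(px) {
  x <- px[, 1]; y <- px[, 2]
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  sxx <- sum((x - cx)^2) / n
  syy <- sum((y - cy)^2) / n
  sxy <- sum((x - cx) * (y - cy)) / n
  eg <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  semi <- sqrt(2 * pmax(eg$values, 1e-12))
  v <- eg$vectors[, 1]
  theta <- ((atan2(v[2], v[1]) * 180 / pi + 90) %% 180) - 90
  list(center_x = cx, center_y = cy,
       major_diameter = 2 * semi[1], minor_diameter = 2 * semi[2],
       orientation_deg = theta)
}

#' Cell acceptance criteria
#'
#' A detected object is classified as a deformed RBC only if (a) it is
#' elongated along the flow axis (`L_X > L_Y`), (b) the elongation is
#' substantial (`L_X - L_Y >= elongation_fraction * L_X`, default 0.2, which
#' implies DI >= 1/9), and (c) both extents fall in the configured size
#' windows, interpreted in `config$criteria_units`. The reported reason names
#' the first criterion that fails, in the order (a), (b), (c).
#'
#' @param l_x,l_y Cell extents in px (vectorized, equal length, positive).
#' @param config A [pipeline_config()].
#' @param um_per_px Calibration used when `criteria_units = "micrometers"`.
#' @return A tibble with columns `accepted` (logical) and `reason`
#'   (`NA` when accepted, otherwise `"not_elongated"`, `"elongation_below_threshold"`,
#'   `"lx_out_of_range"` or `"ly_out_of_range"`).
#' @export
accept_cell <- function(l_x, l_y, config = pipeline_config(), um_per_px = 0.6) {
  if (any(l_x <= 0) || any(l_y <= 0)) {
    stop("cell extents must be positive", call. = FALSE)
  }
  scale <- if (config$criteria_units == "micrometers") um_per_px else 1
  cx <- l_x * scale; cy <- l_y * scale
  reason <- rep(NA_character_, length(l_x))
  fail_a <- !(l_x > l_y)
  fail_b <- !fail_a & (l_x - l_y < config$elongation_fraction * l_x)
  fail_cx <- cx < config$lx_range[1] | cx > config$lx_range[2]
  fail_cy <- cy < config$ly_range[1] | cy > config$ly_range[2]
  reason[fail_a] <- "not_elongated"
  reason[fail_b] <- "elongation_below_threshold"
  pending <- is.na(reason)
  reason[pending & fail_cx] <- "lx_out_of_range"
  pending <- is.na(reason)
  reason[pending & fail_cy] <- "ly_out_of_range"
  tibble::tibble(accepted = is.na(reason), reason = reason)
}

#' Run the sine-window pipeline on one image
#'
#' Composes the whole workflow on a monochrome, rotation-aligned grid:
#' [sine_window_kernel()] smoothing and subtraction
#' ([suppress_background()]), [enhance()], [detect_objects()],
#' [fit_ellipse()] per object, [accept_cell()], and the deformability index
#' of each accepted cell with `L_X` / `L_Y` taken as the fitted major/minor
#' diameters.
#'
#' @param grid An [intensity_grid()] or matrix (monochrome, streamlines
#'   horizontal).
#' @param config A [pipeline_config()].
#' @param stress_dyn_cm2,viscosity_mPas,donor_id,group Metadata forwarded to
#'   [summarize_image()].
#' @return A list with `cells` (a tibble of all detected objects:
#'   `pipeline`, `centroid_x`, `centroid_y`, `l_x`, `l_y`,
#'   `orientation_deg`, `di`, `accepted`, `reject_reason`) and `summary`
#'   (the one-row [summarize_image()] tibble over accepted cells).
#' @export
run_sinewin <- function(grid, config = pipeline_config(),
                        stress_dyn_cm2 = NA_real_, viscosity_mPas = 1.12,
                        donor_id = NA_character_, group = NA_character_) {
  grid <- as_grid(grid)
  kernel <- sine_window_kernel(config$kernel_length)
  residual <- suppress_background(grid, kernel)
  enhanced <- enhance(residual, config$contrast_percentiles,
                      config$gaussian_sigma_sinewin)
  comps <- detect_objects(enhanced, config$diameter_range_px,
                          config$max_foreground_fraction)
  ev <- as.matrix(enhanced)
  cells <- purrr::map(comps, function(p) {
    contour <- object_contour(ev, p)
    fit <- if (!is.null(contour) && nrow(contour) >= 6) {
      f <- fit_ellipse(contour, points = TRUE)
      if (f$method == "conic") f else fit_ellipse(p)
    } else {
      fit_ellipse(p)
    }
    tibble::tibble(
      centroid_x = fit$center_x, centroid_y = fit$center_y,
      l_x = fit$major_diameter, l_y = fit$minor_diameter,
      orientation_deg = fit$orientation_deg
    )
  }) |> dplyr::bind_rows()
  if (nrow(cells) == 0L) {
    cells <- tibble::tibble(
      centroid_x = numeric(), centroid_y = numeric(),
      l_x = numeric(), l_y = numeric(), orientation_deg = numeric()
    )
  }
  acc <- if (nrow(cells) > 0) {
    accept_cell(cells$l_x, cells$l_y, config, um_per_px = grid$um_per_px)
  } else {
    tibble::tibble(accepted = logical(), reason = character())
  }
  cells <- cells |>
    dplyr::mutate(
      di = (.data$l_x - .data$l_y) / (.data$l_x + .data$l_y),
      accepted = acc$accepted,
      reject_reason = acc$reason
    ) |>
    dplyr::mutate(pipeline = "sinewin", .before = 1)
  summary <- summarize_image(
    cells[cells$accepted, , drop = FALSE],
    stress_dyn_cm2 = stress_dyn_cm2, viscosity_mPas = viscosity_mPas,
    donor_id = donor_id, group = group
  )
  list(cells = cells, summary = summary)
}
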
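# The Difference-of-Gaussians workflow: band-pass filtering, horizontal
# top-hat, scaled Otsu binarization, border/area/DI filtering, and
# farthest-point axis measurement.

#' Difference-of-Gaussians band-pass filter
#'
#' Subtracts a wide-Gaussian smoothing of the image from a narrow-Gaussian
#' smoothing (`G(sigma1) * I - G(sigma2) * I`, edge-replicated boundaries).
#' Slowly varying background illumination cancels while compact structures
#' at the cell scale survive as distinct bright regions. The defaults
#' `sigma1 = 0.7`, `sigma2 = 16` px target RBC-sized objects at 0.6 um/px.
#'
#' @param grid An [intensity_grid()] or matrix.
#' @param sigma1,sigma2 Gaussian sigmas in px, `0 < sigma1 < sigma2`.
#' @param double_pass If `TRUE`, applies the band-pass twice (an alternative
#'   reading of "two DoG filters"); off by default.
#' @return An [intensity_grid()] of band-pass residuals (may be negative).
#' @export
dog_filter <- function(grid, sigma1 = 0.7, sigma2 = 16, double_pass = FALSE) {
  grid <- as_grid(grid)
  if (!(sigma1 > 0 && sigma2 > sigma1)) {
    stop("need 0 < sigma1 < sigma2", call. = FALSE)
  }
  v <- gaussian_blur(grid$values, sigma1) - gaussian_blur(grid$values, sigma2)
  if (double_pass) {
    v <- gaussian_blur(v, sigma1) - gaussian_blur(v, sigma2)
  }
  intensity_grid(v, um_per_px = grid$um_per_px)
}

erode_rows <- function(m, half) {
  p <- pad_cols(m, half, half)
  w <- ncol(m)
  out <- p[, (half + 1):(half + w), drop = FALSE]
  for (k in c(seq_len(half), -seq_len(half))) {
    out <- pmin(out, p[, (half + 1 + k):(half + w + k), drop = FALSE])
  }
  out
}

dilate_rows <- function(m, half) {
  p <- pad_cols(m, half, half)
  w <- ncol(m)
  out <- p[, (half + 1):(half + w), drop = FALSE]
  for (k in c(seq_len(half), -seq_len(half))) {
    out <- pmax(out, p[, (half + 1 + k):(half + w + k), drop = FALSE])
  }
  out
}

#' Horizontal white top-hat transform
#'
#' White top-hat with a 1 x `length_px` horizontal line structuring element:
#' the image minus its morphological opening (erosion then dilation, edge
#' replicated). Horizontal structures longer than the element -- flow streaks
#' -- survive the opening and cancel, while compact objects shorter than the
#' element are erased by it and survive in the output. Even element lengths
#' are promoted to the next odd number (with a warning) so the element is
#' symmetric about a centre pixel.
#'
#' @param grid An [intensity_grid()] or matrix.
#' @param length_px Structuring element length, px (>= 1). The default 45
#'   comfortably exceeds any single cell while undercutting streak lengths.
#' @return An [intensity_grid()]; values are in `[0, input]` wherever the
#'   input is non-negative, and always `>= 0`... see Details.
#' @details The top-hat is `input - opening(input)`; since the opening never
#'   exceeds the input, the output is non-negative everywhere, and it is
#'   bounded above by `input - min(input)` (equal to `input` on a zero-floor
#'   image).
#' @export
tophat_horizontal <- function(grid, length_px = 45L) {
  grid <- as_grid(grid)
  if (length_px < 1) stop("element length must be >= 1", call. = FALSE)
  length_px <- as.integer(length_px)
  if (length_px %% 2L == 0L) {
    warning(sprintf("even element length %d promoted to %d", length_px,
                    length_px + 1L), call. = FALSE)
    length_px <- length_px + 1L
  }
  half <- (length_px - 1L) %/% 2L
  v <- grid$values
  opened <- if (half == 0L) v else dilate_rows(erode_rows(v, half), half)
  intensity_grid(v - opened, um_per_px = grid$um_per_px)
}

#' Segment a filtered image into candidate cell components
#'
#' Binarizes at [otsu_threshold()] scaled by `otsu_factor` (foreground at or
#' above the scaled threshold), labels 8-connected components, discards
#' components touching any image border, and retains those whose pixel area
#' lies inside `area_range_px` (inclusive).
#'
#' @param grid An [intensity_grid()] or matrix (typically a top-hat output).
#' @param config A [pipeline_config()] supplying `otsu_factor` and
#'   `area_range_px`.
#' @return A list: `labels` (integer matrix, 0 = background), and
#'   `components`, a tibble with one row per component (`label`, `area`,
#'   `touches_border`, `kept`) carrying each component's pixel set in the
#'   list-column `pixels`.
#' @export
segment <- function(grid, config = pipeline_config()) {
  grid <- as_grid(grid)
  v <- grid$values
  thr <- otsu_threshold(grid) * config$otsu_factor
  fg <- v >= thr
  # foreground-fraction plausibility guard: see pipeline_config()
  if (mean(fg) > config$max_foreground_fraction) {
    fg[] <- FALSE
  }
  labels <- label_components(fg)
  comps <- component_pixels(labels)
  h <- nrow(v); w <- ncol(v)
  info <- purrr::map(seq_along(comps), function(i) {
    p <- comps[[i]]
    tibble::tibble(
      label = i,
      area = nrow(p),
      touches_border = any(p[, "x"] == 1L | p[, "x"] == w |
                           p[, "y"] == 1L | p[, "y"] == h),
      pixels = list(p)
    )
  }) |> dplyr::bind_rows()
  if (nrow(info) == 0L) {
    info <- tibble::tibble(label = integer(), area = integer(),
                           touches_border = logical(), pixels = list())
  }
  info$kept <- !info$touches_border &
    info$area >= config$area_range_px[1] & info$area <= config$area_range_px[2]
  list(labels = labels, components = info)
}

#' Farthest-point cell axes
#'
#' Measures a segmented cell the way the scaled-Otsu workflow defines its
#' axes: the pair of pixel centres at maximal Euclidean distance (searched
#' exhaustively over the component's convex hull; exact ties broken by
#' lexicographic pixel order) defines the primary axis, and `L_X` is that
#' distance plus one. All pixel centres are then projected onto the axis and
#' its perpendicular; `L_Y` is the perpendicular projection span plus one.
#' The "+1" converts centre-to-centre distances to pixel extents, so a
#' single-file row of k pixels has length k, consistent with area filters
#' counting k pixels.
#'
#' @param px 2-column matrix of pixel coordinates (`x`, `y`), >= 2 rows.
#' @return A one-row tibble: `l_x`, `l_y`, `orientation_deg` (primary-axis
#'   angle vs. the X axis, in (-90, 90\]), `centroid_x`, `centroid_y`.
#' @export
principal_axes <- function(px) {
  px <- as.matrix(px)
  if (nrow(px) < 2L) stop("need at least 2 pixels", call. = FALSE)
  pts <- unique(px)
  hull <- if (nrow(pts) >= 3L) {
    idx <- grDevices::chull(pts[, 1], pts[, 2])
    pts[idx, , drop = FALSE]
  } else {
    pts
  }
  # exhaustive farthest pair over hull points, exact squared distances
  n <- nrow(hull)
  best <- NULL; best_d2 <- -1
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- hull[i, ]; q <- hull[j, ]
    # orient the pair lexicographically for deterministic tie-breaking
    if (q[1] < p[1] || (q[1] == p[1] && q[2] < p[2])) { tmp <- p; p <- q; q <- tmp }
    d2 <- sum((p - q)^2)
    if (d2 > best_d2 ||
        (d2 == best_d2 && lex_less(c(p, q), c(best$p, best$q)))) {
      best_d2 <- d2
      best <- list(p = p, q = q)
    }
  }
  if (n == 1L) best <- list(p = hull[1, ], q = hull[1, ])
  d <- sqrt(max(best_d2, 0))
  u <- if (d > 0) (best$q - best$p) / d else c(1, 0)
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  u <- unname(u)
  n_proj <- (px[, 1] - best$p[1]) * (-u[2]) + (px[, 2] - best$p[2]) * u[1]
  theta <- atan2(u[2], u[1]) * 180 / pi
  theta <- ((theta + 90) %% 180) - 90
  tibble::tibble(
    l_x = d + 1,
    l_y = diff(range(n_proj)) + 1,
    orientation_deg = theta,
    centroid_x = mean(px[, 1]),
    centroid_y = mean(px[, 2])
  )
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Run the DoG pipeline on one image
#'
#' Composes [dog_filter()], [tophat_horizontal()], [segment()] and
#' [principal_axes()] on a monochrome, rotation-aligned grid, computes each
#' cell's deformability index, and rejects cells whose DI exceeds
#' `config$di_cap` as segmentation artifacts (strongly elongated residues of
#' streaks or merged cells).
#'
#' @inheritParams run_sinewin
#' @return A list with `cells` (tibble over all segmented components:
#'   `pipeline`, `centroid_x`, `centroid_y`, `l_x`, `l_y`,
#'   `orientation_deg`, `area`, `di`, `accepted`, `reject_reason`) and
#'   `summary` (the one-row [summarize_image()] tibble over accepted cells).
#'   Reject reasons are recorded with priority `area_out_of_range`,
#'   `touches_border`, `di_above_cap`.
#' @export
run_dog <- function(grid, config = pipeline_config(),
                    stress_dyn_cm2 = NA_real_, viscosity_mPas = 1.12,
                    donor_id = NA_character_, group = NA_character_) {
  grid <- as_grid(grid)
  filtered <- dog_filter(grid, config$dog_sigma1, config$dog_sigma2)
  topped <- tophat_horizontal(filtered, config$tophat_length_px)
  seg <- segment(topped, config)
  info <- seg$components
  cells <- purrr::map(seq_len(nrow(info)), function(i) {
    p <- info$pixels[[i]]
    ax <- if (nrow(p) >= 2L) {
      principal_axes(p)
    } else {
      tibble::tibble(l_x = 1, l_y = 1, orientation_deg = 0,
                     centroid_x = p[1, 1], centroid_y = p[1, 2])
    }
    ax$area <- info$area[i]
    ax$touches_border <- info$touches_border[i]
    ax
  }) |> dplyr::bind_rows()
  if (nrow(cells) == 0L) {
    cells <- tibble::tibble(
      l_x = numeric(), l_y = numeric(), orientation_deg = numeric(),
      centroid_x = numeric(), centroid_y = numeric(),
      area = integer(), touches_border = logical()
    )
  }
  cells <- cells |>
    dplyr::mutate(
      di = (.data$l_x - .data$l_y) / (.data$l_x + .data$l_y),
      reject_reason = dplyr::case_when(
        .data$area < config$area_range_px[1] |
          .data$area > config$area_range_px[2] ~ "area_out_of_range",
        .data$touches_border ~ "touches_border",
        .data$di > config$di_cap ~ "di_above_cap",
        TRUE ~ NA_character_
      ),
      accepted = is.na(.data$reject_reason)
    ) |>
    dplyr::select("centroid_x", "centroid_y", "l_x", "l_y",
                  "orientation_deg", "area", "di", "accepted",
                  "reject_reason") |>
    dplyr::mutate(pipeline = "dog", .before = 1)
  summary <- summarize_image(
    cells[cells$accepted, , drop = FALSE],
    stress_dyn_cm2 = stress_dyn_cm2, viscosity_mPas = viscosity_mPas,
    donor_id = donor_id, group = group
  )
  list(cells = cells, summary = summary)
}
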
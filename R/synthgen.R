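# Synthetic microfluidic images with known cell geometry, and synthetic donor
# cohorts of DI values. The generator is the package's test bed: real raw
# image sets from this kind of assay are rarely deposited, so pipelines are
# validated by recovering known ground truth.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Background specification for synthetic streamline images
#'
#' Describes the background of a microfluidic brightfield frame: horizontal
#' streamline bands with sharp transverse (Y) boundaries whose intensity
#' varies smoothly along the flow (X) axis, plus additive sensor noise.
#'
#' @param n_bands Number of horizontal streamline bands (>= 0; 0 gives a flat
#'   background).
#' @param band_edge_sharpness Logistic transition width of band edges, px.
#' @param x_smoothness_scale Correlation length (px) of the smooth intensity
#'   modulation along X. Must be large relative to cells (>= 50) so the
#'   background is genuinely smooth at the cell scale; the empirical
#'   autocorrelation of a band's X-profile decays to 1/e at this lag.
#' @param base_level Mean background intensity (8-bit scale).
#' @param band_amplitude Intensity scale of band-to-band level differences
#'   and of the along-X modulation.
#' @param noise_sd SD of i.i.d. additive Gaussian pixel noise.
#' @return A `background_spec` list.
#' @export
background_spec <- function(n_bands = 6L,
                            band_edge_sharpness = 1.5,
                            x_smoothness_scale = 200,
                            base_level = 120,
                            band_amplitude = 25,
                            noise_sd = 2) {
  stopifnot(n_bands >= 0, band_edge_sharpness > 0, x_smoothness_scale >= 50,
            base_level >= 0, band_amplitude >= 0, noise_sd >= 0)
  structure(
    list(n_bands = as.integer(n_bands),
         band_edge_sharpness = band_edge_sharpness,
         x_smoothness_scale = x_smoothness_scale,
         base_level = base_level,
         band_amplitude = band_amplitude,
         noise_sd = noise_sd),
    class = "background_spec"
  )
}

# Smooth zero-mean profile of length n with 1/e autocorrelation length
# `scale`: Gaussian-smoothed white noise (kernel sd = scale/2 gives
# ACF(tau) = exp(-tau^2 / scale^2)), rescaled to unit SD.
smooth_profile <- function(n, scale) {
  s <- scale / 2
  pad <- ceiling(3.5 * s)
  z <- stats::rnorm(n + 2 * pad)
  k <- gaussian_kernel_1d(s)
  sm <- convolve_rows(matrix(z, 1L), k)[1L, ]
  p <- sm[(pad + 1):(pad + n)]
  p <- p - mean(p)
  sdev <- stats::sd(p)
  if (sdev > 0) p / sdev else p * 0
}

#' Render a synthetic streamline background
#'
#' Builds the background described by a [background_spec()]: band levels are
#' drawn per band, rows blend adjacent bands through logistic edges of the
#' given sharpness, each band's level is modulated along X by a smooth random
#' profile, and Gaussian noise is added last. Bit-for-bit reproducible from
#' `(spec, seed)`.
#'
#' @param spec A [background_spec()].
#' @param height,width Image dimensions, px (>= 32).
#' @param seed Integer RNG seed.
#' @param um_per_px Spatial calibration attached to the output.
#' @return An [intensity_grid()].
#' @export
render_background <- function(spec, height = 400L, width = 400L, seed = 1L,
                              um_per_px = 0.6) {
  if (height < 32 || width < 32) {
    stop("image dimensions must be at least 32 px", call. = FALSE)
  }
  with_seed(seed, {
    if (spec$n_bands == 0L) {
      v <- matrix(spec$base_level, height, width)
    } else {
      nb <- spec$n_bands
      levels <- spec$base_level + spec$band_amplitude * stats::runif(nb, -1, 1)
      profiles <- t(vapply(
        seq_len(nb),
        function(b) 0.4 * spec$band_amplitude *
          smooth_profile(width, spec$x_smoothness_scale),
        numeric(width)
      ))
      edges <- seq(0.5, height + 0.5, length.out = nb + 1)
      y <- seq_len(height)
      # soft membership of each row in each band (logistic edges)
      memb <- vapply(seq_len(nb), function(b) {
        lo <- if (b == 1L) rep(1, height) else
          stats::plogis((y - edges[b]) / spec$band_edge_sharpness)
        hi <- if (b == nb) rep(0, height) else
          stats::plogis((y - edges[b + 1]) / spec$band_edge_sharpness)
        lo - hi
      }, numeric(height))
      memb <- memb / rowSums(memb)
      v <- memb %*% (levels + profiles)
    }
    if (spec$noise_sd > 0) {
      v <- v + matrix(stats::rnorm(height * width, sd = spec$noise_sd),
                      height, width)
    }
    intensity_grid(v, um_per_px = um_per_px)
  })
}

# Anti-aliased additive rendering of one ellipse via 4x4 subpixel sampling.
add_ellipse <- function(v, cx, cy, a, b, theta_deg, amplitude, ss = 4L) {
  h <- nrow(v); w <- ncol(v)
  r <- max(a, b) + 1.5
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  if (length(xs) == 0L || length(ys) == 0L) return(v)
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  th <- theta_deg * pi / 180
  cov <- matrix(0, length(ys), length(xs))
  for (oy in off) for (ox in off) {
    dx <- outer(rep(1, length(ys)), xs + ox - cx)
    dy <- outer(ys + oy - cy, rep(1, length(xs)))
    u <- (cos(th) * dx + sin(th) * dy) / a
    q <- (-sin(th) * dx + cos(th) * dy) / b
    cov <- cov + (u * u + q * q <= 1)
  }
  v[ys, xs] <- v[ys, xs] + amplitude * cov / (ss * ss)
  v
}

#' Render cells onto a background grid
#'
#' Adds each cell as an anti-aliased filled ellipse (subpixel coverage
#' weighting at the rim) of the given intensity amplitude. Cells are rendered
#' bright on the background by default, matching what both pipelines detect
#' after filtering; pass negative amplitudes to simulate dark cells.
#'
#' @param grid An [intensity_grid()] or matrix.
#' @param cells Data frame with columns `center_x`, `center_y`, `a`
#'   (semi-major, px), `b` (semi-minor, px), `theta_deg`, `amplitude`.
#'   Zero rows are allowed.
#' @return A list: `grid` (the new [intensity_grid()]) and `truth`, a tibble
#'   with one row per rendered cell carrying its true geometry, the true
#'   `di = (a - b) / (a + b)` (scale-free, so semi-axes give the same value
#'   as full extents), and an `overlaps` flag marking cells whose centre
#'   distance to some other cell is below the sum of their semi-majors.
#' @export
render_cells <- function(grid, cells) {
  grid <- as_grid(grid)
  cells <- tibble::as_tibble(cells)
  if (nrow(cells) == 0L) {
    return(list(grid = grid, truth = empty_truth()))
  }
  if (any(cells$a <= 0) || any(cells$b <= 0)) {
    stop("ellipse semi-axes must be positive", call. = FALSE)
  }
  if (any(cells$b > cells$a)) {
    stop("semi-major `a` must be >= semi-minor `b`", call. = FALSE)
  }
  v <- grid$values
  for (i in seq_len(nrow(cells))) {
    v <- add_ellipse(v, cells$center_x[i], cells$center_y[i],
                     cells$a[i], cells$b[i], cells$theta_deg[i],
                     cells$amplitude[i])
  }
  n <- nrow(cells)
  overlaps <- rep(FALSE, n)
  if (n > 1L) {
    d <- as.matrix(stats::dist(cbind(cells$center_x, cells$center_y)))
    lim <- outer(cells$a, cells$a, `+`)
    diag(d) <- Inf
    overlaps <- apply(d < lim, 1L, any)
  }
  truth <- tibble::tibble(
    cell = seq_len(n),
    center_x = cells$center_x, center_y = cells$center_y,
    a = cells$a, b = cells$b, theta_deg = cells$theta_deg,
    amplitude = cells$amplitude,
    di = (cells$a - cells$b) / (cells$a + cells$b),
    overlaps = overlaps
  )
  list(grid = intensity_grid(v, um_per_px = grid$um_per_px), truth = truth)
}

empty_truth <- function() {
  tibble::tibble(
    cell = integer(), center_x = numeric(), center_y = numeric(),
    a = numeric(), b = numeric(), theta_deg = numeric(),
    amplitude = numeric(), di = numeric(), overlaps = logical()
  )
}

#' Generate a complete synthetic microfluidic image with ground truth
#'
#' Samples cell geometries uniformly within the given ranges, places them by
#' rejection sampling (by default non-overlapping: pairwise centre distances
#' must exceed the sum of semi-majors, and each cell lies fully inside the
#' frame), renders the streamline background, then the cells. Deterministic
#' given `seed`.
#'
#' The default geometry emulates deformed RBCs at 0.6 um/px: semi-major
#' 4.5-6.5 px with true DI 0.05-0.30, giving rendered areas of roughly
#' 50-130 px.
#'
#' @param n_cells Number of cells (>= 0).
#' @param background A [background_spec()].
#' @param cell_ranges List of length-2 ranges: `a` (semi-major, px), and
#'   either `di` (semi-minor derived as `b = a(1-DI)/(1+DI)`) or `b`
#'   (sampled directly, truncated at `a`); plus `theta_deg` and `amplitude`.
#' @param height,width Image dimensions, px.
#' @param seed Integer RNG seed.
#' @param allow_overlap If `TRUE`, skip the separation constraint (used to
#'   test rejection of overlapping cells downstream).
#' @param max_attempts Placement attempts per cell before giving up with an
#'   error naming the achieved count.
#' @param um_per_px Spatial calibration.
#' @return A list: `grid` (an [intensity_grid()]) and `truth` (see
#'   [render_cells()]).
#' @export
generate_image <- function(n_cells = 20L,
                           background = background_spec(),
                           cell_ranges = list(a = c(4.5, 6.5),
                                              di = c(0.05, 0.30),
                                              theta_deg = c(-15, 15),
                                              amplitude = c(60, 90)),
                           height = 400L, width = 400L, seed = 1L,
                           allow_overlap = FALSE,
                           max_attempts = 1000L,
                           um_per_px = 0.6) {
  stopifnot(n_cells >= 0)
  bg <- render_background(background, height, width, seed = seed,
                          um_per_px = um_per_px)
  if (n_cells == 0L) {
    return(list(grid = bg, truth = empty_truth()))
  }
  runif_range <- function(r) stats::runif(1, r[1], r[2])
  cells <- with_seed(seed + 1L, {
    placed <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        a <- runif_range(cell_ranges$a)
        b <- if (!is.null(cell_ranges$di)) {
          di <- runif_range(cell_ranges$di)
          a * (1 - di) / (1 + di)
        } else {
          min(runif_range(cell_ranges$b), a)
        }
        margin <- a + 2
        cand <- list(
          center_x = stats::runif(1, 1 + margin, width - margin),
          center_y = stats::runif(1, 1 + margin, height - margin),
          a = a, b = b,
          theta_deg = runif_range(cell_ranges$theta_deg),
          amplitude = runif_range(cell_ranges$amplitude)
        )
        if (allow_overlap || i == 1L) { ok <- TRUE; break }
        prev <- dplyr::bind_rows(placed[seq_len(i - 1L)])
        sep <- sqrt((prev$center_x - cand$center_x)^2 +
                    (prev$center_y - cand$center_y)^2)
        if (all(sep > prev$a + cand$a)) { ok <- TRUE; break }
      }
      if (!ok) {
        stop(sprintf(
          "could not place cell %d of %d after %d attempts (placed %d)",
          i, n_cells, max_attempts, i - 1L
        ), call. = FALSE)
      }
      placed[[i]] <- cand
    }
    dplyr::bind_rows(placed)
  })
  render_cells(bg, cells)
}

#' Write a ground-truth table next to an image
#'
#' @param truth Ground-truth tibble from [generate_image()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
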
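# Low-level raster helpers shared by both pipelines. All convolutions use
# edge replication so constant backgrounds stay exactly constant through
# every linear stage.

pad_cols <- function(m, left, right) {
  w <- ncol(m)
  m[, c(rep(1L, left), seq_len(w), rep(w, right)), drop = FALSE]
}

# 1-D convolution of each row with `weights`, edge-replicated, same width.
# Odd lengths use plain centred convolution. Even lengths have no integer
# centre: the mean of the left- and right-aligned passes restores exact
# symmetry, so constants map to constants and linear ramps to linear ramps.
convolve_rows <- function(m, weights) {
  n <- length(weights)
  w <- ncol(m)
  if (n > w) stop("kernel longer than image rows", call. = FALSE)
  run <- function(left, right) {
    p <- pad_cols(m, left, right)
    out <- matrix(0, nrow(m), w)
    for (k in seq_len(n)) {
      out <- out + weights[k] * p[, k:(k + w - 1), drop = FALSE]
    }
    out
  }
  lo <- (n - 1L) %/% 2L
  hi <- n - 1L - lo
  if (lo == hi) run(lo, hi) else (run(lo, hi) + run(hi, lo)) / 2
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable isotropic Gaussian blur with edge replication.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  t(convolve_rows(t(convolve_rows(m, k)), k))
}

#' Otsu threshold of a real-valued image
#'
#' Classic Otsu thresholding generalized to real-valued images: a 256-bin
#' histogram is built over the observed value range and the inter-bin
#' boundary maximizing the between-class variance is returned (ties broken
#' toward the smallest threshold). Filtered images are real-valued, so the
#' textbook 8-bit formulation does not apply directly; binning over the
#' observed range is its natural generalization.
#'
#' @param grid An [intensity_grid()] or numeric matrix with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins.
#' @return The threshold value, on the scale of the input. Foreground is
#'   conventionally `values >= threshold`.
#' @export
otsu_threshold <- function(grid, n_bins = 256L) {
  v <- as.numeric(as.matrix(as_grid(grid)))
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("constant image: Otsu threshold is undefined", call. = FALSE)
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / length(v)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(p)[-n_bins]
  m0 <- cumsum(p * centers)[-n_bins]
  mt <- sum(p * centers)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  t_idx <- which.max(between)  # first maximum = smallest threshold
  lo + t_idx * (hi - lo) / n_bins
}

# 8-connected component labelling by iterative minimum-label propagation.
# Returns an integer matrix: 0 for background, 1..K for components numbered
# in raster order of first occurrence.
label_components <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(Inf, h, w)
  lab[fg] <- which(fg)
  if (!any(fg)) return(matrix(0L, h, w))
  shift <- function(m, dy, dx) {
    out <- matrix(Inf, h, w)
    ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
    oky <- ys >= 1 & ys <= h; okx <- xs >= 1 & xs <= w
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  repeat {
    new <- lab
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      new <- pmin(new, shift(lab, dy, dx))
    }
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!fg] <- 0
  out <- matrix(0L, h, w)
  ids <- lab[fg]
  out[fg] <- as.integer(factor(ids, levels = unique(ids[order(which(fg))])))
  # renumber in raster order of each component's first pixel
  first <- tapply(which(fg), out[fg], min)
  remap <- integer(length(first))
  remap[order(first)] <- seq_along(first)
  out[fg] <- remap[out[fg]]
  out
}

# Pixel coordinates (x = column, y = row) of each labelled component.
component_pixels <- function(labels) {
  k <- max(labels)
  if (k == 0L) return(list())
  idx <- which(labels > 0L)
  h <- nrow(labels)
  ys <- (idx - 1L) %% h + 1L
  xs <- (idx - 1L) %/% h + 1L
  split.data.frame(cbind(x = xs, y = ys), labels[idx])
}
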
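# Shared helpers for building synthetic fixtures in code.

# Match measured cells to ground-truth cells by nearest centroid and return
# the truth rows in measurement order.
match_truth <- function(cells, truth) {
  idx <- vapply(seq_len(nrow(cells)), function(i) {
    which.min((truth$center_x - cells$centroid_x[i])^2 +
              (truth$center_y - cells$centroid_y[i])^2)
  }, integer(1))
  truth[idx, , drop = FALSE]
}

# Filled ellipse raster: centres (x, y) inside the ellipse with semi-axes
# (a, b) rotated by theta_deg, translated to (cx, cy).
raster_ellipse <- function(a, b, theta_deg = 0, cx = 50, cy = 50) {
  r <- ceiling(a) + 1
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r))
  th <- theta_deg * pi / 180
  u <- (cos(th) * g[, 1] + sin(th) * g[, 2]) / a
  q <- (-sin(th) * g[, 1] + cos(th) * g[, 2]) / b
  px <- g[u^2 + q^2 <= 1, , drop = FALSE]
  px[, 1] <- px[, 1] + cx
  px[, 2] <- px[, 2] + cy
  px
}

# Horizontal smooth-stripe image (value depends on row only).
stripe_grid <- function(n = 240, period = 60, amplitude = 60, base = 120) {
  intensity_grid(matrix(rep(amplitude * sin(seq_len(n) * 2 * pi / period) + base,
                            times = n), n, n))
}

# Brute-force Otsu: naive double loop over all candidate bin splits,
# independent of the package's cumulative-sum implementation.
otsu_brute <- function(v, n_bins = 256L) {
  lo <- min(v); hi <- max(v)
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  best <- -Inf; best_t <- NA
  for (t in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:t] * centers[1:t]) / n0
    m1 <- sum(counts[(t + 1):n_bins] * centers[(t + 1):n_bins]) / n1
    s <- (n0 / sum(counts)) * (n1 / sum(counts)) * (m0 - m1)^2
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  lo + best_t * (hi - lo) / n_bins
}
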
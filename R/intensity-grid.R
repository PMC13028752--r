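#' Pixel intensity grid
#'
#' The raster unit every pipeline stage consumes and produces: a matrix of
#' finite real-valued intensities (rows are the Y/transverse axis, columns the
#' X/flow axis) together with the spatial calibration of the imaging system.
#' 8-bit inputs are carried on the \[0, 255\] scale; intermediate stages may
#' produce values outside that range (e.g. signed background residuals) and
#' quantization back to 8 bits happens only on export.
#'
#' @param values Numeric matrix of pixel intensities; all values finite.
#' @param um_per_px Spatial calibration, micrometres per pixel (> 0). The
#'   default 0.6 matches a 10x objective on a 1600x1600 sCMOS sensor typical
#'   of microfluidic RBC imaging.
#'
#' @return An `intensity_grid` object.
#' @export
#' @examples
#' g <- intensity_grid(matrix(0, 32, 64))
#' dim(g)
intensity_grid <- function(values, um_per_px = 0.6) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all pixel intensities must be finite", call. = FALSE)
  }
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || !is.finite(um_per_px) ||
      um_per_px <= 0) {
    stop("`um_per_px` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = unname(values), um_per_px = as.numeric(um_per_px)),
    class = "intensity_grid"
  )
}

#' @export
dim.intensity_grid <- function(x) dim(x$values)

#' @export
as.matrix.intensity_grid <- function(x, ...) x$values

#' @export
print.intensity_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<intensity_grid> %d x %d px, %.3g um/px, range [%.4g, %.4g]\n",
    nrow(v), ncol(v), x$um_per_px, min(v), max(v)
  ))
  invisible(x)
}

is_intensity_grid <- function(x) inherits(x, "intensity_grid")

# Coerce matrices transparently so helpers can take either form.
as_grid <- function(x, um_per_px = 0.6) {
  if (is_intensity_grid(x)) x else intensity_grid(x, um_per_px = um_per_px)
}

#' Convert a 1- or 3-channel raster to a monochrome grid
#'
#' Brightfield acquisitions are often stored as 24-bit RGB even though all
#' three channels carry the same 8-bit signal. For 3-channel input the first
#' channel is taken (not an average): when the channels are truly equal the
#' choice is immaterial, and when they are not, averaging would silently blend
#' them. Any pixel where channels disagree by more than one intensity unit
#' raises a warning instead.
#'
#' @param image An `intensity_grid`, a numeric matrix (single channel), or a
#'   3-dimensional numeric array with 1 or 3 planes along the third dimension
#'   (as returned by [read_image()] for RGB files).
#' @param um_per_px Calibration used when `image` carries none.
#'
#' @return An [intensity_grid()] with a single channel.
#' @export
to_monochrome <- function(image, um_per_px = 0.6) {
  if (is_intensity_grid(image)) {
    return(image)
  }
  if (is.matrix(image)) {
    return(intensity_grid(image, um_per_px = um_per_px))
  }
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop("`image` must be a matrix, intensity_grid, or 3-d array", call. = FALSE)
  }
  nchan <- dim(image)[3L]
  if (!nchan %in% c(1L, 3L)) {
    stop(sprintf("expected 1 or 3 channels, got %d", nchan), call. = FALSE)
  }
  if (nchan == 3L) {
    spread <- pmax(
      abs(image[, , 1L] - image[, , 2L]),
      abs(image[, , 1L] - image[, , 3L]),
      abs(image[, , 2L] - image[, , 3L])
    )
    if (any(spread > 1)) {
      warning(sprintf(
        "RGB channels differ by more than 1 intensity unit at %d pixel(s); using channel 1",
        sum(spread > 1)
      ), call. = FALSE)
    }
  }
  intensity_grid(image[, , 1L, drop = TRUE], um_per_px = um_per_px)
}

#' Read a TIFF or PNG image
#'
#' Reads 8-bit grayscale or RGB images, returning intensities on the
#' \[0, 255\] scale (the underlying readers use \[0, 1\]). Grayscale files
#' yield a matrix; RGB files yield a height x width x 3 array suitable for
#' [to_monochrome()].
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return A numeric matrix or 3-d array of intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image extension '%s' (use tif/tiff/png)", ext),
         call. = FALSE)
  )
  if (is.array(raw) && length(dim(raw)) == 3L && dim(raw)[3L] == 4L) {
    raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  }
  raw * 255
}

#' Write an intensity grid as an 8-bit grayscale image
#'
#' Values are clipped to \[0, 255\] and rounded half up before quantization.
#'
#' @param grid An [intensity_grid()] or numeric matrix.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, path) {
  v <- as.matrix(as_grid(grid))
  v <- floor(pmin(pmax(v, 0), 255) + 0.5) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    png = png::writePNG(v, path),
    stop(sprintf("unsupported image extension '%s' (use tif/tiff/png)", ext),
         call. = FALSE)
  )
  invisible(path)
}

#' Read or write an image metadata sidecar
#'
#' Per-image acquisition metadata travels in a small key-value sidecar file
#' (one `key: value` per line) next to the image: donor id, donor group,
#' applied wall shear stress, suspension viscosity, and spatial calibration.
#'
#' @param path Sidecar file path.
#' @return For `read_sidecar()`, a one-row tibble with columns `donor_id`,
#'   `group`, `stress_dyn_cm2`, `viscosity_mPas`, `calibration_um_per_px`.
#' @export
read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  out <- stats::setNames(as.list(vals), keys)
  for (k in c("stress_dyn_cm2", "viscosity_mPas", "calibration_um_per_px")) {
    if (!is.null(out[[k]])) out[[k]] <- as.numeric(out[[k]])
  }
  tibble::as_tibble(out)
}

#' @param meta A one-row data frame or named list of metadata fields.
#' @rdname read_sidecar
#' @export
write_sidecar <- function(meta, path) {
  meta <- as.list(meta)
  writeLines(sprintf("%s: %s", names(meta), vapply(meta, format, character(1))),
             path)
  invisible(path)
}
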
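#' Image stack container
#'
#' An `ImageStack` holds a temporal stack of photon-calibrated camera frames
#' together with the acquisition metadata needed by the localization and
#' MUSICAL engines. Frames are stored as an `H x W x K` array (rows `y`,
#' columns `x`, third dimension time).
#'
#' Coordinate convention: pixel indices are 0-based and continuous positions
#' use the centre of pixel `(0, 0)` as the origin, with `x` increasing along
#' columns and `y` along rows. All intensities are assumed to be in photon
#' units (any camera gain/offset already applied); use `gain`/`offset` in
#' [read_stack()] for a linear correction.
#'
#' @param data numeric `H x W x K` array (or `H x W` matrix for a single
#'   frame) of finite, non-negative photon counts.
#' @param pixel_size pixel size in the sample plane, nm.
#' @param frame_rate acquisition rate, frames per second.
#' @param wavelength emission wavelength, nm.
#' @param na numerical aperture of the objective.
#' @return An object of class `ImageStack` with fields `data`, `pixel_size`,
#'   `frame_rate`, `wavelength`, `na`.
#' @export
image_stack <- function(data, pixel_size, frame_rate, wavelength, na) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be an H x W x K array")
  if (dim(data)[3] < 1L) stop("no frames")
  if (!all(is.finite(data))) stop("stack contains non-finite values")
  if (any(data < 0)) stop("stack contains negative values")
  stopifnot(pixel_size > 0, frame_rate > 0, wavelength > 0, na > 0)
  structure(list(data = data, pixel_size = pixel_size,
                 frame_rate = frame_rate, wavelength = wavelength, na = na),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d frames of %d x %d px (%g nm/px, %g fps, lambda %g nm, NA %g)\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_rate, x$wavelength, x$na))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an [image_stack()].
#' @return integer frame count `K`.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' Gaussian PSF width for a stack
#'
#' Standard deviation of the Gaussian approximation to the diffraction
#' limited PSF, `0.21 * lambda / NA`.
#'
#' @param stack an [image_stack()].
#' @param units `"px"` or `"nm"`.
#' @return PSF sigma in the requested units.
#' @export
psf_sigma <- function(stack, units = c("px", "nm")) {
  units <- match.arg(units)
  s_nm <- 0.21 * stack$wavelength / stack$na
  if (units == "nm") s_nm else s_nm / stack$pixel_size
}

#' Read a multi-page TIFF stack
#'
#' Reads a multi-page TIFF (one 2-D frame per page) into an [image_stack()].
#' Stacks written by [write_stack()] carry a JSON sidecar (`<path>.json`)
#' with the intensity scale and acquisition metadata; for foreign TIFFs the
#' metadata must be supplied.
#'
#' @param path TIFF file path.
#' @param metadata named list overriding/supplying `pixel_size`,
#'   `frame_rate`, `wavelength`, `na` (and optionally `scale`).
#' @param gain,offset linear photon calibration applied as
#'   `(value - offset) / gain` per pixel.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, metadata = list(), gain = 1, offset = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("no frames in ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse grayscale-with-channels
    p
  })
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent frame shapes in ", path)
  meta <- list(scale = 1, pixel_size = NA_real_, frame_rate = NA_real_,
               wavelength = NA_real_, na = NA_real_)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar, simplifyVector = TRUE))
  meta <- utils::modifyList(meta, metadata)
  for (f in c("pixel_size", "frame_rate", "wavelength", "na"))
    if (is.na(meta[[f]])) stop("missing acquisition metadata field: ", f)
  data <- array(0, dim = c(shp, length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]] * meta$scale
  data <- (data - offset) / gain
  if (any(data < 0))
    stop("negative values after gain/offset correction; check calibration")
  image_stack(data, meta$pixel_size, meta$frame_rate, meta$wavelength, meta$na)
}

#' Write a stack as multi-page float TIFF
#'
#' Values are stored as 32-bit float scaled into `[0, 1]`; the scale factor
#' and the acquisition metadata are recorded in a JSON sidecar so that
#' [read_stack()] restores the original photon units.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  sc <- max(stack$data, 1)
  K <- n_frames(stack)
  pages <- lapply(seq_len(K), function(k) stack$data[, , k] / sc)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write ", path)
  jsonlite::write_json(
    list(scale = sc, pixel_size = stack$pixel_size, frame_rate = stack$frame_rate,
         wavelength = stack$wavelength, na = stack$na),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract a soft-windowed pixels-by-frames matrix
#'
#' Cuts a `window_size x window_size` window centred on an acquisition pixel
#' and builds the `N x K` matrix analysed by MUSICAL: column `k` is the
#' vectorized window of frame `k`, multiplied elementwise by a Gaussian soft
#' window `w(dx, dy) = exp(-(dx^2 + dy^2) / (2 * soft_rms^2))`. Pixels
#' falling outside the image contribute exactly 0 (zero padding), so windows
#' at the image border are valid.
#'
#' @param stack an [image_stack()].
#' @param center integer `c(x, y)` pixel coordinates (0-based).
#' @param window_size odd window side length in pixels.
#' @param soft_rms root-mean-square width of the Gaussian soft window, px.
#' @return A `WindowMatrix`: list with `values` (`N x K`), `center`,
#'   `offsets` (`N x 2` matrix of `(dx, dy)` pixel offsets) and
#'   `soft_weights` (`N`-vector).
#' @export
extract_window <- function(stack, center, window_size = 7, soft_rms = 3) {
  stopifnot(window_size %% 2 == 1, soft_rms > 0, length(center) == 2)
  d <- dim(stack$data)
  cx <- as.integer(center[1]); cy <- as.integer(center[2])
  if (cx < 0 || cx >= d[2] || cy < 0 || cy >= d[1])
    stop("window center outside image bounds")
  h <- (window_size - 1L) %/% 2L
  off <- as.matrix(expand.grid(dy = -h:h, dx = -h:h))  # column-major: dy fastest
  w <- exp(-(off[, "dx"]^2 + off[, "dy"]^2) / (2 * soft_rms^2))
  rows <- cy + off[, "dy"]; cols <- cx + off[, "dx"]
  inside <- rows >= 0 & rows < d[1] & cols >= 0 & cols < d[2]
  K <- d[3]; N <- window_size^2
  vals <- matrix(0, N, K)
  idx_in <- which(inside)
  # linear indices into each frame (column-major H x W)
  lin <- rows[idx_in] + 1L + d[1] * cols[idx_in]
  HW <- d[1] * d[2]
  for (k in seq_len(K))
    vals[idx_in, k] <- stack$data[lin + (k - 1L) * HW]
  vals <- vals * w
  structure(list(values = vals, center = c(cx, cy),
                 offsets = off[, c("dx", "dy"), drop = FALSE],
                 soft_weights = w, window_size = window_size,
                 soft_rms = soft_rms),
            class = "WindowMatrix")
}
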
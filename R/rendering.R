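#' Super-resolution grid geometry
#'
#' Defines the sub-pixel raster on which reconstructions are accumulated.
#' The grid covers the acquisition field `[-0.5, W-0.5] x [-0.5, H-0.5]`
#' (continuous pixel coordinates) with `factor` SR pixels per acquisition
#' pixel, or an arbitrary SR pixel size in nm.
#'
#' @param img_shape `c(H, W)` acquisition field, pixels.
#' @param pixel_size acquisition pixel size, nm.
#' @param factor integer subdivision factor (default 8, i.e. 12.5 nm for
#'   100 nm pixels); ignored when `sr_pixel_size` is given.
#' @param sr_pixel_size SR pixel size in nm (e.g. 13), optional.
#' @return an `SRGrid` list: `dim` (`c(Hs, Ws)`), `sr_px` (SR pixel in
#'   acquisition-pixel units), `sr_pixel_size` (nm), `origin` (nm of the
#'   top-left grid corner), `img_shape`, `pixel_size`.
#' @export
sr_grid <- function(img_shape, pixel_size, factor = 8, sr_pixel_size = NULL) {
  H <- img_shape[1]; W <- img_shape[2]
  if (is.null(sr_pixel_size)) {
    sr_px <- 1 / factor
    dim <- c(H * factor, W * factor)
  } else {
    sr_px <- sr_pixel_size / pixel_size
    dim <- c(ceiling(H / sr_px), ceiling(W / sr_px))
  }
  structure(list(dim = as.integer(dim), sr_px = sr_px,
                 sr_pixel_size = sr_px * pixel_size,
                 origin = c(-0.5, -0.5) * pixel_size,
                 img_shape = as.integer(img_shape), pixel_size = pixel_size),
            class = "SRGrid")
}

# SR bin (0-based c(ix, iy)) of a continuous pixel position, or NA outside.
sr_bin <- function(grid, x_px, y_px) {
  ix <- floor((x_px + 0.5) / grid$sr_px)
  iy <- floor((y_px + 0.5) / grid$sr_px)
  if (is.na(ix) || is.na(iy) ||
      ix < 0 || ix >= grid$dim[2] || iy < 0 || iy >= grid$dim[1])
    return(c(NA_integer_, NA_integer_))
  c(as.integer(ix), as.integer(iy))
}

#' Super-resolution image
#'
#' @param values `Hs x Ws` matrix of non-negative values.
#' @param grid the [sr_grid()] the values live on.
#' @param mode character tag describing the deposit rule.
#' @return an `SRImage`.
#' @export
sr_image <- function(values, grid, mode = "count") {
  stopifnot(identical(dim(values), as.integer(grid$dim)) ||
              identical(dim(values), grid$dim))
  structure(list(values = values, grid = grid, mode = mode),
            class = "SRImage")
}

#' @export
print.SRImage <- function(x, ...) {
  cat(sprintf("SRImage [%s]: %d x %d @ %.3g nm/px, sum %.6g\n", x$mode,
              x$grid$dim[1], x$grid$dim[2], x$grid$sr_pixel_size,
              sum(x$values)))
  invisible(x)
}

#' Render a localization-microscopy image
#'
#' Accumulates localizations on the SR grid under a chosen deposit rule
#' `b_k`. `"count"` is the conventional LM image (`b_k = 1` per
#' localization). `"photons"` is the debiased LM image: each localization
#' deposits its estimated photon count `psi`, so bright, high-SNR events
#' carry proportionally more weight. `"frame_mean"` and `"fg_mean"` weight
#' every localization of frame `k` by the frame's mean intensity
#' (respectively over all pixels or over the detected foreground), supplied
#' as a [stack_weights()] object (`1/w_k` is the deposit). `"precision"`
#' deposits the inverse variance `1/precision^2`, normalized to unit mean
#' over the retained localizations.
#'
#' @param table a `LocalizationTable` from [localize_stack()].
#' @param grid an [sr_grid()].
#' @param mode deposit rule.
#' @param weights `FrameWeights` (required for `frame_mean` / `fg_mean`;
#'   mode must match).
#' @param valid_only drop rows flagged invalid (default `TRUE`).
#' @return an [sr_image()]; `attr(, "n_dropped")` counts localizations
#'   falling outside the grid.
#' @export
render_lm <- function(table, grid,
                      mode = c("count", "photons", "frame_mean", "fg_mean",
                               "precision"),
                      weights = NULL, valid_only = TRUE) {
  mode <- match.arg(mode)
  img <- matrix(0, grid$dim[1], grid$dim[2])
  tab <- as.data.frame(table)
  if (valid_only && nrow(tab)) tab <- tab[tab$valid, , drop = FALSE]
  if (mode %in% c("frame_mean", "fg_mean")) {
    need <- if (mode == "frame_mean") "frame_mean" else "foreground_mean"
    if (is.null(weights) || !identical(weights$mode, need))
      stop("mode '", mode, "' needs FrameWeights computed with mode '",
           need, "'")
  }
  dropped <- 0L
  if (nrow(tab)) {
    dep <- switch(mode,
      count = rep(1, nrow(tab)),
      photons = tab$photons,
      frame_mean = 1 / weights$w[tab$frame + 1L],
      fg_mean = 1 / weights$w[tab$frame + 1L],
      precision = {
        iv <- 1 / tab$precision_nm^2
        iv / mean(iv)
      })
    for (r in seq_len(nrow(tab))) {
      ij <- sr_bin(grid, tab$x_px[r], tab$y_px[r])
      if (any(is.na(ij))) { dropped <- dropped + 1L; next }
      img[ij[2] + 1L, ij[1] + 1L] <- img[ij[2] + 1L, ij[1] + 1L] + dep[r]
    }
  }
  out <- sr_image(img, grid, mode = mode)
  attr(out, "n_dropped") <- dropped
  out
}

#' Heuristic localization filters
#'
#' The strict retain-or-reject filters commonly applied to localization
#' tables: axial ratio of the fitted PSF at most `axial_ratio_max`
#' (e.g. 1.3), mean fitted width within `width_range` nm (e.g. 200-400 nm),
#' and fit amplitude (height) strictly greater than `height_min`. Filters
#' set to `NULL` are inactive; with all `NULL` and `valid_only = FALSE` the
#' table is returned unchanged.
#'
#' @param table a `LocalizationTable`.
#' @param axial_ratio_max maximum `max(sx, sy)/min(sx, sy)`, or `NULL`.
#' @param width_range `c(lo, hi)` nm bounds (inclusive) on the mean fitted
#'   Gaussian width, or `NULL`.
#' @param height_min minimum fit amplitude (exclusive), counts, or `NULL`.
#' @param valid_only also drop rows flagged invalid.
#' @return filtered `LocalizationTable`.
#' @export
filter_localizations <- function(table, axial_ratio_max = NULL,
                                 width_range = NULL, height_min = NULL,
                                 valid_only = FALSE) {
  tab <- as.data.frame(table)
  keep <- rep(TRUE, nrow(tab))
  if (valid_only) keep <- keep & tab$valid
  if (!is.null(axial_ratio_max))
    keep <- keep & tab$axial_ratio <= axial_ratio_max
  if (!is.null(width_range)) {
    w_nm <- (tab$sigma_x_px + tab$sigma_y_px) / 2 * attr(table, "pixel_size")
    keep <- keep & w_nm >= width_range[1] & w_nm <= width_range[2]
  }
  if (!is.null(height_min)) keep <- keep & tab$amplitude > height_min
  out <- tab[keep, , drop = FALSE]
  attr(out, "pixel_size") <- attr(table, "pixel_size")
  class(out) <- class(table)
  out
}

#' Intensity-range binary segmentation
#'
#' Thresholds a reconstruction into the pixels whose value lies in
#' `[lo, hi]`. On a count-mode image, `lo = hi = 1` selects pixels with
#' exactly one localization; on a photon-mode image, ranges of total photon
#' counts isolate structures by expected per-emitter photon budget.
#'
#' @param image an [sr_image()] (or plain matrix).
#' @param lo,hi inclusive bounds, `lo <= hi`.
#' @return logical matrix.
#' @export
segment_intensity_range <- function(image, lo, hi) {
  stopifnot(lo <= hi)
  v <- if (inherits(image, "SRImage")) image$values else image
  v >= lo & v <= hi
}

#' Intensity histogram of a reconstruction
#'
#' @param image an [sr_image()] or matrix.
#' @param bins number of equal-width bins (default 2000).
#' @param drop_zero drop the lowest (background) bin from the report.
#' @return data frame with `mid`, `lo`, `hi`, `count`.
#' @export
intensity_histogram <- function(image, bins = 2000, drop_zero = FALSE) {
  v <- if (inherits(image, "SRImage")) image$values else image
  br <- seq(min(v), max(v), length.out = bins + 1)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  out <- data.frame(mid = h$mids, lo = utils::head(br, -1),
                    hi = br[-1], count = h$counts)
  if (drop_zero) out <- out[-1, ]
  out
}

#' Write an SR image as float TIFF with JSON sidecar
#'
#' @param image an [sr_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_sr_image <- function(image, path) {
  sc <- max(image$values, 1)
  tiff::writeTIFF(image$values / sc, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(
    list(scale = sc, mode = image$mode,
         sr_pixel_size = image$grid$sr_pixel_size,
         origin = image$grid$origin, dim = image$grid$dim,
         img_shape = image$grid$img_shape,
         pixel_size = image$grid$pixel_size),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
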
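#' Localization configuration
#'
#' @param roi_size square fitting window side, px (odd, >= 7).
#' @param init_radius initial Gaussian width for the fit, px.
#' @param max_iter maximum least-squares iterations.
#' @param rel_tol relative parameter-change tolerance terminating the fit.
#' @param min_separation non-maximum-suppression radius for candidates, px.
#' @param threshold_c candidate threshold in MADs above the frame median;
#'   `c = 2` is the permissive ("thorough search") preset, 4 the default.
#' @return a `LocalizeConfig` list.
#' @export
localize_config <- function(roi_size = 7, init_radius = 1.5, max_iter = 10,
                            rel_tol = 1e-3, min_separation = 3,
                            threshold_c = 4) {
  stopifnot(roi_size >= 7, roi_size %% 2 == 1, init_radius > 0,
            max_iter >= 1, rel_tol > 0, min_separation >= 1)
  structure(list(roi_size = as.integer(roi_size), init_radius = init_radius,
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 min_separation = min_separation, threshold_c = threshold_c),
            class = "LocalizeConfig")
}

#' Detect emitter candidates in a frame
#'
#' Local maxima above an automatic robust threshold
#' (`median + c * MAD`), non-maximum suppressed so that no two candidates
#' are closer than `min_separation` pixels (brighter peak wins).
#'
#' @param frame `H x W` matrix of counts.
#' @param min_separation suppression radius, px.
#' @param threshold_c threshold constant `c` (MAD units).
#' @return integer matrix with columns `x`, `y` (0-based pixel coords),
#'   possibly zero rows.
#' @export
detect_candidates <- function(frame, min_separation = 3, threshold_c = 4) {
  H <- nrow(frame); W <- ncol(frame)
  thr <- stats::median(frame) + threshold_c * stats::mad(frame)
  if (stats::mad(frame) == 0) thr <- stats::median(frame) + threshold_c * sqrt(max(stats::median(frame), 1))
  # strict local maxima over the 8-neighbourhood (ties broken by raster order)
  cand <- NULL
  for (r in 2:(H - 1)) for (cc in 2:(W - 1)) {
    v <- frame[r, cc]
    if (v <= thr) next
    nb <- frame[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    nb[2, 2] <- -Inf
    if (v > max(nb)) cand <- rbind(cand, c(cc - 1L, r - 1L, v))
  }
  if (is.null(cand))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  cand <- cand[order(-cand[, 3]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j][d2 < min_separation^2] <- FALSE
    }
  }
  out <- cand[keep, 1:2, drop = FALSE]
  storage.mode(out) <- "integer"
  colnames(out) <- c("x", "y")
  out
}

#' Fit a single emitter in an ROI
#'
#' Unweighted least-squares fit of an elliptical Gaussian
#' `A * exp(-((x - x0)^2 / (2 sx^2) + (y - y0)^2 / (2 sy^2))) + b`
#' to a small image patch, with both widths initialized at `init_radius`.
#' Iteration stops after `max_iter` steps or when the relative parameter
#' change falls below `rel_tol`. Fits that do not improve on a flat model,
#' have non-positive amplitude, or widths exceeding the ROI are flagged
#' invalid but returned, so that filter studies can inspect them.
#'
#' @param roi square matrix, at least 7 x 7.
#' @param init_radius initial width, px.
#' @param max_iter,rel_tol iteration controls.
#' @return one-row data frame with `x`, `y` (0-based px within the ROI),
#'   `amplitude`, `sigma_x_px`, `sigma_y_px`, `background`, `residual`
#'   (RMS residual / ROI peak), `axial_ratio`, `valid`.
#' @export
fit_emitter <- function(roi, init_radius = 1.5, max_iter = 10, rel_tol = 1e-3) {
  stopifnot(nrow(roi) >= 7, ncol(roi) >= 7)
  H <- nrow(roi); W <- ncol(roi)
  gx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  gy <- matrix(0:(H - 1), H, W)
  b0 <- min(roi); a0 <- max(roi) - b0
  pk <- which(roi == max(roi), arr.ind = TRUE)[1, ]
  p0 <- c(A = a0, x0 = unname(pk["col"]) - 1, y0 = unname(pk["row"]) - 1,
          sx = init_radius, sy = init_radius, b = b0)
  model <- function(p)
    p[1] * exp(-((gx - p[2])^2 / (2 * p[4]^2) + (gy - p[3])^2 / (2 * p[5]^2))) + p[6]
  invalid <- function() data.frame(
    x = NA_real_, y = NA_real_, amplitude = NA_real_, sigma_x_px = NA_real_,
    sigma_y_px = NA_real_, background = NA_real_, residual = NA_real_,
    axial_ratio = NA_real_, valid = FALSE)
  if (a0 <= 0) return(invalid())
  # hitting max_iter is an intended stopping rule, not a warning condition
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = p0, fn = function(p) as.vector(roi - model(p)),
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ptol = rel_tol, ftol = rel_tol))), silent = TRUE)
  if (inherits(fit, "try-error")) return(invalid())
  p <- fit$par
  p[4] <- abs(p[4]); p[5] <- abs(p[5])
  rms <- sqrt(mean(fit$fvec^2))
  ok <- is.finite(p[1]) && p[1] > 0 && p[4] > 0.2 && p[5] > 0.2 &&
    p[4] < max(H, W) && p[5] < max(H, W) &&
    p[2] > -1 && p[2] < W && p[3] > -1 && p[3] < H
  data.frame(x = p[2], y = p[3], amplitude = p[1], sigma_x_px = p[4],
             sigma_y_px = p[5], background = p[6],
             residual = rms / max(roi),
             axial_ratio = max(p[4], p[5]) / min(p[4], p[5]),
             valid = isTRUE(ok))
}

#' Estimated photon count of a localization
#'
#' Volume under the fitted Gaussian excluding background:
#' `psi = 2 * pi * A * sigma_x * sigma_y` (photon units given
#' photon-calibrated input, widths in pixels).
#'
#' @param fit one-row fit result from [fit_emitter()] (or any list with
#'   `amplitude`, `sigma_x_px`, `sigma_y_px`, `valid`).
#' @return estimated photons.
#' @export
estimate_photons <- function(fit) {
  if (!isTRUE(fit$valid)) stop("cannot estimate photons for an invalid fit")
  2 * pi * fit$amplitude * fit$sigma_x_px * fit$sigma_y_px
}

#' Thompson-style localization precision
#'
#' Predicted standard deviation of the fitted position,
#' `Delta^2 = (s^2 + a^2/12) / psi + 8 * pi * s^4 * b^2 / (a^2 * psi^2)`,
#' with `s` the mean fitted PSF width in nm, `a` the pixel size in nm,
#' `b` the fitted background (counts/pixel) and `psi` the photon count.
#'
#' @param fit one-row fit result from [fit_emitter()].
#' @param pixel_size pixel size `a`, nm.
#' @param photons optional photon count (default [estimate_photons()]).
#' @return precision in nm.
#' @export
estimate_precision <- function(fit, pixel_size, photons = NULL) {
  psi <- if (is.null(photons)) estimate_photons(fit) else photons
  if (psi <= 0) stop("photon count must be positive")
  s <- (fit$sigma_x_px + fit$sigma_y_px) / 2 * pixel_size
  a <- pixel_size
  b <- max(fit$background, 0)
  sqrt((s^2 + a^2 / 12) / psi + 8 * pi * s^4 * b^2 / (a^2 * psi^2))
}

#' Localize emitters over a whole stack
#'
#' Frame-by-frame candidate detection and Gaussian fitting; each frame is
#' treated independently of all others. Candidates too close to the image
#' border for a full ROI are skipped; duplicate fits converging within
#' 0.5 px of each other in one frame are merged, keeping the lower-residual
#' fit (first in raster order on ties). The result is deterministic for a
#' given stack and configuration.
#'
#' @param stack an [image_stack()].
#' @param cfg a [localize_config()].
#' @return A `LocalizationTable`: data frame with columns `frame` (0-based),
#'   `x_px`, `y_px`, `x_nm`, `y_nm`, `amplitude`, `sigma_x_px`,
#'   `sigma_y_px`, `background`, `photons`, `precision_nm`, `residual`,
#'   `axial_ratio`, `valid`; pixel size in `attr(, "pixel_size")`.
#' @export
localize_stack <- function(stack, cfg = localize_config()) {
  K <- n_frames(stack)
  H <- dim(stack$data)[1]; W <- dim(stack$data)[2]
  h <- (cfg$roi_size - 1L) %/% 2L
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    fr <- stack$data[, , k]
    cand <- detect_candidates(fr, cfg$min_separation, cfg$threshold_c)
    if (!nrow(cand)) next
    fits <- NULL
    for (i in seq_len(nrow(cand))) {
      cx <- cand[i, "x"]; cy <- cand[i, "y"]
      if (cx < h || cx >= W - h || cy < h || cy >= H - h) next
      roi <- fr[(cy - h + 1L):(cy + h + 1L), (cx - h + 1L):(cx + h + 1L)]
      f <- fit_emitter(roi, cfg$init_radius, cfg$max_iter, cfg$rel_tol)
      f$x <- f$x + cx - h
      f$y <- f$y + cy - h
      fits <- rbind(fits, f)
    }
    if (is.null(fits) || !nrow(fits)) next
    # merge duplicates: same-frame fits within 0.5 px keep the lower residual
    if (nrow(fits) > 1) {
      ord <- order(fits$residual, seq_len(nrow(fits)))
      keep <- rep(TRUE, nrow(fits))
      for (a in ord) {
        if (!keep[a]) next
        d2 <- (fits$x - fits$x[a])^2 + (fits$y - fits$y[a])^2
        dup <- which(keep & d2 < 0.25 & seq_len(nrow(fits)) != a &
                       !is.na(d2))
        dup <- dup[fits$residual[dup] >= fits$residual[a]]
        keep[dup] <- FALSE
      }
      fits <- fits[keep, , drop = FALSE]
    }
    fits$frame <- k - 1L
    rows[[k]] <- fits
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- fit_emitter(matrix(1, 7, 7))[0, ]
  if (!"frame" %in% names(tab)) tab$frame <- integer(0)
  tab$photons <- ifelse(tab$valid,
                        2 * pi * tab$amplitude * tab$sigma_x_px * tab$sigma_y_px,
                        NA_real_)
  tab$precision_nm <- rep(NA_real_, nrow(tab))
  ok <- which(tab$valid & tab$photons > 0)
  for (i in ok)
    tab$precision_nm[i] <- estimate_precision(tab[i, ], stack$pixel_size,
                                              tab$photons[i])
  tab$x_px <- tab$x; tab$y_px <- tab$y
  tab$x_nm <- tab$x * stack$pixel_size
  tab$y_nm <- tab$y * stack$pixel_size
  tab <- tab[, c("frame", "x_px", "y_px", "x_nm", "y_nm", "amplitude",
                 "sigma_x_px", "sigma_y_px", "background", "photons",
                 "precision_nm", "residual", "axial_ratio", "valid")]
  rownames(tab) <- NULL
  attr(tab, "pixel_size") <- stack$pixel_size
  class(tab) <- c("LocalizationTable", "data.frame")
  tab
}

#' Write / read localization tables as CSV
#'
#' @param table a `LocalizationTable`.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_locs <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locs
#' @param pixel_size pixel size (nm) to attach on read.
#' @export
read_locs <- function(path, pixel_size) {
  tab <- utils::read.csv(path)
  attr(tab, "pixel_size") <- pixel_size
  class(tab) <- c("LocalizationTable", "data.frame")
  tab
}
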
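#' Detect the foreground of a frame
#'
#' Splits a frame into foreground and background by modelling the
#' distribution of log-intensities `log(1 + I)` as bimodal and thresholding
#' it with the two-class between-variance (Otsu) criterion on a 256-bin
#' histogram. Pixels whose log-intensity exceeds the threshold are
#' foreground. A constant frame has no usable split and yields an empty
#' foreground flagged as degenerate.
#'
#' @param frame `H x W` matrix of non-negative counts.
#' @return A `ForegroundMask`: list with `mask` (logical `H x W`),
#'   `n_foreground`, `threshold` (in intensity units) and `degenerate`.
#' @export
detect_foreground <- function(frame) {
  stopifnot(is.matrix(frame), all(frame >= 0))
  lg <- log1p(frame)
  rg <- range(lg)
  if (rg[1] == rg[2]) {
    return(structure(list(mask = matrix(FALSE, nrow(frame), ncol(frame)),
                          n_foreground = 0L, threshold = NA_real_,
                          degenerate = TRUE),
                     class = "ForegroundMask"))
  }
  u <- (lg - rg[1]) / (rg[2] - rg[1])
  thr_u <- EBImage::otsu(u, range = c(0, 1), levels = 256)
  thr_lg <- thr_u * (rg[2] - rg[1]) + rg[1]
  mask <- lg > thr_lg
  structure(list(mask = mask, n_foreground = sum(mask),
                 threshold = expm1(thr_lg), degenerate = FALSE),
            class = "ForegroundMask")
}

#' Per-frame debias weight
#'
#' Computes the frame weight `w_k` used to equalize frames before MUSICAL
#' (and for frame-weighted LM rendering). The primary rule is the inverse
#' mean foreground intensity,
#' `w_k = (sum_{r in F} I(r) / N_F)^-1`;
#' the two variants use the inverse mean, respectively the inverse standard
#' deviation, of the whole frame.
#'
#' @param frame `H x W` matrix of counts.
#' @param mode `"foreground_mean"`, `"frame_mean"` or `"frame_std"`.
#' @param mask optional [detect_foreground()] result to reuse.
#' @return positive scalar weight; for `foreground_mean`,
#'   `attr(, "n_foreground")` carries the foreground pixel count.
#' @export
frame_weight <- function(frame,
                         mode = c("foreground_mean", "frame_mean", "frame_std"),
                         mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "frame_mean") {
    m <- mean(frame)
    if (m <= 0) stop("frame mean is zero; weight undefined")
    return(1 / m)
  }
  if (mode == "frame_std") {
    s <- stats::sd(frame)
    if (!is.finite(s) || s <= 0)
      stop("frame standard deviation is zero; weight undefined")
    return(1 / s)
  }
  if (is.null(mask)) mask <- detect_foreground(frame)
  if (mask$degenerate || mask$n_foreground == 0L) {
    warning("empty foreground; falling back to frame_mean weight")
    w <- frame_weight(frame, "frame_mean")
    attr(w, "n_foreground") <- 0L
    return(w)
  }
  m <- mean(frame[mask$mask])
  if (m <= 0) stop("foreground mean is zero; weight undefined")
  w <- 1 / m
  attr(w, "n_foreground") <- mask$n_foreground
  w
}

#' Debias weights for a whole stack
#'
#' Applies [frame_weight()] to every frame and returns the weight series
#' together with its reciprocal `1/w_k`, the diagnostic plotted to judge
#' whether debiasing matters: a flat `1/w_k` trend means the foreground
#' intensity is stable and reweighting is immaterial, a decaying trend
#' (e.g. under photobleaching) means low-SNR frames would otherwise be
#' under-represented by MUSICAL.
#'
#' @param stack an [image_stack()].
#' @param mode weight rule, see [frame_weight()].
#' @return A `FrameWeights` list: `w`, `one_over_w`, `mode`,
#'   `n_foreground` (per frame; `NA` outside foreground mode).
#' @export
stack_weights <- function(stack,
                          mode = c("foreground_mean", "frame_mean", "frame_std")) {
  mode <- match.arg(mode)
  K <- n_frames(stack)
  w <- numeric(K)
  nf <- rep(NA_integer_, K)
  for (k in seq_len(K)) {
    wk <- frame_weight(stack$data[, , k], mode)
    w[k] <- as.numeric(wk)
    if (!is.null(attr(wk, "n_foreground"))) nf[k] <- attr(wk, "n_foreground")
  }
  structure(list(w = w, one_over_w = 1 / w, mode = mode, n_foreground = nf),
            class = "FrameWeights")
}

#' @export
print.FrameWeights <- function(x, ...) {
  cat(sprintf("FrameWeights [%s]: K = %d, 1/w range [%.4g, %.4g]\n",
              x$mode, length(x$w), min(x$one_over_w), max(x$one_over_w)))
  invisible(x)
}

#' Write frame weights as CSV
#'
#' @param weights a [stack_weights()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  utils::write.csv(
    data.frame(frame_index = seq_along(weights$w) - 1L, w_k = weights$w,
               one_over_wk = weights$one_over_w,
               n_foreground = weights$n_foreground),
    path, row.names = FALSE)
  invisible(path)
}
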
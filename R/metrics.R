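# 1-D Gaussian filter taps, 11 points, sigma 1.5, normalized to unit sum.
.ssim_kernel <- function(size = 11, sigma = 1.5) {
  h <- (size - 1) / 2
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  g / sum(g)
}

# Valid-mode separable filtering: rows then columns.
.filter_valid <- function(x, g) {
  n <- length(g)
  H <- nrow(x); W <- ncol(x)
  if (H < n || W < n) stop("image smaller than the SSIM window")
  # band (Toeplitz) matrices implementing 'valid' correlation
  Br <- matrix(0, H - n + 1, H)
  for (i in seq_len(H - n + 1)) Br[i, i:(i + n - 1)] <- g
  Bc <- matrix(0, W - n + 1, W)
  for (i in seq_len(W - n + 1)) Bc[i, i:(i + n - 1)] <- g
  Br %*% x %*% t(Bc)
}

#' Structural similarity index between two reconstructions
#'
#' Mean local SSIM computed with an 11 x 11 Gaussian weighting window
#' (sigma 1.5) and the reference constants `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`. Because reconstructions from different algorithms are
#' in incommensurate units (counts, photons, pseudospectrum), both images
#' are min-max normalized to `[0, 1]` (so `L = 1`) before comparison;
#' disable with `normalize = FALSE` for images already on a common scale.
#' Border pixels without a full window are excluded (valid-mode filtering).
#'
#' @param image_a,image_b [sr_image()]s on identical grids, or plain
#'   matrices of identical size.
#' @param normalize min-max normalize each image independently.
#' @param L dynamic range when `normalize = FALSE`.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(image_a, image_b, normalize = TRUE, L = 1) {
  a <- if (inherits(image_a, "SRImage")) image_a$values else image_a
  b <- if (inherits(image_b, "SRImage")) image_b$values else image_b
  if (inherits(image_a, "SRImage") && inherits(image_b, "SRImage") &&
      !isTRUE(all.equal(image_a$grid[c("dim", "sr_px")],
                        image_b$grid[c("dim", "sr_px")])))
    stop("images live on different SR grids")
  if (!identical(dim(a), dim(b))) stop("image dimensions differ")
  if (normalize) {
    mm <- function(x) if (max(x) > min(x)) (x - min(x)) / (max(x) - min(x)) else x * 0
    a <- mm(a); b <- mm(b); L <- 1
  }
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  g <- .ssim_kernel()
  mu_a <- .filter_valid(a, g); mu_b <- .filter_valid(b, g)
  va <- .filter_valid(a * a, g) - mu_a^2
  vb <- .filter_valid(b * b, g) - mu_b^2
  cab <- .filter_valid(a * b, g) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Pairwise SSIM comparison report
#'
#' Scores every unordered pair of a named set of reconstructions, mirroring
#' the SSIM tables used to compare original and debiased LM/MUSICAL images.
#'
#' @param images named list of [sr_image()]s (or matrices) on a common grid,
#'   at least 2, names unique.
#' @param normalize passed to [ssim()].
#' @return A `ComparisonReport` data frame with `name_a`, `name_b`, `ssim`;
#'   `attr(, "L")` records the dynamic range used.
#' @export
pairwise_report <- function(images, normalize = TRUE) {
  nm <- names(images)
  if (length(images) < 2) stop("need at least 2 images")
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop("images must have unique non-empty names")
  pairs <- utils::combn(length(images), 2)
  out <- data.frame(
    name_a = nm[pairs[1, ]], name_b = nm[pairs[2, ]],
    ssim = apply(pairs, 2, function(ij)
      ssim(images[[ij[1]]], images[[ij[2]]], normalize = normalize)))
  attr(out, "L") <- if (normalize) 1 else NA_real_
  class(out) <- c("ComparisonReport", "data.frame")
  out
}
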
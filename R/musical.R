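#' MUSICAL configuration
#'
#' @param window_size soft window side, px (odd; default 7).
#' @param soft_rms Gaussian soft-window RMS width, px (default 3).
#' @param alpha pseudospectrum exponent (default 4).
#' @param sigma0_rule how the signal/null threshold is chosen per window:
#'   `"fraction"` uses `sigma0 = sigma0_value * sigma1` (default fraction
#'   0.01), `"fixed"` uses `sigma0_value` directly, `"knee"` uses the
#'   simplified knee criterion of [knee_sigma0()].
#' @param sigma0_value fraction of `sigma1` or fixed threshold value.
#' @param sigma0_scope `"global"` (default) takes the `sigma1` of the
#'   fraction rule as the largest singular value of the full image-stack
#'   matrix, giving one threshold for every window, so that windows holding
#'   only background fall entirely into the null subspace; `"window"`
#'   applies the fraction rule with each window's own `sigma1`.
#' @param subpixel integer subdivision of the acquisition pixel for test
#'   points (default 8).
#' @param eps floor on the null-projection norm `d_N` (values at the floor
#'   are a deterministic cap; the default keeps capped and near-capped
#'   pseudospectrum values well above floating-point rounding noise).
#' @return a `MusicalConfig` list.
#' @export
musical_config <- function(window_size = 7, soft_rms = 3, alpha = 4,
                           sigma0_rule = c("fraction", "fixed", "knee"),
                           sigma0_value = 0.01,
                           sigma0_scope = c("global", "window"),
                           subpixel = 8, eps = 1e-8) {
  stopifnot(window_size %% 2 == 1, soft_rms > 0, alpha > 0,
            sigma0_value > 0, subpixel >= 1)
  structure(list(window_size = as.integer(window_size), soft_rms = soft_rms,
                 alpha = alpha, sigma0_rule = match.arg(sigma0_rule),
                 sigma0_value = sigma0_value,
                 sigma0_scope = match.arg(sigma0_scope),
                 subpixel = as.integer(subpixel), eps = eps),
            class = "MusicalConfig")
}

#' Simplified knee threshold on a singular-value spectrum
#'
#' Picks the threshold at the knee of the log singular-value curve, located
#' as the point of maximum perpendicular distance from the chord joining the
#' first and last (positive) values. This is a simplified stand-in for the
#' full knee criterion used with MUSICAL sub-stack analyses; the result
#' carries the chosen index as an attribute and is labelled accordingly.
#'
#' @param singular_values non-negative values sorted in descending order
#'   (at least 3 positive).
#' @return the singular value at the knee; `attr(, "index")` gives its
#'   position, `attr(, "criterion")` is `"simplified_knee"`.
#' @export
knee_sigma0 <- function(singular_values) {
  d <- singular_values[singular_values > 0]
  if (length(d) < 3) stop("need at least 3 positive singular values")
  y <- log(d)
  x <- seq_along(y)
  n <- length(y)
  # perpendicular distance from the chord (x1,y1)-(xn,yn)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  dist <- abs(dy * (x - x[1]) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  i <- which.max(dist)
  out <- d[i]
  attr(out, "index") <- i
  attr(out, "criterion") <- "simplified_knee"
  out
}

.resolve_sigma0 <- function(d, cfg, sigma1_global = NULL) {
  switch(cfg$sigma0_rule,
         fraction = {
           s1 <- if (cfg$sigma0_scope == "global" && !is.null(sigma1_global))
             sigma1_global else d[1]
           cfg$sigma0_value * s1
         },
         fixed = cfg$sigma0_value,
         knee = as.numeric(knee_sigma0(d)))
}

#' Signal/null subspace split of a window matrix
#'
#' Singular value decomposition of the `N x K` soft-windowed matrix; the
#' eigenimages (left singular vectors) with singular value above the
#' threshold `sigma0` span the signal subspace, the remainder the null
#' subspace. `nu = sqrt(sum_{sigma_i <= sigma0} sigma_i^2)` measures the
#' intensity mass relegated to noise.
#'
#' @param window a [extract_window()] result.
#' @param cfg a [musical_config()].
#' @param sigma1_global optional global largest singular value (for
#'   `sigma0_scope = "global"`).
#' @return A `SubspaceSplit`: `eigenimages` (`N x min(N, K)` orthonormal
#'   columns), `singular_values` (descending), `signal_idx`, `sigma0`,
#'   `nu`, `degenerate`, plus the window geometry (`offsets`,
#'   `soft_weights`, `center`).
#' @export
subspace_split <- function(window, cfg = musical_config(),
                           sigma1_global = NULL) {
  A <- window$values
  if (all(A == 0)) {
    return(structure(list(eigenimages = NULL, singular_values = numeric(0),
                          signal_idx = integer(0), sigma0 = NA_real_,
                          nu = NA_real_, degenerate = TRUE,
                          offsets = window$offsets,
                          soft_weights = window$soft_weights,
                          center = window$center),
                     class = "SubspaceSplit"))
  }
  sv <- svd(A)
  sigma0 <- .resolve_sigma0(sv$d, cfg, sigma1_global)
  signal_idx <- which(sv$d > sigma0)
  nu <- sqrt(sum(sv$d[sv$d <= sigma0]^2))
  structure(list(eigenimages = sv$u, singular_values = sv$d,
                 signal_idx = signal_idx, sigma0 = sigma0, nu = nu,
                 degenerate = FALSE, offsets = window$offsets,
                 soft_weights = window$soft_weights, center = window$center),
            class = "SubspaceSplit")
}

# Unit-normalized, soft-weighted PSF vector(s) sampled at the window's pixel
# centres for test points at offsets (tx, ty) from the window centre.
# Returns an N x T matrix with unit columns.
.psf_vectors <- function(offsets, soft_weights, tx, ty, psf_sigma_px) {
  G <- exp(-((outer(offsets[, 1], tx, "-"))^2 +
               (outer(offsets[, 2], ty, "-"))^2) / (2 * psf_sigma_px^2))
  G <- G * soft_weights
  nrm <- sqrt(colSums(G^2))
  nrm[nrm == 0] <- 1
  sweep(G, 2, nrm, "/")
}

#' MUSIC pseudospectrum at a test point
#'
#' Projects the soft-weighted, unit-normalized PSF vector at a sub-pixel
#' test point onto the signal subspace (`d_S`) and its orthogonal
#' complement (`d_N`, completed to the full `N`-dimensional pixel space when
#' `K < N`), and returns `(d_S / d_N)^alpha`. High values mean the test
#' point is consistent with a genuine emitter position.
#'
#' @param test_point `c(tx, ty)` offset from the window centre, px.
#' @param split a [subspace_split()].
#' @param cfg a [musical_config()].
#' @param psf_sigma_px PSF sigma in pixels.
#' @return non-negative scalar (0 for a degenerate window).
#' @export
pseudospectrum_at <- function(test_point, split, cfg, psf_sigma_px) {
  if (split$degenerate) return(0)
  g <- .psf_vectors(split$offsets, split$soft_weights,
                    test_point[1], test_point[2], psf_sigma_px)
  .pseudospectrum(g, split, cfg)[1]
}

# Pseudospectrum for unit PSF vectors given as columns of G. d_N is the norm
# of the residual of G after projection on the signal subspace (the
# orthogonal complement of the signal space, complete even when K < N); when
# the signal subspace spans the full pixel space, d_N is exactly the eps
# floor, so the value is a deterministic cap rather than rounding noise.
.pseudospectrum <- function(G, split, cfg) {
  if (!length(split$signal_idx)) return(rep(0, ncol(G)))
  Us <- split$eigenimages[, split$signal_idx, drop = FALSE]
  P <- crossprod(Us, G)
  ds <- sqrt(pmin(colSums(P^2), 1))
  if (length(split$signal_idx) >= nrow(G)) {
    dn <- rep(cfg$eps, ncol(G))
  } else {
    R <- G - Us %*% P
    dn <- pmax(sqrt(colSums(R^2)), cfg$eps)
  }
  (ds / dn)^cfg$alpha
}

# Largest singular value of the full stack matrix (pixels x frames) by
# power iteration on the K x K Gram matrix.
.global_sigma1 <- function(stack, iters = 200, tol = 1e-12) {
  d <- dim(stack$data)
  A <- matrix(stack$data, d[1] * d[2], d[3])
  v <- rep(1 / sqrt(d[3]), d[3])
  s_old <- 0
  for (i in seq_len(iters)) {
    v <- crossprod(A, A %*% v)        # (A^T A) v
    nv <- sqrt(sum(v^2))              # converges to sigma1^2
    if (nv == 0) return(0)
    v <- v / nv
    if (abs(nv - s_old) < tol * max(nv, 1)) break
    s_old <- nv
  }
  sqrt(sum((A %*% v)^2))
}

#' Full MUSICAL reconstruction
#'
#' Runs the windowed MUSIC analysis over the whole field: for every
#' acquisition pixel a soft window is extracted (zero-padded at borders),
#' optionally reweighted per frame, split into signal/null subspaces at
#' `sigma0`, and the pseudospectrum `(d_S/d_N)^alpha` is evaluated on the
#' sub-pixel test grid across the window footprint. Overlapping windows are
#' stitched by averaging weighted with the soft-window value at each test
#' point. With the `fraction` sigma0 rule the result is invariant to a
#' global rescaling of the stack, hence also to any constant frame weight.
#'
#' @param stack an [image_stack()].
#' @param cfg a [musical_config()].
#' @param weights optional `FrameWeights` (frame `k` is multiplied by
#'   `w_k` before analysis).
#' @return an [sr_image()] with `mode` `"musical"` (or
#'   `"musical_debiased"` when weights are given).
#' @export
musical_image <- function(stack, cfg = musical_config(), weights = NULL) {
  d <- dim(stack$data)
  H <- d[1]; W <- d[2]; K <- d[3]
  if (!is.null(weights) && length(weights$w) != K)
    stop("weights length must equal the number of frames")
  wk <- if (is.null(weights)) NULL else weights$w
  sig_px <- psf_sigma(stack)
  f <- cfg$subpixel
  grid <- sr_grid(c(H, W), stack$pixel_size, factor = f)
  hs <- (cfg$window_size - 1L) %/% 2L
  # test-point offsets relative to a window centre lie on a fixed lattice:
  # SR pixel centres within the window footprint
  span <- hs + 0.5
  off1d <- (seq_len((2 * hs + 1) * f) - 0.5) / f - span
  tt <- expand.grid(ty = off1d, tx = off1d)
  Gall <- .psf_vectors(.window_offsets(cfg$window_size),
                       .soft_weights(cfg$window_size, cfg$soft_rms),
                       tt$tx, tt$ty, sig_px)
  stitch_w <- exp(-(tt$tx^2 + tt$ty^2) / (2 * cfg$soft_rms^2))
  s1g <- if (cfg$sigma0_scope == "global") {
    st <- stack
    if (!is.null(wk)) st$data <- sweep(st$data, 3, wk, "*")
    .global_sigma1(st)
  } else NULL
  num <- matrix(0, grid$dim[1], grid$dim[2])
  den <- matrix(0, grid$dim[1], grid$dim[2])
  nT1 <- length(off1d)
  for (cx in 0:(W - 1)) for (cy in 0:(H - 1)) {
    win <- extract_window(stack, c(cx, cy), cfg$window_size, cfg$soft_rms)
    if (!is.null(wk)) win$values <- sweep(win$values, 2, wk, "*")
    split <- subspace_split(win, cfg, s1g)
    vals <- if (split$degenerate) rep(0, nrow(tt))
            else .pseudospectrum(Gall, split, cfg)
    # global SR indices of the test points (0-based)
    ix <- floor((cx + tt$tx + 0.5) * f + 1e-9)
    iy <- floor((cy + tt$ty + 0.5) * f + 1e-9)
    ok <- ix >= 0 & ix < grid$dim[2] & iy >= 0 & iy < grid$dim[1]
    lin <- iy[ok] + 1L + grid$dim[1] * ix[ok]
    num[lin] <- num[lin] + stitch_w[ok] * vals[ok]
    den[lin] <- den[lin] + stitch_w[ok]
  }
  out <- num
  nz <- den > 0
  out[nz] <- out[nz] / den[nz]
  sr_image(out, grid,
           mode = if (is.null(weights)) "musical" else "musical_debiased")
}

.window_offsets <- function(window_size) {
  h <- (window_size - 1L) %/% 2L
  off <- as.matrix(expand.grid(dy = -h:h, dx = -h:h))
  off[, c("dx", "dy"), drop = FALSE]
}

.soft_weights <- function(window_size, soft_rms) {
  off <- .window_offsets(window_size)
  exp(-(off[, 1]^2 + off[, 2]^2) / (2 * soft_rms^2))
}

#' Reweight a stack for debiased MUSICAL
#'
#' Multiplies every frame by its debias weight `w_k` (from
#' [stack_weights()]), so that all frames present comparable foreground
#' intensity to the eigen-decomposition. The weighting changes no pixel's
#' signal-to-noise ratio: dividing frame `k` of the result by `w_k`
#' restores the input exactly.
#'
#' @param stack an [image_stack()].
#' @param mode weight rule, see [frame_weight()].
#' @return list with `stack` (weighted copy) and `weights` (`FrameWeights`).
#' @export
debias_stack <- function(stack,
                         mode = c("foreground_mean", "frame_mean", "frame_std")) {
  mode <- match.arg(mode)
  weights <- stack_weights(stack, mode)
  out <- stack
  out$data <- sweep(stack$data, 3, weights$w, "*")
  list(stack = out, weights = weights)
}

#' Temporal null-subspace diagnostics for a window
#'
#' Computes, for the soft window centred at `window_center`, the per-frame
#' window intensity `I_k`, its running mean `Itilde_k` over frames
#' `[1, k]`, the full-stack null-portion level `Itilde * sigma1 / nu`, the
#' same level per temporal sub-stack (with `sigma1`, `nu` recomputed on the
#' sub-stack columns), and, when debias weights are supplied, the debiased
#' level `Jtilde * sigma1 / (nu * w_k)` expressed in original-frame units
#' (`J_k = w_k I_k` is the weighted stack). Comparing the full-stack level
#' with sub-stack levels shows how much intensity whole-stack MUSICAL
#' relegates to the null subspace in low-SNR epochs; the debiased level
#' tracking the sub-stack levels indicates an adaptive threshold.
#'
#' @param stack an [image_stack()].
#' @param window_center `c(x, y)` pixel coordinates (0-based).
#' @param cfg a [musical_config()]; the `knee` sigma0 rule is the natural
#'   choice here.
#' @param substacks list of `c(first, last)` 1-based frame ranges.
#' @param weights optional `FrameWeights`.
#' @return A `TemporalDiagnostics` list: `I_k`, `Itilde_k`, `level_full`,
#'   `substacks` (data frame: `first`, `last`, `Itilde`, `sigma1`, `nu`,
#'   `level`), `level_debiased` (per frame, or `NULL`), `undefined` flag
#'   (`TRUE` when `nu = 0`).
#' @export
temporal_diagnostics <- function(stack, window_center, cfg = musical_config(),
                                 substacks = list(), weights = NULL) {
  K <- n_frames(stack)
  win <- extract_window(stack, window_center, cfg$window_size, cfg$soft_rms)
  # raw (soft-weight-free) window sums for the intensity series
  I_k <- colSums(win$values / win$soft_weights)
  Itilde_k <- cumsum(I_k) / seq_len(K)
  lvl <- function(vals, Ibar) {
    sv <- svd(vals)$d
    sigma0 <- .resolve_sigma0(sv, cfg)
    nu <- sqrt(sum(sv[sv <= sigma0]^2))
    if (nu == 0) return(c(NA_real_, sv[1], nu))
    c(Ibar * sv[1] / nu, sv[1], nu)
  }
  full <- lvl(win$values, mean(I_k))
  sub <- NULL
  for (rg in substacks) {
    stopifnot(rg[1] >= 1, rg[2] <= K, rg[1] <= rg[2])
    ks <- rg[1]:rg[2]
    l <- lvl(win$values[, ks, drop = FALSE], mean(I_k[ks]))
    sub <- rbind(sub, data.frame(first = rg[1], last = rg[2],
                                 Itilde = mean(I_k[ks]), sigma1 = l[2],
                                 nu = l[3], level = l[1]))
  }
  level_deb <- NULL
  if (!is.null(weights)) {
    stopifnot(length(weights$w) == K)
    Jvals <- sweep(win$values, 2, weights$w, "*")
    J_k <- I_k * weights$w
    lj <- lvl(Jvals, mean(J_k))
    level_deb <- lj[1] / weights$w
  }
  structure(list(I_k = I_k, Itilde_k = Itilde_k, level_full = full[1],
                 sigma1 = full[2], nu = full[3], substacks = sub,
                 level_debiased = level_deb,
                 undefined = is.na(full[1])),
            class = "TemporalDiagnostics")
}
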
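# Shared fixtures, all generated in code.

# Small Poisson-noise stack with no structure.
noise_stack <- function(H = 12, W = 12, K = 40, mean = 20, seed = 1) {
  set.seed(seed)
  image_stack(array(stats::rpois(H * W * K, mean), c(H, W, K)) + 0.0,
              pixel_size = 100, frame_rate = 50, wavelength = 600, na = 1.49)
}

# Stack with one static emitter rendered noiselessly at a given position.
static_emitter_stack <- function(x0 = 9, y0 = 9, photons = 500, K = 5,
                                 H = 19, W = 19, sigma_px = 0.85,
                                 background = 0) {
  fr <- matrix(background, H, W)
  fx <- stats::pnorm(0:(W - 1) + 0.5, x0, sigma_px) -
    stats::pnorm(0:(W - 1) - 0.5, x0, sigma_px)
  fy <- stats::pnorm(0:(H - 1) + 0.5, y0, sigma_px) -
    stats::pnorm(0:(H - 1) - 0.5, y0, sigma_px)
  fr <- fr + photons * outer(fy, fx)
  image_stack(array(rep(fr, K), c(H, W, K)),
              pixel_size = 100, frame_rate = 50, wavelength = 600, na = 1.49)
}

# Deterministic window matrix with prescribed singular values.
matrix_with_sv <- function(d, N = 6, K = 4, seed = 3) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(stats::rnorm(N * N), N)))[, seq_along(d), drop = FALSE]
  V <- qr.Q(qr(matrix(stats::rnorm(K * K), K)))[, seq_along(d), drop = FALSE]
  U %*% diag(d, length(d)) %*% t(V)
}

# Wrap a plain N x K matrix as a WindowMatrix with trivial geometry.
as_window <- function(values, window_size = NULL) {
  N <- nrow(values)
  ws <- if (is.null(window_size)) as.integer(round(sqrt(N))) else window_size
  h <- (ws - 1) %/% 2
  off <- as.matrix(expand.grid(dy = -h:h, dx = -h:h))[, c("dx", "dy")]
  structure(list(values = values, center = c(h, h),
                 offsets = off, soft_weights = rep(1, N),
                 window_size = ws, soft_rms = 3),
            class = "WindowMatrix")
}

# A small fork run shared by the slower integration tests (computed once).
fork_small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(run_fork_experiment(fork_preset_small(seed = 11)))
    cache
  }
})
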
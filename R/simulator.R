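#' Simulation configuration
#'
#' Parameters of the synthetic blinking-fluorophore experiment: a telegraph
#' (on/off) photoswitching process with mean on/off times, irreversible
#' photobleaching, Poisson photon emission, diffraction-limited imaging and
#' Poisson shot noise. Defaults reproduce a demanding but realistic STORM-like
#' acquisition: 5 ms mean on time, 95 ms mean off time (duty cycle 5%),
#' bleaching time constant 540 ms, 1e5 photons/s, NA 1.49, 100 nm pixels,
#' 50 frames/s over 10,000 frames, signal-to-background ratio 100.
#'
#' @param tau_on,tau_off mean on/off durations, ms.
#' @param tau_bleach bleaching time constant, ms (`Inf` disables bleaching).
#' @param photon_rate emission rate while on, photons/s.
#' @param na numerical aperture.
#' @param magnification optical magnification (sample nm per camera nm).
#' @param pixel_size camera pixel size in sample units, nm.
#' @param n_frames number of frames.
#' @param frame_rate frames per second.
#' @param sbr signal-to-background ratio: mean noiseless foreground signal
#'   divided by the uniform background level. `Inf` disables background.
#' @param wavelength emission wavelength, nm.
#' @param img_shape `c(H, W)` field size in pixels.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param bleach_mode `"memoryless"` draws the bleach time from an
#'   exponential law with mean `tau_bleach` (survival exactly
#'   `exp(-t / tau_bleach)`); `"literal"` applies, before every frame, a
#'   uniform draw compared against `exp(-t / tau_bleach)` with `t` the time
#'   since acquisition start (a stricter, super-exponential rule).
#' @param duration_law `"exponential"` draws on/off durations from
#'   exponential laws with the stated means (standard telegraph model);
#'   `"poisson_ms"` draws integer millisecond durations from Poisson laws
#'   with the same means.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(tau_on = 5, tau_off = 95, tau_bleach = 540,
                       photon_rate = 1e5, na = 1.49, magnification = 1,
                       pixel_size = 100, n_frames = 10000, frame_rate = 50,
                       sbr = 100, wavelength = 600, img_shape = c(24, 24),
                       seed = NULL,
                       bleach_mode = c("memoryless", "literal"),
                       duration_law = c("exponential", "poisson_ms")) {
  stopifnot(tau_on > 0, tau_off > 0, tau_bleach > 0, photon_rate > 0,
            na > 0, pixel_size > 0, n_frames >= 1, frame_rate > 0,
            sbr > 0, wavelength > 0, all(img_shape >= 1))
  structure(list(tau_on = tau_on, tau_off = tau_off, tau_bleach = tau_bleach,
                 photon_rate = photon_rate, na = na,
                 magnification = magnification, pixel_size = pixel_size,
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 sbr = sbr, wavelength = wavelength,
                 img_shape = as.integer(img_shape), seed = seed,
                 bleach_mode = match.arg(bleach_mode),
                 duration_law = match.arg(duration_law)),
            class = "SimConfig")
}

#' Fork test geometry
#'
#' Builds the fork phantom used throughout the package: a stem of length
#' `segment_length` and two prongs of the same length joined at the top of
#' the stem, the prongs separated by `prong_angle` symmetrically about the
#' stem axis. Emitters are placed uniformly at random along each segment.
#' The junction is at the origin; the stem extends along `-y`.
#'
#' @param n_per_segment emitters per segment.
#' @param segment_length segment length, nm.
#' @param prong_angle angle between the two prongs, degrees.
#' @param seed integer RNG seed or `NULL`.
#' @return An `EmitterSet`: data frame with columns `x`, `y` (nm) and
#'   `segment_id` (1 = stem, 2-3 = prongs); segment endpoints (nm) in
#'   `attr(, "geometry")`.
#' @export
make_fork_geometry <- function(n_per_segment = 100, segment_length = 500,
                               prong_angle = 30, seed = NULL) {
  stopifnot(n_per_segment >= 0, segment_length > 0)
  if (!is.null(seed)) set.seed(seed)
  half <- prong_angle / 2 * pi / 180
  dirs <- rbind(c(0, -1),                    # stem, from junction downwards
                c(sin(half), cos(half)),     # prong +
                c(-sin(half), cos(half)))    # prong -
  geometry <- data.frame(segment_id = 1:3, x0 = 0, y0 = 0,
                         x1 = dirs[, 1] * segment_length,
                         y1 = dirs[, 2] * segment_length)
  if (n_per_segment == 0) {
    em <- data.frame(x = numeric(0), y = numeric(0), segment_id = integer(0))
  } else {
    t <- stats::runif(3 * n_per_segment)
    seg <- rep(1:3, each = n_per_segment)
    em <- data.frame(x = t * segment_length * dirs[seg, 1],
                     y = t * segment_length * dirs[seg, 2],
                     segment_id = seg)
  }
  structure(em, geometry = geometry, class = c("EmitterSet", "data.frame"))
}

# Sample one emitter's on intervals (ms) over [0, t_total], truncated at the
# bleach time. Telegraph process started in its stationary state.
.sample_intervals <- function(cfg, t_total, bleach_time) {
  t_end <- min(t_total, bleach_time)
  draw <- function(n, tau)
    if (cfg$duration_law == "exponential") stats::rexp(n, 1 / tau)
    else stats::rpois(n, tau)
  on <- stats::runif(1) < cfg$tau_on / (cfg$tau_on + cfg$tau_off)
  t <- 0
  starts <- numeric(0); ends <- numeric(0)
  while (t < t_end) {
    dur <- draw(1, if (on) cfg$tau_on else cfg$tau_off)
    if (on && dur > 0) {
      starts <- c(starts, t)
      ends <- c(ends, min(t + dur, t_end))
    }
    t <- t + dur
    on <- !on
    if (dur == 0 && cfg$duration_law == "poisson_ms") {
      # zero-length Poisson draws: avoid infinite loops by forcing progress
      t <- t + .Machine$double.eps
    }
  }
  cbind(start = starts, end = ends)
}

#' Simulate blinking and bleaching traces
#'
#' Draws, for every emitter, a continuous-time on/off telegraph process with
#' mean on/off durations `tau_on`/`tau_off`, applies photobleaching per
#' `cfg$bleach_mode`, and (optionally) samples per-frame photon counts as
#' `Poisson(photon_rate * on-time overlap with the frame exposure)`.
#' Exposure is 100% duty cycle: frame `k` integrates over
#' `[(k-1)/frame_rate, k/frame_rate)`.
#'
#' @param emitters an `EmitterSet` (only the number of emitters is used).
#' @param cfg a [sim_config()].
#' @param sample_photons if `FALSE`, skip photon sampling (`photons = NULL`);
#'   useful for bleaching statistics on many emitters.
#' @return An `EmitterTraces` list: `intervals` (per-emitter matrices of on
#'   interval `start`/`end` in ms, truncated at the bleach time),
#'   `bleach_time` (ms, `Inf` if unbleached within the acquisition),
#'   `photons` (`K x n_emitters` integer matrix or `NULL`), `frame_dt` (ms),
#'   `n_frames`.
#' @export
sample_traces <- function(emitters, cfg, sample_photons = TRUE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- nrow(emitters)
  dt <- 1000 / cfg$frame_rate                 # frame duration, ms
  t_total <- cfg$n_frames * dt
  bleach <- if (!is.finite(cfg$tau_bleach)) rep(Inf, n)
  else if (cfg$bleach_mode == "memoryless") stats::rexp(n, 1 / cfg$tau_bleach)
  else .literal_bleach_times(n, dt, cfg$n_frames, cfg$tau_bleach)
  intervals <- lapply(seq_len(n), function(i)
    .sample_intervals(cfg, t_total, bleach[i]))
  photons <- NULL
  if (sample_photons && n > 0) {
    photons <- matrix(0L, cfg$n_frames, n)
    for (i in seq_len(n)) {
      ov <- .frame_overlap(intervals[[i]], dt, cfg$n_frames)
      nz <- which(ov > 0)
      if (length(nz))
        photons[nz, i] <- stats::rpois(length(nz), cfg$photon_rate * ov[nz] / 1000)
    }
  } else if (sample_photons) {
    photons <- matrix(0L, cfg$n_frames, 0)
  }
  structure(list(intervals = intervals,
                 bleach_time = ifelse(bleach > t_total, Inf, bleach),
                 photons = photons, frame_dt = dt,
                 n_frames = cfg$n_frames),
            class = "EmitterTraces")
}

# Literal per-frame bleaching rule: before frame k (elapsed time t), each
# still-active emitter draws u ~ U(0,1) and bleaches if u > exp(-t/tau).
.literal_bleach_times <- function(n, dt, K, tau) {
  bleach <- rep(Inf, n)
  active <- rep(TRUE, n)
  for (k in seq_len(K)) {
    t <- (k - 1) * dt
    idx <- which(active)
    if (!length(idx)) break
    u <- stats::runif(length(idx))
    hit <- u > exp(-t / tau)
    bleach[idx[hit]] <- t
    active[idx[hit]] <- FALSE
  }
  bleach
}

# On-time overlap (ms) of a set of [start, end) intervals with each of K
# frames of duration dt.
.frame_overlap <- function(iv, dt, K) {
  ov <- numeric(K)
  if (!nrow(iv)) return(ov)
  for (j in seq_len(nrow(iv))) {
    a <- iv[j, 1]; b <- iv[j, 2]
    if (b <= a) next
    k0 <- max(1L, floor(a / dt) + 1L)
    k1 <- min(K, ceiling(b / dt))
    if (k1 < k0) next
    ks <- k0:k1
    ov[ks] <- ov[ks] + pmax(0, pmin(b, ks * dt) - pmax(a, (ks - 1) * dt))
  }
  ov
}

#' Map emitter positions to pixel coordinates
#'
#' Emitters are placed so that the bounding box of the geometry is centred in
#' the field. Returns continuous 0-based pixel coordinates (centre of pixel
#' `(0,0)` is the origin).
#'
#' @param emitters an `EmitterSet` (positions in nm).
#' @param cfg a [sim_config()].
#' @return data frame with `x_px`, `y_px`.
#' @export
emitters_to_px <- function(emitters, cfg) {
  geo <- attr(emitters, "geometry")
  xs <- c(geo$x0, geo$x1); ys <- c(geo$y0, geo$y1)
  cx <- mean(range(xs)); cy <- mean(range(ys))
  H <- cfg$img_shape[1]; W <- cfg$img_shape[2]
  data.frame(
    x_px = (emitters$x - cx) * cfg$magnification / cfg$pixel_size + (W - 1) / 2,
    y_px = (emitters$y - cy) * cfg$magnification / cfg$pixel_size + (H - 1) / 2)
}

# Pixel-integrated Gaussian PSF: photons spread over pixels by the product of
# 1-D Gaussian integrals (error functions) in x and y.
.add_psf <- function(frame, x0, y0, n_photons, sigma_px) {
  H <- nrow(frame); W <- ncol(frame)
  r <- ceiling(4 * sigma_px) + 1L
  cx <- round(x0); cy <- round(y0)
  xs <- max(0, cx - r):min(W - 1, cx + r)
  ys <- max(0, cy - r):min(H - 1, cy + r)
  if (!length(xs) || !length(ys)) return(frame)
  fx <- stats::pnorm(xs + 0.5, x0, sigma_px) - stats::pnorm(xs - 0.5, x0, sigma_px)
  fy <- stats::pnorm(ys + 0.5, y0, sigma_px) - stats::pnorm(ys - 0.5, y0, sigma_px)
  frame[ys + 1L, xs + 1L] <- frame[ys + 1L, xs + 1L] + n_photons * outer(fy, fx)
  frame
}

#' Render an image stack from traces
#'
#' Spreads each emitter's per-frame photons by the pixel-integrated Gaussian
#' PSF (`sigma = 0.21 * lambda / NA`), adds a uniform background chosen so
#' that the mean noiseless foreground signal equals `sbr` times the
#' background level, and (unless `noiseless`) replaces every pixel by a
#' Poisson draw with that mean. Foreground pixels are those within
#' `2 * sigma_psf` of any emitter; the mean is taken over frames with at
#' least one active emitter.
#'
#' @param emitters an `EmitterSet`.
#' @param traces matching `EmitterTraces` with photon counts.
#' @param cfg a [sim_config()].
#' @param noiseless if `TRUE`, return expected values (no shot noise).
#' @param background if `FALSE`, omit the background term.
#' @return an [image_stack()].
#' @export
render_frames <- function(emitters, traces, cfg, noiseless = FALSE,
                          background = TRUE) {
  if (is.null(traces$photons)) stop("traces carry no photon counts")
  H <- cfg$img_shape[1]; W <- cfg$img_shape[2]; K <- cfg$n_frames
  sigma_px <- 0.21 * cfg$wavelength / cfg$na / cfg$pixel_size
  pos <- emitters_to_px(emitters, cfg)
  data <- array(0, dim = c(H, W, K))
  n <- nrow(emitters)
  for (k in seq_len(K)) {
    fr <- matrix(0, H, W)
    if (n > 0) {
      act <- which(traces$photons[k, ] > 0)
      for (i in act)
        fr <- .add_psf(fr, pos$x_px[i], pos$y_px[i], traces$photons[k, i], sigma_px)
    }
    data[, , k] <- fr
  }
  if (background && is.finite(cfg$sbr) && n > 0) {
    fg <- .foreground_pixels(pos, c(H, W), 2 * sigma_px)
    frames_on <- which(rowSums(traces$photons) > 0)
    if (length(frames_on) && any(fg)) {
      sig <- mean(apply(data[, , frames_on, drop = FALSE], 3,
                        function(f) mean(f[fg])))
      b <- sig / cfg$sbr
      data <- data + b
    }
  }
  if (!noiseless)
    data <- array(stats::rpois(length(data), data), dim = dim(data))
  image_stack(data, cfg$pixel_size, cfg$frame_rate, cfg$wavelength, cfg$na)
}

.foreground_pixels <- function(pos, shape, radius_px) {
  H <- shape[1]; W <- shape[2]
  fg <- matrix(FALSE, H, W)
  gx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  gy <- matrix(0:(H - 1), H, W)
  for (i in seq_len(nrow(pos)))
    fg <- fg | ((gx - pos$x_px[i])^2 + (gy - pos$y_px[i])^2 <= radius_px^2)
  fg
}

#' Ground-truth maps on a super-resolution grid
#'
#' Bins, at each emitter's true position, the number of emission events
#' (on intervals) and the total number of emitted photons. These are the
#' references against which count-mode and photon-mode reconstructions are
#' judged.
#'
#' @param emitters an `EmitterSet`.
#' @param traces matching `EmitterTraces`.
#' @param grid an [sr_grid()].
#' @param cfg the [sim_config()] used for rendering (fixes the nm-to-pixel
#'   placement).
#' @return list of two [sr_image()]s: `event_map` and `photon_map`.
#' @export
ground_truth_maps <- function(emitters, traces, grid, cfg) {
  pos <- emitters_to_px(emitters, cfg)
  ev <- matrix(0, grid$dim[1], grid$dim[2])
  ph <- matrix(0, grid$dim[1], grid$dim[2])
  for (i in seq_len(nrow(pos))) {
    ij <- sr_bin(grid, pos$x_px[i], pos$y_px[i])
    if (any(is.na(ij))) next
    ev[ij[2], ij[1]] <- ev[ij[2], ij[1]] + nrow(traces$intervals[[i]])
    if (!is.null(traces$photons))
      ph[ij[2], ij[1]] <- ph[ij[2], ij[1]] + sum(traces$photons[, i])
  }
  list(event_map = sr_image(ev, grid, mode = "events"),
       photon_map = sr_image(ph, grid, mode = "photons_truth"))
}
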
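test_that("fork geometry has configured counts, angle and on-segment emitters", {
  em <- make_fork_geometry(seed = 5)
  expect_equal(nrow(em), 300)
  expect_equal(as.vector(table(em$segment_id)), rep(100L, 3))
  geo <- attr(em, "geometry")
  v2 <- c(geo$x1[2] - geo$x0[2], geo$y1[2] - geo$y0[2])
  v3 <- c(geo$x1[3] - geo$x0[3], geo$y1[3] - geo$y0[3])
  ang <- acos(sum(v2 * v3) / sqrt(sum(v2^2) * sum(v3^2))) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-12)
  expect_equal(sqrt(sum(v2^2)), 500)
  # every emitter lies on its segment (distance to segment ~ 0)
  for (s in 1:3) {
    pts <- em[em$segment_id == s, ]
    d <- c(geo$x1[s] - geo$x0[s], geo$y1[s] - geo$y0[s]) / 500
    perp <- abs((pts$x - geo$x0[s]) * d[2] - (pts$y - geo$y0[s]) * d[1])
    expect_lt(max(perp), 1e-9)
  }
  # empty set still carries the geometry
  e0 <- make_fork_geometry(n_per_segment = 0)
  expect_equal(nrow(e0), 0)
  expect_equal(nrow(attr(e0, "geometry")), 3)
})

test_that("sampled traces have the configured photokinetics", {
  cfg <- sim_config(n_frames = 600, frame_rate = 50, tau_bleach = Inf,
                    img_shape = c(16, 16), seed = 8)
  em <- make_fork_geometry(n_per_segment = 100, seed = 8)
  tr <- sample_traces(em, cfg)
  # on-duration mean: exclude intervals truncated by the acquisition end
  durs <- unlist(lapply(tr$intervals, function(iv) {
    d <- iv[, "end"] - iv[, "start"]
    d[iv[, "end"] < 600 * 20]
  }))
  expect_gt(length(durs), 1e4)
  expect_lt(abs(mean(durs) - 5), 3 * 5 / sqrt(length(durs)))
  # photon rate: photons per unit on-time
  on_ms <- sum(unlist(lapply(tr$intervals, function(iv)
    sum(iv[, "end"] - iv[, "start"]))))
  rate <- sum(tr$photons) / (on_ms / 1000)
  expect_lt(abs(rate - 1e5), 3 * sqrt(sum(tr$photons)) / (on_ms / 1000))
  # no photons without on-time overlap, none after bleach
  cfgb <- sim_config(n_frames = 200, img_shape = c(16, 16), seed = 9)
  trb <- sample_traces(em, cfgb)
  for (i in c(1, 57, 200)) {
    ov <- smlmdebias:::.frame_overlap(trb$intervals[[i]], trb$frame_dt, 200)
    expect_true(all(trb$photons[ov == 0, i] == 0))
  }
  # reproducibility: same seed identical, different seed different
  tr2 <- sample_traces(em, cfg)
  expect_identical(tr$photons, tr2$photons)
  cfg2 <- cfg; cfg2$seed <- 99
  expect_false(identical(sample_traces(em, cfg2)$photons, tr$photons))
})

test_that("memoryless bleaching survival matches the exponential law", {
  cfg <- sim_config(n_frames = 100, img_shape = c(8, 8), seed = 10)
  em <- data.frame(x = numeric(2e4), y = numeric(2e4), segment_id = 1L)
  attr(em, "geometry") <- attr(make_fork_geometry(0), "geometry")
  tr <- sample_traces(em, cfg, sample_photons = FALSE)
  for (t in c(100, 540, 1500)) {
    p <- exp(-t / 540)
    frac <- mean(tr$bleach_time > t)
    expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / 2e4))
  }
})

test_that("literal bleach rule is stricter than the memoryless one", {
  em <- data.frame(x = numeric(5e3), y = numeric(5e3), segment_id = 1L)
  attr(em, "geometry") <- attr(make_fork_geometry(0), "geometry")
  cfg <- sim_config(n_frames = 60, img_shape = c(8, 8), seed = 12,
                    bleach_mode = "literal")
  tr <- sample_traces(em, cfg, sample_photons = FALSE)
  t <- 540
  expect_lt(mean(tr$bleach_time > t), exp(-t / 540))
})

test_that("noiseless rendering conserves photons and is linear", {
  cfg <- sim_config(n_frames = 20, img_shape = c(30, 30), sbr = Inf,
                    tau_bleach = Inf, seed = 13)
  # single emitter well away from borders
  em <- data.frame(x = 10, y = -20, segment_id = 1L)
  attr(em, "geometry") <- data.frame(segment_id = 1, x0 = 0, y0 = 0,
                                     x1 = 0, y1 = -1)
  tr <- sample_traces(em, cfg)
  st <- render_frames(em, tr, cfg, noiseless = TRUE, background = FALSE)
  expect_equal(apply(st$data, 3, sum), as.numeric(tr$photons[, 1]),
               tolerance = 1e-6)
  # linearity in photons_per_frame
  tr2 <- tr; tr2$photons <- tr$photons * 3L
  st2 <- render_frames(em, tr2, cfg, noiseless = TRUE, background = FALSE)
  expect_equal(st2$data, st$data * 3, tolerance = 1e-12)
})

test_that("rendered PSF matches the pixel-integrated Gaussian oracle", {
  cfg <- sim_config(n_frames = 1, img_shape = c(15, 15), sbr = Inf,
                    tau_bleach = Inf, seed = 14)
  em <- data.frame(x = 0, y = 0, segment_id = 1L)
  attr(em, "geometry") <- data.frame(segment_id = 1, x0 = 0, y0 = 0,
                                     x1 = 0, y1 = 0)
  tr <- sample_traces(em, cfg)
  tr$photons[1, 1] <- 1000L
  st <- render_frames(em, tr, cfg, noiseless = TRUE, background = FALSE)
  pos <- emitters_to_px(em, cfg)
  sig <- psf_sigma(st)
  # brightest pixel at the emitter
  pk <- which(st$data[, , 1] == max(st$data[, , 1]), arr.ind = TRUE)
  expect_equal(unname(pk[1, "col"] - 1), round(pos$x_px))
  expect_equal(unname(pk[1, "row"] - 1), round(pos$y_px))
  # numeric double-integral oracle over a few pixels
  for (px in list(c(7, 7), c(8, 7), c(6, 9))) {
    oracle <- 1000 * stats::integrate(function(x)
      exp(-(x - pos$x_px)^2 / (2 * sig^2)) / sqrt(2 * pi * sig^2),
      px[1] - 0.5, px[1] + 0.5)$value *
      stats::integrate(function(y)
        exp(-(y - pos$y_px)^2 / (2 * sig^2)) / sqrt(2 * pi * sig^2),
        px[2] - 0.5, px[2] + 0.5)$value
    expect_equal(st$data[px[2] + 1, px[1] + 1, 1], oracle, tolerance = 1e-6)
  }
})

test_that("background level realizes the configured SBR; zero emitters give flat frames", {
  cfg <- sim_config(n_frames = 30, img_shape = c(16, 16), sbr = 100,
                    seed = 15)
  em <- make_fork_geometry(seed = 15)
  tr <- sample_traces(em, cfg)
  stn <- render_frames(em, tr, cfg, noiseless = TRUE)
  st0 <- render_frames(em, tr, cfg, noiseless = TRUE, background = FALSE)
  b <- min(stn$data - st0$data)
  expect_equal(max(stn$data - st0$data), b, tolerance = 1e-9)  # uniform
  pos <- emitters_to_px(em, cfg)
  fg <- smlmdebias:::.foreground_pixels(pos, c(16, 16), 2 * psf_sigma(stn))
  frames_on <- which(rowSums(tr$photons) > 0)
  sig <- mean(apply(st0$data[, , frames_on, drop = FALSE], 3,
                    function(f) mean(f[fg])))
  expect_equal(sig / b, 100, tolerance = 1e-9)
})

test_that("ground-truth maps conserve events and photons", {
  cfg <- sim_config(n_frames = 50, img_shape = c(16, 16), seed = 16)
  em <- make_fork_geometry(seed = 16)
  tr <- sample_traces(em, cfg)
  grid <- sr_grid(c(16, 16), 100, factor = 8)
  maps <- ground_truth_maps(em, tr, grid, cfg)
  expect_equal(sum(maps$photon_map$values), sum(tr$photons))
  expect_equal(sum(maps$event_map$values),
               sum(vapply(tr$intervals, nrow, integer(1))))
  expect_true(all(maps$event_map$values >= 0))
  expect_true(all(maps$event_map$values == round(maps$event_map$values)))
})
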
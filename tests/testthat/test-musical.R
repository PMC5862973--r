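test_that("identical frames give a single nonzero singular value whose eigenimage is the mean image", {
  st <- noise_stack(10, 10, 1, seed = 51)
  stc <- image_stack(array(rep(st$data[, , 1], 8), c(10, 10, 8)),
                     100, 50, 600, 1.49)
  win <- extract_window(stc, c(5, 5))
  sp <- subspace_split(win)
  expect_equal(sum(sp$singular_values > 1e-8 * sp$singular_values[1]), 1)
  e1 <- sp$eigenimages[, 1]
  mean_img <- rowMeans(win$values)
  cosang <- abs(sum(e1 * mean_img)) / sqrt(sum(mean_img^2))
  expect_equal(cosang, 1, tolerance = 1e-12)
})

test_that("nu follows its definition on a prescribed spectrum", {
  A <- matrix_with_sv(c(3, 2, 1))
  win <- as_window(A)
  sp15 <- subspace_split(win, musical_config(sigma0_rule = "fixed",
                                             sigma0_value = 1.5))
  expect_equal(sp15$nu, 1, tolerance = 1e-10)
  sp25 <- subspace_split(win, musical_config(sigma0_rule = "fixed",
                                             sigma0_value = 2.5))
  expect_equal(sp25$nu, sqrt(5), tolerance = 1e-10)
  # nu non-decreasing in sigma0
  nus <- vapply(c(0.5, 1.5, 2.5, 3.5), function(s0)
    subspace_split(win, musical_config(sigma0_rule = "fixed",
                                       sigma0_value = s0))$nu, numeric(1))
  expect_true(all(diff(nus) >= 0))
})

test_that("window SVD agrees with the Gram-matrix eigendecomposition oracle", {
  set.seed(52)
  A <- matrix(rnorm(24), 6, 4)
  win <- as_window(A)
  sp <- subspace_split(win)
  ev <- eigen(tcrossprod(A), symmetric = TRUE)
  expect_lt(max(abs(sp$singular_values - sqrt(pmax(ev$values[1:4], 0)))),
            1e-8)
  # subspace projectors match (eigenvectors may differ by sign/rotation)
  k <- length(sp$signal_idx)
  Ps <- tcrossprod(sp$eigenimages[, sp$signal_idx, drop = FALSE])
  Pe <- tcrossprod(ev$vectors[, seq_len(k), drop = FALSE])
  expect_lt(max(abs(Ps - Pe)), 1e-8)
  # orthonormality and descending order on a real window
  st <- noise_stack(12, 12, 30, seed = 53)
  spw <- subspace_split(extract_window(st, c(6, 6)))
  U <- spw$eigenimages
  expect_lt(max(abs(crossprod(U) - diag(ncol(U)))), 1e-10)
  expect_true(all(diff(spw$singular_values) <= 1e-12))
})

test_that("pseudospectrum ratio identities and completeness hold", {
  st <- noise_stack(12, 12, 60, seed = 54)
  win <- extract_window(st, c(6, 6))
  sp <- subspace_split(win)
  cfg <- musical_config()
  sig <- psf_sigma(st)
  # d_S^2 + d_N^2 = 1 for the unit-normalized PSF vector (K >= N)
  g <- smlmdebias:::.psf_vectors(sp$offsets, sp$soft_weights, 0.2, -0.4, sig)
  Us <- sp$eigenimages[, sp$signal_idx, drop = FALSE]
  P <- crossprod(Us, g)
  ds2 <- sum(P^2)
  dn2 <- sum((g - Us %*% P)^2)
  expect_lt(abs(ds2 + dn2 - 1), 1e-10)
  # (d_S / d_N)^alpha: alpha = 4 quadruples the log-ratio
  v <- pseudospectrum_at(c(0.2, -0.4), sp, cfg, sig)
  expect_equal(v, (sqrt(ds2) / sqrt(dn2))^4, tolerance = 1e-8)
  # ratio identity: d_S = d_N -> 1; ratio 2 with alpha 4 -> 16
  expect_equal((1 / 1)^cfg$alpha, 1)
  expect_equal((2)^cfg$alpha, 16)
  # degenerate (all-zero) window -> 0
  z <- image_stack(array(0, c(9, 9, 4)) + 0, 100, 50, 600, 1.49)
  z$data[1, 1, ] <- 1  # keep stack valid but window at far corner all zero
  spz <- subspace_split(extract_window(z, c(7, 7), 3, 3))
  expect_true(spz$degenerate)
  expect_equal(pseudospectrum_at(c(0, 0), spz, cfg, sig), 0)
})

test_that("musical_image is invariant to global scaling and uniform weights", {
  st <- noise_stack(12, 12, 40, seed = 55)
  cfg <- musical_config(subpixel = 2)
  m1 <- musical_image(st, cfg)
  st2 <- st; st2$data <- st2$data * 7.3
  m2 <- musical_image(st2, cfg)
  expect_equal(m2$values, m1$values, tolerance = 1e-5)
  w <- structure(list(w = rep(3.3, 40), one_over_w = rep(1 / 3.3, 40),
                      mode = "frame_mean", n_foreground = rep(NA, 40)),
                 class = "FrameWeights")
  m3 <- musical_image(st, cfg, w)
  expect_equal(m3$values, m1$values, tolerance = 1e-5)
  expect_error(musical_image(st, cfg, structure(list(w = rep(1, 5)),
                                                class = "FrameWeights")),
               "length")
})

test_that("two blinking emitters 150 nm apart are resolved near their true positions", {
  set.seed(56)
  H <- 15; W <- 15; K <- 500
  sig_px <- 0.21 * 600 / 1.49 / 100
  x1 <- 6.3; x2 <- 7.8; yy <- 7.0   # 150 nm apart on 100 nm pixels
  data <- array(0, c(H, W, K))
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  spread <- function(x0, y0, n) {
    fx <- pnorm(xs + 0.5, x0, sig_px) - pnorm(xs - 0.5, x0, sig_px)
    fy <- pnorm(ys + 0.5, y0, sig_px) - pnorm(ys - 0.5, y0, sig_px)
    n * outer(fy, fx)
  }
  for (k in 1:K) {
    fr <- matrix(2, H, W)
    if (runif(1) < 0.4) fr <- fr + spread(x1, yy, 800)
    if (runif(1) < 0.4) fr <- fr + spread(x2, yy, 800)
    data[, , k] <- rpois(H * W, fr)
  }
  st <- image_stack(data, 100, 50, 600, 1.49)
  mi <- musical_image(st, musical_config(subpixel = 8))
  row <- mi$values[floor((yy + 0.5) * 8) + 1, ]
  xc <- (seq_len(ncol(mi$values)) - 0.5) / 8 - 0.5
  sel <- xc > 5 & xc < 9
  prof <- log10(row[sel] + 1e-12); xr <- xc[sel]
  # two local maxima within 40 nm of the true emitters
  pk <- which(diff(sign(diff(prof))) == -2) + 1
  expect_gte(length(pk), 2)
  top <- pk[order(prof[pk], decreasing = TRUE)[1:2]]
  found <- sort(xr[top])
  expect_lt(abs(found[1] - x1) * 100, 40)
  expect_lt(abs(found[2] - x2) * 100, 40)
})

test_that("debias_stack equalizes foreground means and preserves per-pixel SNR", {
  cfgs <- sim_config(n_frames = 40, img_shape = c(20, 20), seed = 57,
                     tau_bleach = 700)
  em <- make_fork_geometry(seed = 57)
  tr <- sample_traces(em, cfgs)
  st <- render_frames(em, tr, cfgs)
  deb <- suppressWarnings(debias_stack(st, "foreground_mean"))
  for (k in c(1, 10, 25)) {
    m <- detect_foreground(st$data[, , k])
    if (m$degenerate || m$n_foreground == 0) next
    expect_equal(mean(deb$stack$data[, , k][m$mask]), 1, tolerance = 1e-12)
  }
  # exact inverse: weighted frame / w_k reproduces the original
  k <- 5
  expect_equal(deb$stack$data[, , k] / deb$weights$w[k], st$data[, , k],
               tolerance = 1e-14)
  # constant stack: output equals input up to one global scale
  stc <- image_stack(array(rep(st$data[, , 1], 3), c(20, 20, 3)),
                     100, 50, 600, 1.49)
  debc <- debias_stack(stc, "frame_mean")
  pos <- stc$data > 0
  ratio <- debc$stack$data[pos] / stc$data[pos]
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("knee threshold sits at the maximum-distance point of the log spectrum", {
  chord_oracle <- function(d) {
    y <- log(d); x <- seq_along(d); n <- length(d)
    num <- abs((y[n] - y[1]) * (x - x[1]) - (x[n] - x[1]) * (y - y[1]))
    which.max(num / sqrt((y[n] - y[1])^2 + (x[n] - x[1])^2))
  }
  d1 <- c(100, 1, 0.9, 0.8, 0.7)
  k1 <- knee_sigma0(d1)
  expect_equal(attr(k1, "index"), 2)
  expect_equal(attr(k1, "index"), chord_oracle(d1))
  expect_equal(as.numeric(k1), 1)
  # strictly geometric decay: knee strictly interior
  d2 <- 100 * 0.5^(0:9)
  k2 <- knee_sigma0(d2)
  expect_true(attr(k2, "index") > 1 && attr(k2, "index") < 10)
  expect_equal(attr(k2, "index"), chord_oracle(d2))
  # two plateaus: knee between them
  d3 <- c(rep(50, 4), 49, 10, rep(1, 5), 0.95)
  k3 <- knee_sigma0(d3)
  expect_equal(attr(k3, "index"), chord_oracle(d3))
  expect_true(attr(k3, "index") >= 5 && attr(k3, "index") <= 7)
  expect_error(knee_sigma0(c(3, 2)), "at least 3")
})

test_that("temporal diagnostics match a hand-computed two-frame oracle", {
  # 3 x 3 stack, 2 frames, window covering the full frame with no taper
  f1 <- matrix(c(4, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  f2 <- matrix(c(0, 2, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  st <- image_stack(array(c(f1, f2), c(3, 3, 2)), 100, 50, 600, 1.49)
  cfg <- musical_config(window_size = 3, soft_rms = 1e6,
                        sigma0_rule = "fixed", sigma0_value = 3)
  dg <- temporal_diagnostics(st, c(1, 1), cfg)
  expect_equal(dg$I_k, c(4, 2))
  expect_equal(dg$Itilde_k, c(4, 3))
  # columns orthogonal: singular values are 4 and 2; sigma0 = 3 -> nu = 2
  expect_equal(dg$sigma1, 4, tolerance = 1e-10)
  expect_equal(dg$nu, 2, tolerance = 1e-10)
  expect_equal(dg$level_full, mean(c(4, 2)) * 4 / 2, tolerance = 1e-10)
  # constant stack: running mean constant
  stc <- image_stack(array(1, c(3, 3, 4)), 100, 50, 600, 1.49)
  dgc <- temporal_diagnostics(stc, c(1, 1),
                              musical_config(window_size = 3, soft_rms = 1e6,
                                             sigma0_rule = "fixed",
                                             sigma0_value = 0.5))
  expect_true(all(dgc$Itilde_k == dgc$I_k[1]))
  # rank-2 stack with a tiny threshold: only exactly-zero singular values
  # fall below it, so nu = 0 and the level is undefined
  dg0 <- temporal_diagnostics(st, c(1, 1),
                              musical_config(window_size = 3, soft_rms = 1e6,
                                             sigma0_rule = "fixed",
                                             sigma0_value = 1e-9))
  expect_true(dg0$undefined)
})

test_that("bleaching stack: whole-stack null level exceeds the trailing sub-stack level and debiasing adapts", {
  res <- fork_small_run()
  dg <- res$diagnostics
  trailing <- dg$substacks[nrow(dg$substacks), ]
  expect_gt(dg$level_full, trailing$level)
  # mean absolute gap to the per-substack levels, full vs debiased threshold
  gap_full <- gap_deb <- 0
  for (i in seq_len(nrow(dg$substacks))) {
    ks <- dg$substacks$first[i]:dg$substacks$last[i]
    gap_full <- gap_full + mean(abs(dg$level_full - dg$substacks$level[i]))
    gap_deb <- gap_deb + mean(abs(dg$level_debiased[ks] - dg$substacks$level[i]))
  }
  expect_lt(gap_deb, gap_full)
})
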
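#' End-to-end run configuration
#'
#' @param sim a [sim_config()].
#' @param loc a [localize_config()].
#' @param musical a [musical_config()].
#' @param sr_factor SR grid subdivision for LM rendering (matches the
#'   MUSICAL subpixel factor by default).
#' @param modes LM deposit modes to render.
#' @param seed master RNG seed for the run.
#' @return a `RunConfig` list.
#' @export
run_config <- function(sim = sim_config(), loc = localize_config(),
                       musical = musical_config(), sr_factor = musical$subpixel,
                       modes = c("count", "photons"), seed = 1L) {
  structure(list(sim = sim, loc = loc, musical = musical,
                 sr_factor = sr_factor, modes = modes, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Scaled-down fork preset
#'
#' The fork experiment at a desk-scale problem size: 2,000 frames on a
#' 24 x 24 px field, all photophysics parameters at their defaults. With
#' bleaching at 540 ms essentially every emitter has bleached within the
#' first 100 frames, so 2,000 frames capture the full bias phenomenology at
#' a fraction of the full acquisition's cost.
#'
#' @param seed RNG seed.
#' @param n_frames,img_shape overridable problem size.
#' @return a [run_config()].
#' @export
fork_preset_small <- function(seed = 1L, n_frames = 2000,
                              img_shape = c(24, 24)) {
  run_config(sim = sim_config(n_frames = n_frames, img_shape = img_shape,
                              seed = seed),
             loc = localize_config(threshold_c = 2),  # thorough search
             musical = musical_config(subpixel = 4),
             sr_factor = 4, seed = seed)
}

#' Run the synthetic fork experiment
#'
#' Simulates the fork stack, localizes it, renders original (count) and
#' debiased (photon) LM images, computes frame weights, runs original and
#' debiased MUSICAL, and writes all artifacts plus ground-truth maps, the
#' intensity histograms, an SSIM report and temporal diagnostics to
#' `out_dir`. Fully deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return invisible list with `stack`, `truth`, `locs`, `images` (named
#'   list of [sr_image()]s), `weights`, `report`, `diagnostics`.
#' @export
run_fork_experiment <- function(cfg = fork_preset_small(), out_dir = NULL) {
  set.seed(cfg$seed)
  sim <- cfg$sim
  sim$seed <- NULL  # master seed governs the whole run
  emitters <- make_fork_geometry()
  traces <- sample_traces(emitters, sim)
  stack <- render_frames(emitters, traces, sim)
  grid <- sr_grid(sim$img_shape, sim$pixel_size, factor = cfg$sr_factor)
  truth <- ground_truth_maps(emitters, traces, grid, sim)

  locs <- localize_stack(stack, cfg$loc)
  images <- list()
  for (m in cfg$modes) images[[paste0("lm_", m)]] <- render_lm(locs, grid, m)

  deb <- debias_stack(stack, "foreground_mean")
  images$musical <- musical_image(stack, cfg$musical)
  images$musical_debiased <- musical_image(stack, cfg$musical, deb$weights)

  report <- pairwise_report(images)
  junction <- round(colMeans(data.frame(
    x = emitters_to_px(emitters, sim)$x_px,
    y = emitters_to_px(emitters, sim)$y_px)))
  K <- sim$n_frames
  diag_cfg <- cfg$musical; diag_cfg$sigma0_rule <- "knee"
  diagnostics <- temporal_diagnostics(
    stack, junction, diag_cfg,
    substacks = list(c(1, ceiling(K / 8)), c(K - ceiling(K / 8) + 1, K)),
    weights = deb$weights)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stack(stack, file.path(out_dir, "stack.tif"))
    write_locs(locs, file.path(out_dir, "localizations.csv"))
    write_weights(deb$weights, file.path(out_dir, "weights.csv"))
    for (nm in names(images))
      write_sr_image(images[[nm]], file.path(out_dir, paste0(nm, ".tif")))
    write_sr_image(truth$event_map, file.path(out_dir, "truth_events.tif"))
    write_sr_image(truth$photon_map, file.path(out_dir, "truth_photons.tif"))
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "ssim_report.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(x_nm = emitters$x, y_nm = emitters$y,
                 segment_id = emitters$segment_id),
      file.path(out_dir, "emitters.csv"), row.names = FALSE)
    if ("lm_photons" %in% names(images))
      utils::write.csv(intensity_histogram(images$lm_photons, bins = 2000),
                       file.path(out_dir, "histogram_lm_photons.csv"),
                       row.names = FALSE)
    utils::write.csv(
      data.frame(k = seq_len(K), I_k = diagnostics$I_k,
                 Itilde_k = diagnostics$Itilde_k,
                 level_full = diagnostics$level_full,
                 level_debiased = if (is.null(diagnostics$level_debiased))
                   NA_real_ else diagnostics$level_debiased),
      file.path(out_dir, "diagnostics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, n_frames = sim$n_frames,
           img_shape = sim$img_shape, sr_factor = cfg$sr_factor,
           modes = cfg$modes, sigma0_rule = cfg$musical$sigma0_rule,
           sigma0_value = cfg$musical$sigma0_value,
           alpha = cfg$musical$alpha, n_localizations = nrow(locs),
           one_over_wk_range = range(deb$weights$one_over_w)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(stack = stack, truth = truth, locs = locs, images = images,
                 weights = deb$weights, report = report,
                 diagnostics = diagnostics))
}

#' Run the pipeline on an existing stack
#'
#' Same artifact set as [run_fork_experiment()] minus the ground truth:
#' localization, original/debiased LM rendering, frame weights,
#' original/debiased MUSICAL, SSIM report and temporal diagnostics for a
#' stack read from disk.
#'
#' @param cfg a [run_config()] (its `sim` field is ignored).
#' @param stack_path TIFF stack path, metadata in the JSON sidecar or
#'   supplied via `metadata`.
#' @param out_dir output directory or `NULL`.
#' @param metadata passed to [read_stack()].
#' @param diag_center `c(x, y)` window centre for diagnostics (defaults to
#'   the field centre).
#' @param substacks list of frame ranges for the diagnostics.
#' @return invisible list as in [run_fork_experiment()] (no `truth`).
#' @export
run_real_stack <- function(cfg, stack_path, out_dir = NULL, metadata = list(),
                           diag_center = NULL, substacks = NULL) {
  set.seed(cfg$seed)
  stack <- read_stack(stack_path, metadata)
  d <- dim(stack$data); K <- d[3]
  grid <- sr_grid(d[1:2], stack$pixel_size, factor = cfg$sr_factor)
  locs <- localize_stack(stack, cfg$loc)
  images <- list()
  for (m in cfg$modes) images[[paste0("lm_", m)]] <- render_lm(locs, grid, m)
  deb <- debias_stack(stack, "foreground_mean")
  images$musical <- musical_image(stack, cfg$musical)
  images$musical_debiased <- musical_image(stack, cfg$musical, deb$weights)
  report <- pairwise_report(images)
  if (is.null(diag_center)) diag_center <- floor(c(d[2], d[1]) / 2)
  if (is.null(substacks))
    substacks <- list(c(1, ceiling(K / 8)), c(K - ceiling(K / 8) + 1, K))
  diag_cfg <- cfg$musical; diag_cfg$sigma0_rule <- "knee"
  diagnostics <- temporal_diagnostics(stack, diag_center, diag_cfg,
                                      substacks = substacks,
                                      weights = deb$weights)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_locs(locs, file.path(out_dir, "localizations.csv"))
    write_weights(deb$weights, file.path(out_dir, "weights.csv"))
    for (nm in names(images))
      write_sr_image(images[[nm]], file.path(out_dir, paste0(nm, ".tif")))
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "ssim_report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, stack = normalizePath(stack_path),
           n_frames = K, n_localizations = nrow(locs),
           one_over_wk_range = range(deb$weights$one_over_w)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(stack = stack, locs = locs, images = images,
                 weights = deb$weights, report = report,
                 diagnostics = diagnostics))
}
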
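# smlmdebias

Single-molecule localization microscopy (LM) and the eigenimage-based
fluctuation method MUSICAL both mishandle frames whose signal-to-noise
ratio (SNR) drifts over an acquisition — as it always does under
photobleaching or buffer ageing. LM deposits one count per localization,
so dim, unreliable localizations from low-SNR frames weigh exactly as much
as bright ones and clutter the background; the usual countermeasure is a
set of heuristic retain-or-reject filters with user-chosen thresholds.
MUSICAL classifies eigenimages into signal and null subspaces at a
singular-value threshold, so the same low-SNR frames are pushed into the
null subspace and structures emitting late simply disappear.

`smlmdebias` implements automatic, non-heuristic corrections for both
biases, for microscopists and methods developers working with blinking
fluorophore stacks:

* **Debiased LM**: render each localization with its estimated photon
  count `psi = 2*pi*A*sigma_x*sigma_y` instead of a unit count
  (`render_lm(..., mode = "photons")`), with frame-mean, foreground-mean
  and inverse-variance (`1/Delta^2`, Thompson precision) variants, plus
  the classical heuristic filters for comparison.
* **Debiased MUSICAL**: weight frame `k` by the inverse mean foreground
  intensity `w_k = (sum_{r in F} I(r) / N_F)^-1` before the
  eigen-decomposition (`debias_stack()`, `musical_image()`), which
  equalizes foreground intensity across frames without touching any
  pixel's SNR.
* A complete supporting stack: Gaussian least-squares localizer with
  photon and precision estimates, windowed MUSIC pseudospectrum engine
  `(d_S/d_N)^alpha` with signal/null diagnostics, Otsu-on-log foreground
  detection, SSIM comparison, a blinking/bleaching fork-phantom simulator
  with ground-truth maps, and end-to-end workflows with a thin CLI
  (`inst/cli/smlmdebias.R`).

## Worked example

```r
library(smlmdebias)
cfg <- fork_preset_small(seed = 1, n_frames = 500, img_shape = c(20, 20))
res <- run_fork_experiment(cfg, out_dir = "fork_run")
```

This simulates the fork phantom (three 500 nm segments, 100 emitters each,
5 ms / 95 ms blinking, 540 ms bleaching, 1e5 photons/s, SBR 100, 50 fps),
localizes it, renders original (count) and debiased (photon) LM images,
computes the debias weights, runs original and debiased MUSICAL, and
writes all artifacts. Printing the pieces:

```
> res$stack
ImageStack: 500 frames of 20 x 20 px (100 nm/px, 50 fps, lambda 600 nm, NA 1.49)
> nrow(res$locs)            # localizations (thorough-search detector)
[1] 1606
> range(res$weights$one_over_w)
[1]   1.496 484.5
> as.data.frame(res$report)
      name_a           name_b         ssim
1   lm_count       lm_photons 0.4623161660
2   lm_count          musical 0.4455152137
3   lm_count musical_debiased 0.0077566650
4 lm_photons          musical 0.9372484405
5 lm_photons musical_debiased 0.0009161433
6    musical musical_debiased 0.0007824965
```

The `1/w_k` series spans 1.5 to 485: foreground intensity collapses by two
orders of magnitude as emitters bleach, which is exactly the regime where
debiasing matters. The SSIM table shows the signature cross-agreement:
debiased LM (`lm_photons`) resembles original MUSICAL (0.94) far more than
original LM does (0.45) — photon weighting and the eigenimage threshold
suppress the same low-SNR content from opposite directions. The temporal
diagnostics quantify MUSICAL's bias directly:

```
> res$diagnostics$level_full     # whole-stack null-portion level
[1] 50538
> res$diagnostics$substacks
  first last     Itilde      sigma1        nu        level
1     1   63 8316.38095 13875.59865 503.64822 229117.78475
2   438  500   52.20635    41.09103  36.68869     58.47069
```

Analysed on its own, the trailing sub-stack would need a threshold near
58; the whole-stack analysis imposes one near 50,000, relegating those
late frames almost entirely to the null subspace.

On this fully-bleached synthetic stack the *debiased* MUSICAL image
saturates (late frames carry no signal to equalize) — see the methods
vignette (`vignettes/debiasing-localization-and-musical.Rmd`) for this and
other limitations, and for every model, parameter and numerical choice.

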
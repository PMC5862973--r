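---
title: "Debiasing localization microscopy and MUSICAL: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Debiasing localization microscopy and MUSICAL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmdebias)
```

## The bias this package treats

Single-molecule localization microscopy (LM) and eigenimage-based
fluctuation analysis (MUSICAL) both reconstruct super-resolved images from
a temporal stack of frames of blinking fluorophores, and both treat the
temporal variation of the signal-to-noise ratio (SNR) poorly, in opposite
directions.

LM localizes emitters frame by frame and, conventionally, deposits **one
count** per localization on a sub-pixel grid. A localization fitted to a
dim, noisy blob in a low-SNR frame counts exactly as much as one fitted to
a bright, unambiguous emitter image: low-SNR frames are *over-represented*,
and spurious localizations accumulate as background clutter. The usual
remedy is a battery of heuristic retain-or-reject filters (axial ratio,
fitted width window, minimum fit height) with user-chosen thresholds.

MUSICAL decomposes the windowed pixels-by-frames matrix into eigenimages
and splits them into a signal and a null subspace at a singular-value
threshold $\sigma_0$. Bright frames dominate the leading eigenimages, so
whatever the threshold, the contribution of low-SNR frames is pushed into
the null subspace: those frames are *under-represented* and the structures
that only emit late (for example, after most fluorophores have bleached)
vanish from the reconstruction.

The package implements automatic, non-heuristic corrections for both
biases, plus the synthetic data generator, localizer, MUSICAL engine,
diagnostics and SSIM metrics needed to study them end to end.

## Models

### LM rendering

The LM image is $s(x,y) = \sum_k a_k(x,y)$ with $a_k(x,y) = b_k(x,y)$ if
frame $k$ holds a localization at $(x,y)$ and 0 otherwise, rasterized by
integrating over each super-resolution (SR) pixel $\Omega_p$. The deposit
rule $b_k$ distinguishes the modes of `render_lm()`:

| mode | deposit $b_k$ | meaning |
|---|---|---|
| `count` | $1$ | conventional LM |
| `photons` | $\psi_k(x,y)$ | debiased LM: estimated photons of the localization |
| `frame_mean` | mean frame intensity | frame-wise debiasing variant |
| `fg_mean` | mean foreground intensity | frame-wise variant, foreground only |
| `precision` | $1/\Delta^2$ (unit mean) | inverse-variance weighting by localization precision |

The photon estimate is the fitted Gaussian volume
$\psi = 2\pi A \sigma_x \sigma_y$ (background excluded), and the precision
is the Thompson-style estimate
$\Delta^2 = (s^2 + a^2/12)/\psi + 8\pi s^4 b^2/(a^2 \psi^2)$ with $s$ the
mean fitted width in nm, $a$ the pixel size and $b$ the fitted background.
Since $\psi$ rises with the local SNR, photon-weighted rendering
down-weights noise-driven localizations *continuously* instead of
rejecting rows by thresholds — the heuristic filters remain available in
`filter_localizations()` for comparison, and intensity-range segmentation
(`segment_intensity_range()`) exploits the wide, nearly continuous photon
scale of the debiased image.

### MUSICAL and its debiasing

For a soft window (side 7, Gaussian taper with RMS width 3 px by default)
the pixels-by-frames matrix is decomposed by SVD; eigenimages with
$\sigma_i > \sigma_0$ span the signal subspace. For a unit-normalized,
soft-weighted PSF vector $G$ at a sub-pixel test point, the pseudospectrum
is $(d_S/d_N)^\alpha$ with $d_S = \|P_S G\|$, $d_N$ the norm of the
residual to the signal subspace, and $\alpha = 4$ by default. The mass
relegated to noise is summarized by
$\nu = \sqrt{\sum_{\sigma_i \le \sigma_0} \sigma_i^2}$.

Debiasing multiplies every frame by
$w_k = \left( \sum_{r' \in F} I(r') / N_{r'} \right)^{-1}$,
the inverse mean intensity of the detected foreground $F$, before the
decomposition (`debias_stack()`). All pixels of a frame share one $w_k$,
so no pixel's SNR and no spatial structure changes — the frames merely
present comparable foreground intensity to the SVD, letting late, dim
frames reach the signal subspace. Variants using the whole-frame mean or
standard deviation are provided. The diagnostic series $1/w_k$
(`stack_weights()`) shows at a glance whether debiasing can matter: a flat
series means it reduces to a global rescaling, to which the
$\sigma_0 = 0.01\,\sigma_1$ rule is invariant.

### Foreground detection

The foreground is found per frame by thresholding $\log(1+I)$ with the
two-class between-variance (Otsu) criterion on a 256-bin histogram — the
log transform makes the background/foreground split of fluorescence frames
approximately bimodal. A constant frame has no split and returns an empty,
flagged foreground; `frame_weight()` then falls back to the whole-frame
mean with a warning.

### Temporal diagnostics

`temporal_diagnostics()` reports, for one analysis window, the per-frame
window intensity $I_k$, its running mean $\tilde I_k$, and the
null-portion level $\tilde I \sigma_1/\nu$ for the whole stack and for
temporal sub-stacks ($\sigma_1, \nu$ recomputed per sub-stack). On a
bleaching stack the whole-stack level towers over the level of a trailing
sub-stack — the quantitative signature of MUSICAL's bias against late
frames. With debias weights the level $\tilde J \sigma_1/(\nu w_k)$,
expressed in original-frame units, adapts to the sub-stack levels. For
these per-(sub)stack thresholds the simplified knee rule (below) is the
natural $\sigma_0$ choice and is used by the workflow functions.

## The synthetic data generator

`make_fork_geometry()` builds the fork phantom: a 500 nm stem and two
500 nm prongs separated by 30°, each carrying 100 emitters placed uniformly
at random. The fork combines a dense junction with sparse open ends, the
two regimes in which the LM and MUSICAL biases behave differently.
`sample_traces()` simulates, per emitter, a continuous-time on/off
telegraph process (mean on 5 ms, mean off 95 ms, i.e. 5% duty cycle),
photobleaching with time constant 540 ms, and per-frame photon counts
drawn as Poisson with mean (photon rate 1e5/s) x (on-time overlap with the
frame exposure). `render_frames()` spreads photons with the
pixel-integrated Gaussian PSF ($\sigma = 0.21\lambda/\mathrm{NA}$,
defaults $\lambda$ = 600 nm, NA 1.49, 100 nm pixels), adds a uniform
background fixed by the signal-to-background ratio (default 100) and
applies Poisson shot noise to signal plus background.

Choices worth knowing:

* **Duration law.** On/off durations are exponential with the stated means
  (the standard memoryless telegraph model); a discretized Poisson
  alternative with a 1 ms quantum (`duration_law = "poisson_ms"`) has the
  same means and is available for comparison.
* **Bleach modes.** `"memoryless"` (default) draws the bleach time from an
  exponential law with mean `tau_bleach`, so the survival fraction is
  exactly $\exp(-t/\tau)$ — this is what "time constant of bleaching"
  ordinarily means, and it is what the acceptance script recovers by
  fitting the empirical log-survival curve. `"literal"` applies, before
  every frame at elapsed time $t$, an independent uniform draw compared
  against $\exp(-t/\tau)$; the compounding of per-frame checks makes
  survival super-exponential (much faster than $\exp(-t/\tau)$). Both are
  provided because per-frame re-checking is how simple simulators are
  often written; tests pin the qualitative difference.
* **SBR definition.** There is no universal convention; here SBR = (mean
  noiseless signal over foreground pixels, i.e. pixels within
  $2\sigma_{\rm PSF}$ of an emitter, averaged over frames with at least
  one active emitter) / (uniform background level).
* **Geometry and exposure.** The prongs are symmetric about the stem axis,
  emitters start in the stationary on/off state, and frames integrate with
  a 100% duty cycle.
* **Ground truth.** `ground_truth_maps()` bins per-emitter emission-event
  counts and total emitted photons on the SR grid — the references for
  count-mode and photon-mode LM respectively.

What the generator does *not* emulate: stage drift, dipole orientation,
astigmatic/3-D PSFs, structured background, sCMOS pixel noise maps, and
multi-emitter fitting scenarios beyond what Poisson blinking produces.
Tests passing on this generator therefore validate the algorithms under
idealized photophysics; they do not by themselves establish performance on
real acquisitions.

## Numerical choices

* **$\sigma_0$ scope.** With the fraction rule
  $\sigma_0 = 0.01\,\sigma_1$, $\sigma_1$ is by default the largest
  singular value of the *whole* stack matrix (`sigma0_scope = "global"`).
  Taking $\sigma_1$ per window instead places the threshold below the
  noise floor in windows that hold only background (every component then
  counts as signal and the pseudospectrum saturates there); the per-window
  variant remains available for experimentation. The global value is
  computed by power iteration.
* **$d_N$ floor.** $d_N$ is the residual norm after projecting $G$ on the
  signal subspace and is floored at `eps = 1e-8`. Residual norms below
  that are indistinguishable from SVD rounding noise, so a smaller floor
  would report irreproducible capped values; at `1e-8` the worst-case
  relative error of $(d_S/d_N)^4$ is about $10^{-6}$, and a window whose
  signal subspace spans the whole pixel space yields the deterministic cap
  exactly.
* **Windows and stitching.** Windows are centred on every acquisition
  pixel and zero-padded at borders, so the full field is covered. The PSF
  vector is point-sampled at pixel centres, soft-weighted and
  unit-normalized. Each window scores all SR test points in its footprint;
  overlapping windows are averaged with the soft-window value at the test
  point as stitching weight.
* **Simplified knee rule.** `knee_sigma0()` places $\sigma_0$ at the point
  of maximum perpendicular distance from the chord of the log
  singular-value curve. This is a deliberately simple stand-in for more
  elaborate knee criteria and is labelled `simplified_knee` in its output.
* **Localizer.** Candidates are local maxima above median + c MAD (c = 4
  by default; c = 2 is the permissive "thorough search" preset used by the
  fork workflow), fitted with unweighted least squares on a 7x7 ROI,
  initial widths 1.5 px, at most 10 iterations, relative tolerance 1e-3.
  Duplicate fits within 0.5 px in one frame keep the lower residual.
  Invalid fits are kept in the table, flagged, so filter studies can see
  them.
* **SSIM.** 11x11 Gaussian window ($\sigma$ = 1.5), reference constants
  $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$, valid-mode filtering, and
  independent min-max normalization of both images (reconstructions from
  different algorithms are in incommensurate units). The implementation
  matches the reference implementation to ten decimals on a frozen
  fixture.
* **Stack storage.** Multi-page 32-bit float TIFF scaled into [0, 1], with
  the scale and acquisition metadata in a JSON sidecar; round-trips are
  exact to float32 precision.

## Problem sizes used by the test-suite

The full study conditions (10,000 frames) are unnecessary for exercising
the phenomenology: with a 540 ms bleach constant, virtually all emitters
have bleached within the first 100 frames. The packaged scaled-down
preset (`fork_preset_small()`) therefore uses 2,000 frames on a 24 x 24 px
field with a subpixel factor of 4, which retains the full bias/debias
contrast (a long post-bleach epoch of low-SNR frames) at desk scale.
Statistical checks of the generator use at least 1e4 draws per parameter;
the acceptance script recovers the bleach constant from 10,000 emitters
simulated at the full 10,000-frame acquisition length.

## Known limitations

* Debiased MUSICAL assumes every frame still carries *some* signal. On a
  stack whose late frames are pure background (as after complete
  photobleaching), the weights amplify those frames' noise; the weighted
  stack becomes noise-dominated and the debiased pseudospectrum saturates
  at the $d_N$ cap. This mirrors the method's stated domain — debiasing
  MUSICAL is useful when foreground intensity varies but persists — and is
  visible in the packaged fork preset's `musical_debiased` image.
* Pseudospectrum images have an enormous dynamic range; SSIM values
  involving them depend strongly on the min-max normalization convention
  and should be compared only across images produced under the same
  convention.
* The localizer is a single-emitter least-squares fitter; overlapping
  emitters at the fork junction produce the characteristic
  mislocalizations that photon weighting then emphasizes. Multi-emitter
  fitting is out of scope.
* `read_stack()` trusts its input to be photon-calibrated; only a linear
  gain/offset correction is offered.

## A minimal session

```{r example, eval = FALSE}
cfg <- fork_preset_small(seed = 1, n_frames = 500, img_shape = c(20, 20))
res <- run_fork_experiment(cfg, out_dir = "fork_run")
res$report                      # pairwise SSIM table
res$diagnostics$level_full      # whole-stack null-portion level
res$diagnostics$substacks       # per-sub-stack levels
range(res$weights$one_over_w)   # 1/w_k spread; flat means debiasing is moot
```
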
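---
title: "Quantifying biomolecular condensates: models, estimators and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biomolecular condensates: models, estimators and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condenser)
```

This vignette is the package's own account of the measurements it
implements: what each statistic estimates, the assumptions behind it, the
tunable parameters and their defaults, what the synthetic generators emulate
(and deliberately do not), and where the numerical choices were genuinely
open. No empirical claim here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The measurement problem

A protein that undergoes liquid–liquid phase separation coexists as a dense
phase (micrometre-scale condensates) and a dilute phase. Three image
statistics summarise a two-phase field of view:

- the **separation factor**, the percent of total fluorescence in the
  condensed phase: `100 · Σ I(condensate px) / Σ I(all px)`, a measure of
  how much protein has demixed;
- the **client enrichment**, `mean(I inside) / mean(I outside)` of a second
  ("client") channel over condensates segmented on the scaffold channel — an
  image-level estimate of the client's dense/dilute partition ratio;
- the **image CV** (SD/mean), which rises when a fixed amount of
  fluorescence concentrates into fewer structures, and therefore serves as a
  bundling metric for filament images.

Downstream, FRAP kinetics report molecular exchange between a structure and
its surroundings, per-cell accounting tracks how clusters scale and
partition over the cell cycle, and a coupled-enzyme absorbance assay
measures GTPase activity of the client.

## Segmentation and screening

Condensates are segmented deterministically: Gaussian smoothing
(`smooth_sigma`, default 1 px), thresholding at the image median plus
`k_seg` (default 3) robust SDs (MAD), 8-connected component labeling, and an
optional distance-transform watershed for touching objects. The median/MAD
pre-estimate keeps bright objects from inflating the threshold.

A global threshold a few SD above background admits the dim halo that the
point-spread function smears around every bright object; that halo biases
within-condensate means downward. The default boundary refinement
(`refine = "halfmax"`) therefore trims each detected object to pixels above
half-maximum between the background level and the object's 95th-percentile
peak — the tight-boundary behaviour of the star-convex deep-learning
segmenters typically used for this task, without model weights or
nondeterminism. Externally produced label maps can be passed straight to
`screen_condensates()`, so a trained segmenter can replace the built-in one
behind the same interface.

Screening then removes objects with fewer than `min_area_px = 9` pixels or a
mean intensity below `background mean + k·SD` with `k = 3`. Both removals
are strict inequalities: objects exactly at a threshold are retained. The
"intensity" screened is the object's **mean** (the definition most
consistent with the enrichment statistics); the background is all pixels
outside the label map, with no dilation buffer. All image SDs in the package
use the population convention (divisor *n*); for full images the difference
from *n*−1 is negligible, but a fixed convention makes hand-computed
oracles exact.

By convention the separation factor is computed on the maximum intensity
projection of a z-stack, while enrichment uses the best-focus slice — the
slice with maximal intensity SD, ties broken to the lowest index — because
projections mix in out-of-focus client signal that the within-slice ratio
should not see.

## Enrichment, bleedthrough and labeling corrections

Raw enrichment divides the mean client intensity inside condensates by the
mean over the remaining field of view. Two corrections matter in practice:

- **Bleedthrough**: the scaffold fluorophore leaks into the client channel.
  The correction subtracts the raw enrichment of a *no-client control*
  (same imaging, no client added) from the measured raw enrichment. This is
  a first-order correction that behaves well when the control's enrichment
  is close to 1 (low bleedthrough over a nonzero channel background), which
  is the regime the assay is designed for.
- **Degree of labeling**: two clients carrying different average numbers of
  dye molecules per protein would differ in apparent enrichment by
  `DOL_a / DOL_b` even with identical partitioning.
  `expected_labeling_ratio()` computes that fold so an observed enrichment
  difference can be compared against the labeling-only expectation.

The within-condensate CV of the client channel (SD/mean over condensate
pixels) is reported alongside as a heterogeneity measure.

## FRAP normalization and fitting

For in vivo FRAP the package uses double normalization: background-corrected
ROI intensity divided by background-corrected whole-cell intensity, then
scaled so the mean of the pre-bleach frames is exactly 100. Any
multiplicative, frame-wise acquisition photobleaching shared by ROI and
whole-cell signals cancels *identically* in the ratio — this is an algebraic
property, and the test suite verifies it numerically to below 1e−10. The
in vitro mode (no whole-cell reference available for a condensate field)
anchors the background-corrected ROI alone to a pre-bleach mean of 100, and
does not cancel acquisition bleaching; the pre-bleach anchor is the mean of
all pre-bleach frames.

Recovery is fitted on post-bleach points only with the single exponential
`y = y0 + A·e^(−x/t)` (A < 0 for recovery), giving `t½ = t·ln 2`.
Initialization is deterministic: `y0` from the mean of the last 10% of
points, `A` from the first post-bleach point minus `y0`, `t` from the first
crossing of `y0 + A/e` (falling back to half the time span), with `t`
bounded in `(0, 100 × span]`. There are no random restarts, so fitting is a
pure function of the data. A flat series makes `t` unidentifiable and is
returned as `converged = FALSE` with a note, not an error. The immobile
fraction `(100 − y0) / (100 − y0 − A)` is reported as a derived convenience
metric; it is not part of the source analyses this package reimplements.

Aggregation resamples each event's normalized trace onto the common
post-bleach grid by linear interpolation and reports the per-timepoint mean
± SD plus a fit of the mean curve. Linear resampling of an exponential
introduces a small curvature error (≈0.2% in `t` at the default grid), which
is why pooled-vs-individual equality is asserted at 1% in the tests.

## Per-cell accounting and division conservation

`measure_cell()` decomposes a cell's background-corrected fluorescence into
cluster and cytoplasm parts that add up exactly (intensity and area), and
derives fluorescence concentrations (intensity per area — the standard
image proxy for protein concentration) and the enrichment factor
cluster/cytoplasm. The background is a per-image scalar, the mean outside
all cell masks. Cell outlines and lengths are inputs: outline extraction
from phase-contrast data is a separate, solved problem and out of scope.

Cluster geometry uses intensity-unweighted mask moments: axis lengths are
`4·√eigenvalue` of the pixel covariance with a +1/12 unit-square correction,
so a 20 × 5 px rectangle has aspect ratio exactly 4 and a one-pixel-wide
mask has a finite short axis. Because the estimator the original SIM-based
measurements used is not recorded, mask-moment axes should be compared
between conditions measured the same way, not against published absolute
values.

Division conservation compares one pre-division frame with one
post-division frame: the summed background-corrected daughter cluster
intensity as a percent of the mother's cluster intensity, and the same for
total cellular intensity. Cluster **fission** conserves the cluster
statistic; cluster **disintegration** zeroes it while the total statistic is
conserved as diffuse signal. In the division generator the cluster footprint
carries the cluster signal alone (the diffuse level is replaced, not
supplemented, inside it); otherwise "cluster intensity" would conflate the
cluster with the cytoplasm beneath it and the conservation fraction would
not be identifiable from the rendered images.

## GTPase rates

In the NADH-coupled assay, each GTP hydrolysis event consumes one NADH, so
the A340 slope converts to a hydrolysis rate by Beer–Lambert:
`rate = −slope / (ε·l)`, with defaults `ε = 6220 M⁻¹cm⁻¹` and
`l = 0.248 cm` (overridable for other instruments). A no-enzyme control
trace — spontaneous GTP hydrolysis plus UV-induced NADH decomposition — is
subtracted pointwise (interpolated if on a different grid) before fitting.

The fit window is explicit and logged. The default selects the contiguous
window (20 min) with maximal |slope|, which skips lag phases; because a
maximum over windows is selected, this carries a small upward selection bias
when noise is comparable to the per-window slope uncertainty. For clean
steady-state kinetics, pass a fixed `window = c(t_start, t_end)` — the
package's own unbiasedness tests do. A significantly positive corrected
slope (> 3 SE) is flagged as an assay artifact rather than silently
converted to a negative rate.

## What the generators emulate — and what they do not

All generators are pure functions of their parameters and seed, and every
exported truth value is computed from the noiseless, pre-blur object model,
never re-estimated from the rendered image.

- **Condensate scenes**: hard discs/spheres of uniform dense intensity over
  a uniform dilute phase, client channel with a fixed partition ratio plus a
  `β`-scaled copy of the scaffold channel (bleedthrough), isotropic Gaussian
  PSF (kernel normalized to sum 1, so noiseless blur conserves total
  intensity), then Poisson photon noise and additive Gaussian read noise
  (clamped at zero) — the standard fluorescence-camera model. Placement is
  sequential rejection sampling (cap 10,000 attempts) so adding an object
  never perturbs earlier ones. Defaults: 207.6 nm/px (a 106.3 µm field at
  512 × 512), PSF σ = 100 nm (from confocal optics: lateral
  FWHM ≈ 0.4·λ/NA ≈ 200 nm at λ ≈ 580 nm, NA 1.2), radii 500–1100 nm
  (micrometre-scale condensates), dense:dilute 10:1, 50 photons per
  intensity unit, read σ = 0.5.
- **Filament scenes**: smoothed random walks of fixed integrated intensity;
  with probability `b` a path collapses onto one of k shared centerlines.
  This reproduces the *statistical* signature of bundling (CV increasing in
  `b` at fixed total intensity) without any polymer physics. With a single
  path, `b` is ignored — bundling is a multi-path property.
- **FRAP series**: exponential recovery `r(t)` multiplied by a decaying
  whole-cell signal, plus background offsets and Gaussian noise. The decay
  is exactly multiplicative and shared, matching the assumption double
  normalization relies on.
- **Division events** and **cell snapshots**: rectangular rod cells,
  elliptical clusters, linear axis scaling with length, constant
  fluorescence concentration (total = κ·area). Realistic cell shapes,
  lineages and focus drift are not modelled.
- **Absorbance traces**: exactly linear A340 decrease plus Gaussian noise,
  with a depletion check (an error names the time at which A340 would cross
  zero).

Passing tests on these scenes demonstrate that the estimators are correct
*given their model assumptions* — uniform phases, known PSF, exponential
recovery, linear kinetics. They do not show robustness to out-of-focus
haze, intra-condensate structure, non-exponential recovery from diffusion
coupling, or instrument drifts; on real data those remain the analyst's
responsibility.

## Numerical choices and degenerate inputs

- Thresholding uses strict `>` so a zero-variance image yields an empty
  label map (no objects), not an error; screening boundaries are inclusive.
- Coordinates are pixel-centre, (row, col); connectivity is 8-connected.
- `fit_frap_recovery()` needs ≥ 5 post-bleach points;
  `hydrolysis_rate()` ≥ 10 points in the window;
  `estimate_background()` enforces a configurable floor of background
  pixels.
- Test and acceptance problem sizes — 96–128 px scenes, 20-seed loops, 200
  simulated FRAP events, 50 division events — keep the full suite in the
  tens of seconds while leaving Monte-Carlo error well inside the asserted
  tolerance bands.

## Known limitations

Objects are quantified in 2-d (projection or slice), as in the analyses
this package reimplements; there is no 3-d segmentation. The bleedthrough
correction is first-order subtraction of a control's enrichment, valid for
small bleedthrough over a nonzero channel background. The separation factor
deliberately applies no background subtraction; an image with substantial
dilute-phase signal therefore has a nonzero floor. Enrichment estimates
carry a small downward bias (order of a few percent at the default PSF)
because the blur dilutes the inside mean relative to the pre-blur truth —
visible in the acceptance output as `corrected_enrichment_mean_rel_err`.
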
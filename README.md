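# condenser

Quantification of biomolecular condensates and related assays from
fluorescence microscopy and plate-reader data, in R.

Bacterial cell-division regulators and many other proteins form
membraneless, protein-dense assemblies (biomolecular condensates) by
liquid–liquid phase separation. Characterising them quantitatively requires
a recurring set of measurements that this package implements as a tested,
reusable pipeline:

- **Separation factor** — the percentage of total image fluorescence inside
  segmented condensates, `100 · Σ I(condensates) / Σ I(image)`, computed on
  maximum intensity projections after screening objects smaller than 9 px or
  dimmer than background + 3 SD.
- **Client enrichment** — `mean(I inside) / mean(I outside)` of a client
  channel over condensates segmented on the scaffold channel (best-focus
  slice), corrected by subtracting a no-client bleedthrough control's
  enrichment, with the within-condensate CV as a heterogeneity metric and a
  degree-of-labeling fold (`DOL_a / DOL_b`) to rule out labeling artifacts.
- **Bundling CV** — SD/mean of a filament image as a bundling metric,
  normalized to a reference condition.
- **FRAP** — in vivo double normalization
  `(ROI − bg) / (cell − bg)` (cancels acquisition photobleaching exactly),
  pre-bleach anchored to 100%, fitted with `y = y0 + A·e^(−x/t)`;
  `t½ = t · ln 2`; per-event and pooled (mean-curve) fits.
- **Cell-cycle accounting** — per-cell background-corrected intensities,
  fluorescence concentrations (intensity/area), cluster/cytoplasm enrichment
  factors, cluster-axis vs cell-length regression, division conservation
  (daughter/mother intensity percentages distinguishing cluster fission from
  disintegration), cluster counting, constriction–cluster colocalization.
- **GTPase rates** — NADH-coupled assay traces: control subtraction, linear
  slope, Beer–Lambert conversion with ε₃₄₀ = 6220 M⁻¹cm⁻¹ and
  l = 0.248 cm; GTP hydrolysis rate = NADH oxidation rate (1:1 coupling).

Every estimator is paired with a synthetic-data generator
(`simulate_condensate_scene()`, `simulate_filament_scene()`,
`simulate_frap_series()`, `simulate_division_event()`,
`simulate_cell_snapshots()`, `simulate_absorbance_trace()`) that exports the
ground truth it was built from, so the whole pipeline is testable without
external data.

## Worked example

```r
library(condenser)

cfg <- scene_config(c(128, 128), seed = 1)   # 207.6 nm/px, PSF + camera noise
sim <- simulate_condensate_scene(cfg, n_objects = 12, client_partition = 5)

mip  <- max_intensity_projection(sim$scene, "condensate")
cset <- screen_condensates(segment_condensates(mip), mip)
separation_factor(mip, cset)
#> # A tibble: 1 × 4
#>   separation_factor integrated_in integrated_total n_objects
#>               <dbl>         <dbl>            <dbl>     <int>
#> 1              23.5         4997.           21301.        12
sim$truth$true_separation_factor
#> [1] 25.01773
```

About a quarter of the scaffold fluorescence sits in the condensed phase;
the pipeline estimate is within ~1.5 percentage points of the generator's
ground truth under the default imaging conditions. Enrichment on the
best-focus slice, FRAP fitting and the other stages chain the same way:

```r
z   <- best_focus_slice(sim$scene, "condensate")
sl  <- get_plane(sim$scene, "condensate", z)
cs2 <- screen_condensates(segment_condensates(sl), sl)
client_enrichment(get_plane(sim$scene, "client", z), cs2)

frap <- simulate_frap_series(tau = 3, noise_sigma = 2)
fit  <- fit_frap_recovery(normalize_frap_trace(frap$trace, "in_vivo"))
glance(fit)
#> # A tibble: 1 × 7
#>      y0     A     t t_half   rss converged n_points
#>   <dbl> <dbl> <dbl>  <dbl> <dbl> <lgl>        <int>
#> 1  90.9 -60.1  3.08   2.13  275. TRUE            41
```

`t_half ≈ 2.13 min` against a ground truth of `3 · ln 2 ≈ 2.08 min`.
Reproducible batch runs go through JSON configs:
`run_stage(load_run_config("config.json"))` writes stage outputs plus a
`manifest.json` (hashed inputs, parameters, seed, version).

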
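# nucleodyn

Immune cells migrating through living tissue must push their stiffest
organelle — the nucleus — through spaces that can be narrower than the
nucleus itself. In the maturing *Drosophila* wing, hemocytes
(insect leukocytes) move first through open extracellular space and
later through vessel-like channels, and their nuclei respond with
repeated, reversible squeezing deformations. nucleodyn is an R package
for quantifying that nuclear plasticity from time-lapse fluorescence
microscopy: it segments labelled nuclei in 4D stacks, tracks them,
reduces every track to shape and migration statistics, and adds the
companion fluorescence-intensity and vessel-geometry analyses. Because
studies of this kind rarely deposit raw movies, the package ships a
seeded synthetic-movie generator with exact ground truth, so the whole
chain is testable end to end.

## The measurements

**Shape factor (SF).** For each nucleus's 2D maximum projection, the
central second-order area moments give equivalent-ellipse semi-axes
*a* ≥ *b* (eigenvalues λ of the inertia tensor, axis = 2√λ). The shape
factor

&nbsp;&nbsp;&nbsp;&nbsp;SF = (a − b) / (a + b)

is 0 for a round nucleus and approaches 1 with elongation
(`sf_formula = "aspect_ratio"` switches to 1 − b/a, with the squeezing
threshold remapped via `sf_threshold_for()`).

**Squeezing events.** A nucleus is squeezing in a frame when
SF ≥ 0.4. Events are maximal runs of consecutive squeezing frames;
per track the package reports the squeezing proportion, event count
and mean event duration.

**Migration.** Mean instantaneous speed (µm/min), and path length,
Euclidean distance and persistence (Euclidean/path) standardised to a
15-min window.

**Intensity.** Background-corrected lamina rim intensities normalised
to an epithelial reference, median-based A-type/B-type lamin
stoichiometry ratios relative to a reference age, 3D nuclear means
with negative-control correction, phagosome counts, and nuclear
instability rates.

**Vessels.** Wall-to-wall diameters from intensity profiles
(sub-pixel peak refinement), vessel dilation during nuclear transit
(D_during/D_pre), and residual space (D_during − D_nucleus).

## Worked example

Simulate a 20-min vessel movie (40 frames at 30 s), run the full
pipeline (train classifier → segment → track → filter → measure →
summarise → heatmap), and inspect the per-track statistics:

```r
library(nucleodyn)

cfg <- pipeline_config(regime = "vessel", n_nuclei = 3, n_frames = 40,
                       seed = 7)
res <- run_pipeline(cfg, "demo_out")
res$summaries[, c("track_id", "mean_sf", "max_sf", "squeeze_prop",
                  "n_events", "mean_event_min", "mean_speed_um_min",
                  "persistence")]
#> # A tibble: 3 × 8
#>   track_id mean_sf max_sf squeeze_prop n_events mean_event_min mean_speed_um_min
#>      <int>   <dbl>  <dbl>        <dbl>    <int>          <dbl>             <dbl>
#> 1        1   0.394  0.686        0.375        5          1.5                2.09
#> 2        2   0.274  0.694        0.1          2          1                  1.97
#> 3        3   0.290  0.636        0.1          3          0.667              2.03
#>   persistence
#>         <dbl>
#> 1       0.500
#> 2       0.493
#> 3       0.579
```

Each row is one tracked nucleus over 20 min: track 1 spent 37.5% of
its frames squeezing across 5 events averaging 1.5 min, while moving
at ~2 µm/min — the generator's vessel regime produces exactly this
mix of round baseline and episodic elongation. `demo_out/` now holds
`tracks.csv` (per-frame schema: `track_id, frame, time_s,
nucleus_label, x_um, y_um, z_um, area_um2, sf, circularity,
min_feret_um, max_feret_um, gap`), `summaries.csv`, `heatmap.tif` +
`heatmap_counts.tif`, `labels.tif`, a `config.yaml` snapshot and a run
log; rerunning with the same config and seed reproduces the CSVs
byte-for-byte.

Event detection can also be used directly on any SF series:

```r
series <- simulate_sf_series(synth_regime("vessel"), n_frames = 40,
                             seed = 7)
ev <- detect_squeezing(series$sf, threshold = 0.4, frame_interval_s = 30)
ev$events
#> # A tibble: 3 × 4
#>   start_frame end_frame n_frames duration_min
#>         <int>     <int>    <int>        <dbl>
#> 1           2         2        1          0.5
#> 2          13        14        2          1
#> 3          17        24        8          4
ev$proportion
#> [1] 0.275
```

`autoplot()` methods are provided for movies (ground-truth SF traces),
correlation matrices and SF heatmaps; `tidy()`/`glance()` methods
return the underlying tibbles. A thin command-line wrapper with
`simulate`, `train`, `segment`, `track`, `summarize`, `heatmap`,
`intensity`, `vessel` and `run` subcommands lives at
`inst/cli/nucleodyn.R`.

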
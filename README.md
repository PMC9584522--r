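# plumetrics

Quantification of feather primordia patterning and dermal cell-shape
anisotropy in developing bird skin.

During avian skin development, dermal cells condense into feather
primordia — bright spots in stained skin that form rows (chicken, quail,
zebra finch) or 2D arrays (emu, ostrich, penguins). Two readouts
characterize the process, and this package computes both, plus the
time-lapse machinery to follow them in living explants:

* **Pattern fidelity** — the regularity of primordia spacing,
  `sd(neighbour distances) / mean`, for first-row patterns (consecutive
  centers) and arrays (Delaunay-edge neighbours, edges touching the
  convex-hull boundary excluded).
* **Cell-shape anisotropy** — segmentation-free, per interrogation box
  (25 × 25 µm, 50% overlap by default): the box spectrum is binarized to
  its 5% brightest pixels, the inertia matrix of the retained set is
  diagonalized, and the amplitude is
  `a = (1/2) ln(L_maj / L_min) = (1/4) ln(λ1 / λ2)` — zero for isotropic
  texture — with a nematic orientation in [0°, 180°).
* **Time-lapse analysis** — drift registration (phase correlation),
  automatic detection of the competent segment (the 3 adjacent grid
  columns of maximal mean anisotropy) and of inter-primordium/primordium
  regions (4-box extrema, 3×3 blocks for velocimetry), particle image
  velocimetry with a 2-px median pre-filter and 3×3 median outlier test,
  velocity divergence (negative = condensation), 30-frame moving-average
  smoothing with t_ref alignment, and antero-posterior primordia tracking
  with fusion events.
* **Synthetic data** — textures with closed-form planted anisotropy
  ((1/2) ln rho), point patterns with tunable spacing CV, blob images
  with planted detection truth, and time-lapse stacks advected by
  uniform / random-walk / sink flows at 5-min intervals. Every stage of
  the pipeline is tested against this planted ground truth.

## Worked example

Measure the anisotropy of a texture with a planted stretch of rho = 2
along the 90° axis, then spacing statistics for planted point patterns:

```r
library(plumetrics)

scene <- scene_spec(width_px = 256, height_px = 256, pixel_size_um = 1,
                    texture_stretch_ratio = 2, texture_angle_deg = 90,
                    correlation_length_um = 1.5, seed = 42)
frame <- generate_texture(scene)
grid  <- make_grid(frame, box_size_um = 64, overlap_fraction = 0.5)
map   <- anisotropy_map(frame, grid)
avg   <- average_anisotropy(map)
# mean amplitude: 0.348 (theory (1/2)ln 2 = 0.347)
# mean angle: 89.5 deg (planted 90)
```

The measured amplitude matches the Fourier scaling prediction
`(1/2) ln rho` and the orientation recovers the planted axis.

```r
pp <- generate_point_pattern(pattern_spec("row", n_primordia = 12,
                                          mean_spacing_um = 100,
                                          spacing_cv = 0.15, seed = 1))
row_spacing_variability(pp$centers)
#> <spacing_stats> n = 11 edges, mean = 103.86 um, sd = 12.74 um,
#>                 spacing variability = 0.1227
pp$realized_cv   # ground truth carried by the generator: 0.1227

arr <- generate_point_pattern(pattern_spec("hex_array", 60, 100, 0.1,
                                           seed = 2))
delaunay_spacing_variability(arr$centers)
#> <spacing_stats> n = 123 edges, mean = 103.00 um, sd = 22.77 um,
#>                 spacing variability = 0.2210
```

The row statistic reproduces the generator's realized coefficient of
variation exactly (both are computed from the same planted gaps); the
array statistic uses only interior Delaunay edges, so border primordia do
not inflate the spacing spread.

A command-line interface wraps the same functions
(`inst/scripts/plumetrics-cli.R` with subcommands `simulate`,
`anisotropy`, `pattern`, `timelapse`, `retract`); the methods vignette
(`vignettes/quantifying-skin-patterning.Rmd`) documents the model,
parameter defaults and numerical choices.

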
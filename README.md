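# mitonet3d

Quantification of 3D mitochondrial networks and membrane-potential dye
signal from live-cell confocal z-stacks.

Live cells stained with a cationic mitochondrial dye (TMRM, CMXRos, JC-1)
and imaged as a confocal z-stack carry both structural information — the
shape and connectivity of the mitochondrial network — and functional
information, because dye accumulation tracks the inner-membrane potential
ΔΨm. `mitonet3d` is for cell biologists who want to turn such stacks into
numbers: object counts, volumes, intensities, size-class profiles, and, for
repeated imaging of the same field, a quantitative photostability summary
of the dye/microscope combination.

## What it computes

**Segmentation and morphometry.** A mitochondrial-channel stack is filtered
(3D median, then white top-hat with an anisotropy-corrected ellipsoidal
element), thresholded at a constant value, and labelled into 26-connected
objects. Per object: voxel count, volume `v = n · dz·dy·dx` (µm³), mean and
total intensity (measured on the unfiltered stack), and a size class —
small (< 2 µm³, fragmented), medium (2–10 µm³), or network (> 10 µm³). Per
cell, using Hoechst (nucleus) and Calcein-AM (whole cell) channels:

```
cytoplasm volume  = cell volume − nucleus volume
% mt / cytoplasm  = 100 · Σ object volumes / cytoplasm volume
```

with hole filling for intracellular vacuoles and the nuclear mask
intersected with the cell mask so the subtraction cannot go negative.
Groups of cells are summarised as mean ± SD per field.

**Photostability.** For 10 consecutive volumes of one field, mean
intensities of 3–5 rectangular ROIs (100–150 µm²) are measured on maximum
intensity projections and normalised to each ROI's first acquisition. The
relative intensity `y` is modelled by Gaussian maximum likelihood with
joint location and dispersion,

```
y ~ N( α + β·t , exp(γ + δ·t) ),   t ∈ [0, 1] over the series,
```

so β is the relative signal change over the whole series (β = −0.14 means a
14% loss). Constant-location and constant-dispersion submodels are fitted
too, and compared by `AIC = −logL + k` (minimised minus log-likelihood plus
the number of estimated parameters; smaller wins, ties go to the simpler
model). A photostable combination is one where the constant-location model
wins — the best fit is a horizontal line.

**Synthetic data.** `simulate_cell()` / `simulate_series()` render
three-channel stacks (tubular + globular objects, diffuse background, PSF
blur, Poisson + Gaussian noise) with exact voxel-level ground truth, so the
entire pipeline is testable without microscope data.

## A worked example

```r
library(mitonet3d)

# a synthetic mesoangioblast-like cell with 30 planted objects
sim <- simulate_cell(validation_cell_params(seed = 1))
res <- quantify_cell(sim$channels, validation_config(), cell_id = "phantom1")
res$quant
#> # A tibble: 1 × 11
#>   cell_id  n_objects total_mt_volume_um3 nucleus_volume_um3 cell_volume_um3
#> 1 phantom1        30                359.               259.          13075.
#>   cytoplasm_volume_um3 pct_mt_per_cytoplasm total_mt_intensity pct_small
#> 1               12816.                 2.80           1683118.         0
#>   pct_medium pct_network
#> 1         20          80
```

All 30 planted objects are recovered; the nucleus volume (259 µm³) matches
the phantom's analytic ellipsoid to within 0.5%, and the per-cell
percentage field recomputes exactly from its components.

```r
# a simulated photobleaching series: planted slope -0.14, 5% noise
series <- simulate_relative_series(beta = -0.14, sigma = 0.05, seed = 3)
best <- compare_models_aic(fit_trend_models(series))
best
#> <trend_fit> TMRM/SDCM  location: linear, dispersion: constant
#>   alpha 0.9887  beta -0.1382  sigma(0) 0.0497  delta 0.0000
#>   -logL -71.2669  k 3  AIC -68.2669
```

The fitted slope −0.138 recovers the planted −0.14; AIC selects the
linear-location model because the drift is real. `tidy()`, `glance()` and
`autoplot()` work on fitted trend objects; `plot_size_classes()` draws the
size-class composition.

Worked ratios from published-style group tables are one-liners:

```r
pct_mt_per_cytoplasm(85.84e2, 294.02e2)  # myotube % mt volume per cytoplasm
#> [1] 29.19734
24.3 / 1.4                               # myotube vs mesoangioblast intensity fold
#> [1] 17.35714
```

## Package layout

| Area | Functions |
|---|---|
| I/O and containers | `read_stack`, `write_stack`, `voxel_grid`, `channel_set`, `roi_table`, `analysis_config`, `read_analysis_config`, `write_objects_table` |
| Segmentation | `median_filter_3d`, `tophat_filter_3d`, `threshold_constant`, `suggest_threshold`, `label_objects`, `measure_objects`, `classify_size`, `segment_mito` |
| Morphometry | `fill_holes_3d`, `channel_volume`, `quantify_cell`, `size_class_percentages`, `summarize_group` |
| Photostability | `max_intensity_projection`, `roi_mean_intensity`, `build_series`, `fit_trend`, `fit_trend_models`, `compare_models_aic`, `fold_variation` |
| Simulation | `simulate_cell`, `simulate_population`, `simulate_series`, `simulate_relative_series`, `validation_cell_params`, `population_preset` |
| Reporting | `quantify_cells`, `report_group`, `run_pipeline`, `write_run_manifest` |

The methods vignette
(`vignettes/mitochondrial-network-quantification.Rmd`) documents the
models, the numerical choices, the synthetic-data generator and its
limitations.
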
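# echodecorr

Three-dimensional ultrasound **echo decorrelation imaging** for monitoring
and closed-loop control of radiofrequency ablation (RFA), with a seeded
synthetic data generator, voxelwise prediction assessment, and group-level
outcome statistics.

## Who this is for

Researchers in therapeutic ultrasound and image-guided interventions who
need a tested, reproducible implementation of the echo-decorrelation
measurement and control chain: from paired complex IQ echo volumes on a
phased-array sector geometry, through scan conversion and decorrelation
mapping, to threshold-based treatment control and ROC / precision–recall
evaluation of ablation prediction. Because raw clinical IQ data are rarely
redistributable, the package ships a first-class synthetic trial generator
with analytically known ground truth, so every stage is testable on any
machine.

## The core quantity

Each acquisition captures two echo volumes `I0`, `I1` separated by
τ = 50 ms. After scan conversion to an isotropic Cartesian grid, windowed
zero-lag correlations are formed with an isotropic 3D Gaussian window
(σ = 3 mm), and the combined-normalized instantaneous echo decorrelation
per millisecond is

    Δinst(r) = 2 [β²(r) − |R01(r)|²] / ( τ [β²(r) + mean(β²)] )

where `R01` is the windowed cross-correlation of the pair, `β² = R00·R11`
the product of windowed autocorrelations, and `mean(β²)` its spatial
average. `Δinst` lies in `[0, 2/τ]`; its per-voxel running temporal maximum
over a trial is the cumulative decorrelation Δ. The controller stops the
RF generator once the log10-scaled ROI-average of Δ inside a 20 mm
spherical control ROI reaches a threshold (−2.8 by default); trials are
classified UC / SC / USC (uncontrolled / successfully / unsuccessfully
controlled).

## Worked example

```r
library(echodecorr)

# a desk-scale trial: reduced beam geometry, 40 mm grid at 1 mm
geom <- beam_geometry(n_range = 121, n_azimuth = 33, n_elevation = 25,
                      depth_mm = 70)
grid <- cartesian_grid(extent_mm = 40, step_mm = 1)
cfg  <- trial_config(target_diameter_mm = 20, growth_duration_s = 132,
                     cycle_duration_s = 220, noise_snr_db = 30)
trial <- simulate_trial(cfg, geom, grid, seed = 42)
trial$truth_mask
#> <ablation_mask> (truth) 4169 voxels, 4.169 ml

rec <- run_trial(trial, control_config(threshold_log10 = -2.8), "controlled")
rec
#> <trial_record> SC (controlled), duration 0.73 min, final ROI log10 = -2.781
rec$series
#>   time_s statistic stopped
#> 1      0 -4.427880   FALSE
#> 2     22 -3.642200   FALSE
#> 3     44 -2.780708    TRUE
```

The simulated 20 mm lesion voxelizes to 4.169 ml (analytic sphere:
4.189 ml). The ROI statistic starts at the electronic noise floor
(≈ −4.4), rises as the lesion decoheres, and the controlled run stops at
the first 22 s acquisition whose statistic reaches −2.8 — here 44 s, so
the trial is SC with an RF-on time of 0.73 min.

```r
eval_roi <- sphere_mask(grid, c(0, 0, 0), 30)
g <- collect_predictions(rec$final_cum, trial$truth_mask, eval_roi)
prediction_result(g, l_mm = grid$step_mm, sigma_mm = 3)
#> <prediction_result> AUROC 0.999, AUPR 0.998 (floor 0.1644), skew 0.295,
#>                     Ntot 14147 (Neff 1065)
```

Voxelwise, the cumulative map separates ablated from unablated voxels
almost perfectly on this clean synthetic (AUROC 0.999); `Neff` discounts
the voxel count for the spatial correlation introduced by the 3 mm window.

```r
sr <- success_rates(c(normal = 14, steatotic = 11, cirrhotic = 6),
                    c(normal = 16, steatotic = 24, cirrhotic = 15))
round(sr$percent, 1)
#>    normal steatotic cirrhotic
#>      87.5      45.8      40.0
sr$pairwise
#>     group_a   group_b     chisq           p
#> 1    normal steatotic 7.1111111 0.007660761
#> 2    normal cirrhotic 7.6302273 0.005739807
#> 3 steatotic cirrhotic 0.1277406 0.720786218
```

Control success differs sharply by tissue condition: normal liver controls
far more reliably than steatotic or cirrhotic tissue, and the pairwise
chi-squared contrasts (no continuity correction) quantify that.

A full batch — simulate, control, evaluate, statistics — runs through one
configuration document:

```r
cfg <- read_run_config("my_run.yaml")        # must state a seed
pipeline_run(cfg, "out/")                    # outcomes.csv, results.json, ...
```

and a thin command-line front end is installed at
`system.file("exec", "edi", package = "echodecorr")` with subcommands
`simulate`, `decorr`, `control`, `evaluate`, `stats`, `run-all`.

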
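# ptvflow

Particle tracking velocimetry with Gaussian-process post-processing for
slow-flow imaging — built for quantifying cerebrospinal fluid (CSF) flow in
embryonic brain ventricles from label-free time-lapse movies (e.g. OCT
B-scan sequences), where endogenous particles and injected microbeads act
as flow tracers.

The package is aimed at imaging labs that need calibrated, per-compartment
flow statistics from 2-D movies: velocity maps with uncertainty, median
compartment speeds, cross-sectional areas, paired/unpaired nonparametric
comparisons, polarity maps and kymographs with a ciliary beat-frequency
readout.

## The method

Given a movie `I(x, y, t)` with pixel size in µm and frame interval in s,
and a compartment mask, the pipeline estimates a dense velocity field in
three stages:

1. **Detection + tracking.** Bright sub-resolution particles are detected
   per frame by scale-matched Laplacian-of-Gaussian filtering
   (`sigma = blob_radius / sqrt(2)`) with sub-pixel quadratic refinement,
   then linked into trajectories frame-to-frame by solving the linear
   assignment problem with squared-distance costs, distance pruning, and
   per-detection no-link alternatives ("simple LAP" semantics, no
   splits/merges), plus a gap-closing assignment pass.
2. **Windowed weighted least squares.** Each trajectory is partitioned into
   roughly half-second windows; within a window, independent weighted
   linear fits of `x(t)` and `y(t)` give one velocity vector
   `v = (dx/dt, dy/dt)` at the window centroid, robust to tracker noise.
3. **Gaussian-process regression.** Each velocity component is smoothed
   over space by a GP with squared-exponential kernel and
   weight-scaled observation noise; evaluating the posterior at every
   masked pixel yields `v(x, y)` with a per-pixel standard deviation.

The compartmental summary is the **median speed**: the median Euclidean
norm of the vectors collected in a subregion. Group comparisons use the
exact-distribution Wilcoxon signed-rank (paired) and Mann–Whitney
(unpaired) tests, two-sided, with significance at p < 0.01.

Because real movies of this kind are typically not deposited, the package
includes a synthetic scene generator (`flow_spec()` / `simulate_movie()`)
producing OCT-like movies advected by known compartmentalized vortex flows
with exported ground truth, so the entire chain is validated by parameter
recovery.

## Worked example

Simulate a single recirculating compartment whose true median speed is
10 µm/s, run the pipeline, and compare:

```r
library(ptvflow)

spec <- vortex_scene(c(V = 10), radius_um = 120, n_frames = 90,
                     n_particles = 100, seed = 3)
sim  <- simulate_movie(spec)
sim$movie
#> oct_movie: 140 x 140 px, 90 frames, 2 um/px, 0.03333 s/frame

det <- detect_movie(sim$movie, blob_radius = spec$particle_sigma * sqrt(2))
trk <- build_tracks(det, link_params(max_link_distance = 2.5))
vec <- collect_vectors(trk, 1/30, 2) # 574 velocity vectors

pvx <- fit_gpr_component(vec, "vx", seed = 1)
pvy <- fit_gpr_component(vec, "vy", seed = 1)
mask <- compartments_mask(spec$compartments, dim(sim$movie)[1:2], 2)
fld <- predict_field(pvx, pvy, mask$labels > 0, 2)

median_speed(fld, region_label = "V")
#> V: median speed 9.796 um/s over 11296 vectors
round(true_median_speed(sim$ground_truth, "V"), 2)
#> [1] 9.71
```

The compartmental median estimated from the dense field (9.80 µm/s)
matches the median of the generating field sampled along the ground-truth
tracks (9.71 µm/s) within ~1%; the dense field also carries per-pixel
standard deviations (`fld$sd_vx`, `fld$sd_vy`).

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the
package's study-scale experiments end to end, writing tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate_embryo.R` | builds the five-compartment stage-46 scene (median speeds 3.5 / 6.2 / 6.6 / 11.8 / 33.2 µm/s, alternating polarity), writes movie + mask + ground truth |
| `02_run_pipeline.R` | full pipeline on that movie via `run_pipeline()`, writes all artifacts + manifest |
| `03_recovery_table.R` | estimated vs true medians per compartment, caudo-rostral ratio |
| `04_group_comparisons.R` | paired pre/post experiments: unchanged flow (non-significant) vs stopped flow (significant) |
| `05_visualization.R` | temporal colour-coded polarity projection; kymograph + beat frequency before/after beating stops |

A representative `03` output (one seed):

```
 compartment true_median_speed estimated_median_speed relative_error
        LatV              3.62                   3.61        0.00135
         III              6.06                   6.40        0.05591
           M              6.19                   6.62        0.07043
         IVa             11.49                  11.33        0.01438
         IVp             32.83                  35.38        0.07755
estimated caudal/rostral speed ratio: 9.80 (configured 9.49)
```

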
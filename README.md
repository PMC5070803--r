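# nodetrace

Quantification of formin and actin-node dynamics from time-lapse
fluorescence microscopy.

Cells treated with low-dose Latrunculin A reorganize their cytoplasmic
actin into micron-sized nodes; on washout, filaments regrow from the nodes,
and formins such as DAAM1 sit at the node centres with a substantial
immobile fraction. Measuring that biology means a pipeline of small,
unglamorous image quantifications: FRAP curve fitting, photoactivation
pulse-chase spreading, spot tracking and two-channel colocalization,
kymograph velocimetry, and membrane-shell intensity ratios. nodetrace
implements all of them as composable, tibble-in/tibble-out R functions,
together with a synthetic-scene simulator that renders calibrated stacks
with exact ground truth so every stage can be validated without raw movies.

## The core models

**FRAP.** The recovery of a bleached circular ROI is double-normalized
(background-subtracted, divided by a reference region, pre-bleach mean set
to 1) and fitted with the two-timescale model

    F(t) = F0 + A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2)),

from which the mobile fraction (A1 + A2)/(1 - F0), its complement the
immobile fraction, the half time t1/2 (solved on the fitted curve), and an
effective diffusion coefficient (by half-time ratio to a co-acquired
reference of known D, e.g. GFP at 25-30 um^2/s) are derived.

**Photoactivation spreading.** After activating a dark fluorophore in a
circular ROI, each frame is normalized so the whole-cell intensity is 1 and
averaged in annuli [R, R+dR) of distance from the ROI edge; the *spreading
width* is the interpolated distance at which this profile falls to half of
its maximum at that time point — a model-free dispersal statistic.

**Tracking and velocimetry.** Spots are detected by difference-of-Gaussians
with MAD-based thresholds and sub-pixel centroids, linked by greedy
nearest-neighbour matching within a 1 um radius, and summarized as
displacement, speed and excursion cohorts. Filament elongation is read from
kymographs as the least-squares slope of the half-maximum tip front.

## Worked example

Simulate a FRAP experiment on a 12-um cell with a 25% bound fraction,
extract the recovery curve and fit it (the 4.7-s acquisition is about five
times the whole-cell mixing time `R^2 / 4D`, the design rule that makes
the recovery plateau identifiable):

```r
library(nodetrace)

p <- sim_params(pixel_size = 0.2, frame_interval = 0.02, n_frames = 240,
                image_shape = c(96, 96), read_noise_sigma = 0.02, seed = 7)
cell <- make_cell_mask("disk", p$image_shape, p$pixel_size, radius = 6)
ctr <- (96 - 1) * 0.2 / 2
roi  <- circular_roi(ctr, ctr, 1.5)
sim  <- simulate_frap(p, D = 10, bound_fraction = 0.25, roi = roi,
                      bleach_depth = 1, cell_mask = cell,
                      n_molecules = 8000, bleach_frame = 6)
guard <- roi_mask(circular_roi(ctr, ctr, 3), p$image_shape, p$pixel_size)
curve <- extract_recovery(sim$stack, roi, background_region = !cell,
                          reference_region = cell & !guard, bleach_frame = 6)
fit <- fit_two_exp(curve)
fit
#> <frap_fit> F(t) = F0 + A1(1-exp(-t/tau1)) + A2(1-exp(-t/tau2))
#>   F0 = 0.092, A1 = 0.537 (tau1 = 0.0736 s), A2 = 0.114 (tau2 = 1.3 s)
#>   mobile fraction = 0.716 (immobile 0.284), t1/2 = 0.0666 s
glance(fit)$immobile_fraction
#> [1] 0.2842899
```

The fitted immobile fraction (28%) recovers the simulated bound fraction
(25%) within single-replicate noise: the bound molecules never exchange
with the ROI, so the recovery plateaus below the pre-bleach level by their
share. `autoplot(fit)` overlays the fitted curve on the data; `tidy(fit)`
returns the parameters as a tibble.

Filament growth, end to end:

```r
b <- benchmark_filament_rate(seed = 1, n_seeds = 2)
attr(b, "mean_velocity_nm_s")
#> [1] 24.68168
```

Fourteen filaments per cohort are rendered elongating at 25.2 nm/s (0.1 um
pixels, 25 Hz, 10 s, SNR 10), a kymograph is cut along each filament's
axis, and the half-max tip front is regressed on time — the estimator
recovers the true rate within a few percent.

## Command line

A thin CLI over the same functions lives at `inst/cli/nodetrace.R`:

```sh
Rscript inst/cli/nodetrace.R frap --seed 3 --out runs/frap_demo
Rscript inst/cli/nodetrace.R simulate --preset filaments --out runs/fil
```

Each run writes TIFF stacks, CSV tables and a plain-text log of every
parameter affecting numerics.
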
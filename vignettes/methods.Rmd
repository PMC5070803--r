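---
title: "Models and methods behind nodetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nodetrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodetrace)
```

nodetrace quantifies protein mobility and actin-node dynamics in time-lapse
fluorescence microscopy: FRAP recovery fitting, photoactivation pulse-chase
spreading, spot tracking and colocalization, kymograph velocimetry, and
membrane-shell morphometry. Because raw movies of this kind are rarely
shareable, the package ships a synthetic-scene simulator that renders
calibrated stacks with exact ground truth, and every analysis stage is
validated against that truth. This vignette explains the models, the
defaults, and the design decisions a user should know about before trusting
a number.

## Units and coordinates

All user-facing lengths are micrometres, times seconds, and elongation
rates nm/s. Image coordinates put the origin at the centre of the top-left
pixel with 0-based pixel indexing, so `x_um = (col - 1) * pixel_size`.
Conversions are internal; no function takes pixel units except where the
argument name says so (`radius_px`, `line_width_px`).

## The synthetic scenes

The simulator is not a test fixture but the package's definition of the
reference experimental conditions; its defaults are the conditions under
which the analysis stages are claimed to work.

**Optics and camera.** Emitters are rendered as isotropic 2D Gaussians of
sigma 0.12 um — the scale of a high-NA (100x/1.49) TIRF system — by
binning molecule positions bilinearly onto the pixel grid and convolving
with the PSF kernel (circular convolution, so photon flux is conserved
exactly; scenes keep emitters away from frame borders). Noise is Poisson
shot noise on photon counts (gain `poisson_gain`, disabled when `NULL`)
followed by additive Gaussian read noise. These defaults are declared
package conventions, not values inferred from any particular instrument.

**Motion.** Mobile molecules take per-axis Gaussian steps of SD
`sqrt(2 D dt)`; immobile molecules never move. At the cell-mask boundary a
proposed step landing outside is simply not taken (the molecule keeps its
position for that frame). We chose this Metropolis-style rule over
specular reflection deliberately: on a rasterized binary mask the boundary
normal is undefined, whereas stay-put rejection conserves molecule number
and leaves the uniform distribution exactly stationary — the property FRAP
bookkeeping depends on. The cost is a slightly reduced effective D within
one step length of the wall, which none of the shipped benchmarks probe.

**Photobleaching** multiplies brightness by `exp(-k * cumulative exposure)`,
applied per acquired frame, so series with different inter-frame intervals
but equal exposure collapse onto one curve against cumulative exposure —
the diagnostic `fit_exposure_decay()` reproduces.

**Filaments** are straight segments growing at a constant rate from a fixed
origin. They start at `initial_length = 2` um rather than zero length: at
25 nm/s a filament grows only 0.25 um in a 10 s acquisition, so a
zero-length filament would remain smaller than the PSF throughout, and the
half-maximum front of a sub-resolution object tracks its blurred centroid
at roughly half the true rate. With a resolvable initial length the front
coincides with the true tip and the estimator is unbiased. The growth
increment is exactly `rate * elapsed_time` in the truth record.

**Node scenes** place a designed fraction of channel-A nodes within
`coloc_offset` of distinct channel-B nodes and keep every other inter-node
distance above `3 * max(coloc_offset, 2 * psf_sigma)`, so a
distance-threshold colocalization measurement recovers the designed
fraction up to binomial error rather than density-dependent chance overlap.

## FRAP

`extract_recovery()` uses double normalization: ROI mean minus background,
divided by a reference region (minus background) to correct acquisition
bleaching, rescaled so the pre-bleach average is 1. Double normalization
is the standard choice for streaming acquisitions that bleach the whole
cell.

`fit_two_exp()` fits the two-timescale recovery model

$$F(t) = F_0 + A_1\,(1 - e^{-t/\tau_1}) + A_2\,(1 - e^{-t/\tau_2}),$$

the minimal reaction-diffusion-motivated form that yields a mobile
fraction and half time. Numerically the model is fitted in a bounded
reparameterization: plateau $P = F_0 + A_1 + A_2$ (bounds $[0, 1.05]$ — a
normalized curve cannot recover above its pre-bleach level, and the small
headroom absorbs noise) and weight $w = A_1/(A_1+A_2) \in [0,1]$, with both
time constants capped at three times the observation window. The caps
matter: with free bounds a time constant of many multiples of the window
acts as a linear drift absorber, costs almost nothing in residual, and
inflates the extrapolated plateau arbitrarily; capping makes that solution
expensive. Fitting is bounded Levenberg-Marquardt
(`minpack.lm`) from a grid of multi-start time-constant pairs spanning
several decades; the best residual wins and $\tau_1 \le \tau_2$ is enforced
by relabelling. Non-convergence across all starts is reported as an
explicit flag, never silent output.

One acquisition-design caveat matters more than any fitting detail: the
plateau — and with it the immobile fraction — is only identifiable when
the acquisition covers the slowest recovery process. In a closed cell the
slowest process is whole-cell mixing of the bleached pool, time scale
$R^2/4D$ for cell radius $R$, which is much slower than the ROI refill
time $r^2/4D$. With a window shorter than roughly four mixing times the
pair $(A_2, \tau_2)$ trades off along a nearly flat residual valley and
the extrapolated plateau can land anywhere up to its bound; with an
adequate window the fit is stable. The shipped benchmarks and the worked
examples respect this rule.

Two mobile-fraction conventions exist in the literature; both are emitted.
The primary `mobile_fraction` is normalized by bleach depth,
$(A_1+A_2)/(1-F_0)$ — the fraction of what was bleached that recovers —
clamped to $[0,1]$; `mobile_fraction_raw` is the unclamped value. The half
time solves $F(t) = F_0 + (A_1+A_2)/2$ on the fitted curve (not the raw
data) for noise robustness.

`estimate_effective_d()` scales a co-acquired reference fluorophore's known
cytoplasmic D (default 25–30 um²/s, the GFP range) by the fold slowdown of
the half time, returning the widest interval implied by the endpoints; a
3–8-fold slowdown maps to 3.125–10 um²/s. The Soumpasis closed form
(`soumpasis_d()`) is provided only as a cross-check: the ratio route
cancels unknown geometry, the closed form does not.

## Photoactivation spreading

`ring_profile()` measures the mean intensity in half-open annuli
$[R, R+\Delta R)$ of distance from the *edge* of the activation ROI, after
normalizing each frame so total intensity over the cell mask is 1. Pixels
inside the ROI are assigned distance 0, keeping the profile maximum at
$R = 0$ for a fresh pulse. $\Delta R$ defaults to two pixels. The
`spreading_width()` statistic is the linearly interpolated distance at
which the profile first falls to half of its maximum *at that time point*
— a purely numerical estimate; no functional form is fitted to the
profile, by design. Profiles that never drop below half maximum within the
cell return the largest measured distance with an `out_of_support` flag;
secondary peaks beyond the first crossing are ignored and flagged
`multimodal`. `diffusion_travel_bound()` documents the conventional
$4Dt$ scale (20 um for D = 5 um²/s over 1 s) used to sanity-check how far
a pulse can spread; it enters no computation.

## Spot tracking

Detection is difference-of-Gaussians band-pass (sigma and 1.6 sigma),
local maxima within one sigma, kept above `snr_threshold` times the MAD of
the filtered frame, with 3x3 intensity-weighted centroid refinement.
Linking is greedy global nearest-neighbour within a 1 um search radius —
candidate links sorted by distance, ties broken by earlier frame then
lower spot id, both endpoints must be free — with no gap closing and no
merge/split handling. This is deliberately simpler than commercial
trackers: a blinking molecule yields several short tracks rather than
gap-joined ones, which keeps every linking decision reproducible from the
stated rule. Colocalization is bidirectional and non-exclusive (each
fraction counts points within the threshold of *any* partner), with the
threshold defaulting to twice the PSF sigma.

## Morphometry

Segmentation is Gaussian smoothing, Otsu's threshold, largest connected
component, hole filling (EBImage). The membrane shell is every pixel
within 1 um (default) of the boundary by inward Euclidean distance
transform; the package carries its own Felzenszwalb-Huttenlocher transform
because 3D confocal stacks need anisotropy-aware distances (z spacing is
required for 3D masks, and the 2D case is cross-checked against
`EBImage::distmap` in the tests). Membrane/cytosol ratios subtract the
per-frame mean outside the cell as background. Kymograph tip velocimetry
thresholds each row at half of *that row's* maximum — relative, so
photobleaching does not bias the front — interpolates the crossing, and
regresses tip position on time. The temporal colour-coded MIP tints each
frame with a blue-to-red hue and takes per-pixel channel maxima, so static
objects accumulate the spectrum and appear white.

## Benchmark problem sizes

The shipped benchmarks reproduce the reference measurement conditions of
the DAAM1 node system at desk scale. `benchmark_filament_rate()`: 14 filaments per cohort, 0.1 um
pixels, 25 Hz for 10 s, peak signal 10x read noise, 10 cohorts.
`benchmark_frap_immobile()`: a 20 um round cell with a 2 um central ROI,
20 000 molecules, 25 Hz with 10 pre-bleach frames and 20 s of recovery, 10
replicates. The molecule count keeps molecule-number fluctuation in the
ROI near 3.5% SD, and the recovery window is four whole-cell mixing times
($R^2/4D = 5$ s at D = 5 um²/s) so the plateau is identifiable; the
reference region for bleaching correction is the whole cell outside a 4 um
guard zone, which keeps its own counting noise negligible.

## What the synthetic scenes do not emulate

Real movies contain motion blur within an exposure, depth-dependent
defocus, autofluorescent background structure, node fusion and fission,
and directed (non-Brownian) transport. None of these are modelled, so a
passing benchmark demonstrates that the estimators are correct for
diffusion-plus-binding kinetics under Poisson/Gaussian camera noise — not
that they are robust to every artefact of live-cell imaging. Dispersal
measurements that depend on manual analysis choices in real data (exact
spreading widths for particular cell groups, commercial-tracker quality
thresholds, ad hoc edge-region definitions) are covered as ordering and
monotonicity properties, not as exact numbers.
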
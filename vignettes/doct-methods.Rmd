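---
title: "Dynamic OCT spheroid analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic OCT spheroid analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doct)
```

## The measurement model

Dynamic optical coherence tomography (D-OCT) derives intracellular-motility
contrast from repeated OCT B-scans of the same tissue location. Sub-resolution
motion of scatterers inside cells decorrelates the speckle pattern over time,
so the temporal statistics of the per-pixel OCT intensity carry information
that the static intensity image does not: live tumor-spheroid tissue
fluctuates, necrotic tissue fluctuates weakly or on a different time scale.

The acquisition model is a repeated raster scan ([`scan_protocol()`]): the
lateral field is split into `n_regions` regions of `locations_per_region`
B-scan locations, and each region is rastered `n_repeats` times, so every
location is revisited once per `frame_repeat_time_ms`. With the default
8 × 16 × 32 at Δt = 204.8 ms this gives a 52.43 s volume, a
(N−1)Δt = 6.3488 s fluctuation window per location and a Nyquist limit of
1/(2Δt) = 2.44 Hz; dynamics faster than that alias into the sampled
autocorrelation. `protocol_timing()` performs this arithmetic exactly and its
print method formats to 4 significant digits; the full-precision window
6.3488 s is deliberately not pre-truncated, because published protocol tables
sometimes truncate (6.348) rather than round (6.349) and the package should
not bake either convention into the value itself.

The inter-region flyback is modeled as zero: the volumetric acquisition time
is `n_regions × n_repeats × Δt` with no handling overhead. Plate-scale
figures that include liquid handling or repositioning are out of the timing
model's scope.

## The two dynamics estimators

Both estimators operate on the dB-scaled intensity
`I_dB = 10 log10(max(I, floor))` (`to_db()`; floor default 1e-7 of full
scale, i.e. a −70 dB clamp, so the log stays finite on empty voxels).
Working in dB makes both metrics invariant to multiplicative intensity
scaling — system gain and local reflectivity cancel.

**LIV** (logarithmic intensity variance, dB²) is the temporal variance of
`I_dB` with the population divisor N:

$$\mathrm{LIV} = \frac{1}{N}\sum_{i=0}^{N-1}
  \left[I_{dB}(t_i) - \langle I_{dB}\rangle_t\right]^2 .$$

For i.i.d. Gaussian dB noise of variance σ² its expectation is
σ²(N−1)/N — at σ = 3 dB and N = 32, 8.71875 dB² — which is what the
calibration test and the acceptance script verify by simulation.

**OCDS** (OCT correlation decay speed, ms⁻¹) fits an ordinary-least-squares
line to the temporal autocorrelation ρ(τ) over a fixed delay window and
reports the *negated* slope, so a decaying curve yields a positive "decay
speed". The late variant OCDS_l uses τ ∈ [204.8, 1228.8] ms (six grid delays
at Δt = 204.8 ms); the early variant OCDS_e uses τ ∈ [12.8, 64] ms on the
high-density single-location protocol (350 repeats at 12.8 ms). Negative
values (a rising autocorrelation) are kept, not clipped; window endpoints are
inclusive and matched to the delay grid within 1e-9 ms.

Two estimator conventions deserve explanation:

* **Normalization.** The autocorrelation is the standard Pearson form —
  covariance over the square root of the product of the two subsequence
  variances. A normalization by the raw product of variances is
  dimensionally inconsistent for a correlation that must start at ρ(0) = 1,
  and measured autocorrelation curves of this kind do start at 1.
* **Per-lag local centering.** At each lag k the correlation is computed
  between the two overlapping subsequences with their own means and
  variances ("local Pearson"). For series as short as N = 32 this is more
  robust than a single global mean, and it gives each lag a well-defined
  [−1, 1] range. Voxels with zero temporal variance (empty background,
  saturated plate) get LIV = 0 and OCDS = 0 with a `_valid = FALSE` flag
  instead of NaNs.

A consequence of local centering worth knowing (it is asserted as a property
test): for dynamics much slower than the delay window the per-pixel OCDS_l
*saturates* rather than falling back to zero — subtracting segment means
turns a slow drift into apparent window-scale decay, so at N = 32 the
response to the decorrelation time rises from ≈0 (sub-frame-time, aliased
dynamics) to a plateau and declines only weakly beyond. The monotone
decrease from window-scale (200 ms) to slow (5000 ms) dynamics holds for the
ensemble autocorrelation of the process, and the tests check it at that
level. Practically: OCDS_l separates "aliased-fast" from "window-scale"
dynamics well, but it is not a proportional clock for very slow dynamics.

## Pseudo-color rendering

Images are composed in HSV: hue is the dynamics metric mapped linearly from
a metric range onto red (low) → green (high), value is the time-averaged dB
intensity mapped onto [0, 1], and saturation is fixed at 1 — there is no
parameter to change it, since the color convention is part of the method's
identity. Published color bars for these images do not state endpoints, so
the defaults are calibrated on the phantom and fully configurable:
LIV 0–10 dB², OCDS_l 0–6e-4 ms⁻¹, and a per-volume intensity range of
[1st percentile + 5 dB, 99.9th percentile]. Slices are single-voxel planes
(`extract_slice()`), en face at constant depth, B-scan at constant slow-axis
location; no depth projection is applied.

## Segmentation and quantification

The spheroid is segmented from the time-averaged intensity volume by a
config-driven threshold plus connected-component labeling (6-connectivity by
default, 26 optional), replacing the interactive threshold-and-click
workflow with a reproducible one whose provenance (threshold, connectivity,
plate rule) is stored in every mask. The bright well-plate bottom is removed
by an automated geometric rule — a component is a plate when its lateral
footprint covers ≥ 80 % of the field, its axial extent is ≤ 5 voxels and it
reaches the deepest depths — with a manual `z_exclude` depth-range mode as
the faithful fallback; the tests check both modes agree on a fixture. The
largest surviving component is the spheroid.

Quantification (`quantify_spheroid()`) reports spheroid volume
(voxel count × voxel volume), mean LIV and mean OCDS_l over the mask, and
the two necrotic cell ratios: the fraction of spheroid voxels *strictly
below* the cutoffs of 3 dB² (LIV) and 2 × 10⁻⁴ ms⁻¹ (OCDS_l). Boundary
voxels exactly at a cutoff count as viable; lowering a cutoff can therefore
never raise a ratio.

Group comparisons (`compare_groups()`) use the two-sided Mann-Whitney test,
exact by full enumeration for group sizes up to 8 (ties via mid-ranks), with
the continuity-corrected normal approximation beyond. The exact two-sided
floor at n = 5 per group is 2/252 ≈ 0.0079; published p-values of 0.006 for
such designs must come from an approximate or differently-corrected variant,
so the package documents its enumeration convention and does not treat such
printed p-values as reproduction targets. `time_course_table()` assembles
per-(condition, day) means, n−1-divisor standard deviations, replicate
counts after outlier exclusion, and pairwise day-to-day p-values.

## The synthetic phantom

No public spheroid D-OCT dataset accompanies the method, so validation runs
on a speckle phantom with known ground truth. Each voxel's field per frame is

* a static phasor of power 1 − f with a fixed random phase, plus
* K = 10 dynamic phasors (fixed Rayleigh amplitudes of mean power f/K,
  fixed uniform base phases) whose phase perturbations follow a stationary
  Gaussian AR(1) process (sd σ_φ = 2 rad).

The uniform base phases make each dynamic term circularly Gaussian, so at
f = 1 the ensemble intensity is exactly exponential — fully developed
speckle with unit coefficient of variation, which the tests verify. The
AR(1) time constant is set to 2σ_φ²τ_c so that, through the Siegert relation
(intensity correlation = |field correlation|²), the region parameter τ_c is
the small-lag decorrelation time of the *intensity* — the observable the
dynamics metrics see — with a negligible residual long-lag correlation of
exp(−2σ_φ²) ≈ 3 × 10⁻⁴. Intensities are scaled to the region's mean dB
level and summed with exponentially distributed noise of mean
`noise_floor_db` (−30 dB default), so background voxels carry realistic
positive noise rather than zeros.

Phantom geometry is a nested-ball spheroid — necrotic core inside a viable
rim, optional peripheral drug-affected shell — above a bright 3-voxel plate
slab, on a 32 × 40 × 40 (y, z, x) grid of 0.01 mm voxels. The scenario
library encodes the qualitative regimes of interest: a quiet slow-ish core
(f = 0.05, τ_c = 50 ms) for the low-LIV/low-OCDS_l phenotype, a fast
fully-dynamic core (f = 0.95, τ_c = 30 ms < Δt) whose late autocorrelation
is flattened by aliasing (high LIV, near-zero OCDS_l), a viable rim at
f = 0.9, τ_c = 600 ms (inside the OCDS_l window), and slow shells
(τ_c = 8 s) for drug-affected peripheries. A growth series increases the
core radius over virtual treatment days 1/3/6 (fractions ≈ 0.04, 0.20,
0.58 of the spheroid volume).

What the phantom does **not** emulate: the OCT point-spread function and
speckle spatial correlation (voxels are independent), depth attenuation and
shadowing, refraction at the spheroid boundary, polarization effects, and
any calibrated mapping from biological motility to (f, τ_c) — that mapping
is an open research question, and phantom parameters are labeled synthetic.
Passing the phantom suite therefore demonstrates that the estimators,
segmentation and statistics do what they claim on data with known truth; it
does not certify absolute LIV/OCDS magnitudes on biological tissue.

Reproducibility: one master seed per phantom; regions are generated in a
fixed canonical order with vectorized draws, so a spec + seed pair is
bit-reproducible. A counter-based per-voxel stream scheme was considered and
rejected: it only pays off for parallel or out-of-order generation, and the
vectorized canonical order is two orders of magnitude faster in R.

## Numerical and I/O choices

* dB floor 1e-7 (configurable); negative linear intensities are rejected,
  re-applying `to_db` to a dB volume warns and is a no-op.
* OCDS window/grid mismatches are configuration errors naming the window;
  windows must cover ≥ 2 grid delays.
* Volumes are stored as one 32-bit-float multi-page TIFF per B-scan location
  plus a YAML sidecar (protocol, timestamps, scale, affine normalization
  into the TIFF's [0, 1] sample range, written with 17-digit precision).
  Round trips are exact at single precision (~1e-7 relative), which is the
  native sample format; TIFF keeps the fixtures plain and inspectable with
  standard imaging tools.
* Segmentation uses strict `>` thresholding; 3-D connected components are
  built from a vectorized voxel adjacency graph (igraph).

## Problem sizes

The test-suite and acceptance runs use: 10⁴ noise pixels for estimator
calibration; 32 × 40 × 40 × 32-frame phantoms (~1.6 M samples, ≈1.5 s each
to generate and analyze end to end); ten replicate seeds of the three-day
growth series for ranking recovery; a radius-20 voxelized ball for the
segmentation oracle; and full enumeration up to total n = 12 for the exact
rank test. These sizes were chosen so every statistical assertion has
comfortable Monte-Carlo margin while a full run stays in the tens of
seconds.
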
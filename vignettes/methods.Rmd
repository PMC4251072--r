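---
title: "Zone-specific circular fractal dimension of retinal fundus images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone-specific circular fractal dimension: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retfdc)
```

## The measurement problem

Fractal dimension (FD) is a widely used single-number summary of the
branching complexity of the retinal vasculature, and reduced complexity
(rarefaction) is a candidate marker of cerebrovascular risk.  Classical
estimators — box counting on a segmented vessel map, or the slope of the
radially averaged Fourier spectrum — summarize the *whole* image and offer
no way to interrogate a specific region around the optic disc (OD), even
though clinically validated calibre summaries are deliberately zone
specific.

`retfdc` implements a zone-specific estimator, the **circular fractal
dimension (FDC)**: the vessel-enhanced image is read along concentric
circles centred on the OD, each circular intensity profile is treated as a
1D series whose Higuchi fractal dimension is computed, and per-circle
values are averaged within concentric zones.  Because the major retinal
vessels radiate from the disc, a circular scan path crosses them roughly
perpendicularly, so the profiles carry the vessel cross-sections; the OD
itself is excluded by construction.  No segmentation or skeletonization is
required, which removes the main error source of box counting.

## Pipeline

For one image the estimator runs:

1. **Preprocess** (`preprocess_fundus`): the inverted green channel (best
   vessel contrast; vessels become bright), a square crop of side
   4 optic-disc diameters (`roi_factor = 4`) centred on the annotated OD,
   and area-average downsampling to `target_side = 400` pixels.  Area
   averaging is used because it preserves constants exactly and
   anti-aliases thin vessels; with the reference geometry
   (D_OD ≈ 490 px in a 1960-px crop) the working D_OD becomes 100 px.
   All geometry uses 0-based pixel-centre coordinates with half-open
   image extents; a single stated convention avoids off-by-one drift in
   the circle geometry.  An OD too close to the border is a hard error by
   default (`pad = "reflect"` opts into mirror padding), since
   OD-centred photographs should never trigger it silently.

2. **Enhance** (`enhance_vessels`): a 2D Gabor wavelet bank used as a
   directional matched filter — `psi(x) = exp(i k0·x) exp(-|Ax|²/2)` with
   `A = diag(eps^(-1/2), 1)`, elongation `eps = 4`, wave vector
   `k0 = (0, 3)`, scales 4–8 px, and 18 orientations (10° steps, 0–170°).
   For each scale the pixelwise maximum response modulus over orientations
   is kept; the inverted-green intensity is appended as an extra feature
   by default (`include_intensity_feature`).  Responses are computed in
   the frequency domain (periodic borders; the cropped ROI border is dark
   background, so wrap-around artefacts are negligible) with unit-peak
   frequency responses, which fixes the L1 norm of the spatial envelope
   across scales; the per-feature z-normalization that follows makes any
   residual scale factor irrelevant.

   The features feed a **two-class Gaussian mixture** fitted per image by
   EM (full covariances, k-means initialization on a 2000-pixel random
   subsample, at most 100 iterations, relative tolerance 1e-6, fixed
   seed).  The component with the higher mean along the largest-scale
   wavelet response is the vessel class, and its posterior probability is
   mapped to the integer range 0–255 (the *posterior vessel image*).
   A supervised classifier trained on labelled pixels would serve the
   same role; the unsupervised mixture keeps the class-conditional
   semantics self-contained when no labelled training pixels exist.  A
   degenerate fit (collapsed component) falls back to a percentile
   stretch of the largest-scale response, with a warning.

3. **Scan** (`scan_all`): circles at integer radii from `R_OD + 1`
   (one pixel outside the disc margin; a non-integer radius rounds up) to
   `2 · D_OD`, each sampled at `N ≈ 2*pi*r` equal angular steps — about
   one pixel of arc, rounded to a multiple of four so that quarter-turn
   image rotations map the sample grid onto itself exactly — by clamped
   bilinear interpolation, counter-clockwise from angle 0.  Bilinear
   (not nearest-neighbour) sampling avoids staircase artefacts that
   inflate 1D FD; the fixed start angle and direction make outputs
   bit-reproducible.  Zones are
   annuli in OD-diameter units outward from the disc margin:
   A = (0, 0.5], B = (0.5, 1.0], C = (1.0, 1.5] (half-open, closed on the
   right), so with D_OD = 100 the scan uses radii 51–200 with exactly 50
   circles per zone.

4. **Estimate** (`fdc`, `higuchi_fd`): Higuchi's estimator with
   `k_max = 8` on each profile; the FD is minus the slope of
   `log L(k)` on `log k`, where `L(k)` averages the normalized curve
   lengths over the `k` start offsets.  `k_max = 8` suits profile lengths
   of roughly 300–1250 samples (the regression needs `k ≪ N`) and is
   exposed as a parameter.  Profiles are treated as open (non-periodic)
   series; closing the loop would change only O(1/N) terms.  Each zone
   mean is the mean over all circles of the zone, and the seven
   combinations A, B, C, AB, AC, BC, ABC average over *all* constituent
   circles, so with equal counts FDC_AB = (FDC_A + FDC_B)/2 exactly.
   Constant profiles (possible when the posterior saturates near the
   disc) have no defined FD; they are skipped and counted.

Two whole-image comparators share the interface: `spectral_fd` (OLS slope
of log radially-averaged Fourier magnitude against log frequency, fitted
between 4 cycles/image and 0.45 × Nyquist, reported as the absolute slope
with an optional user affine remapping — no canonical slope-to-dimension
formula is imposed) and `box_counting_fd` (box sides 2, 4, …, side/4,
powers of two anchored at the origin, after Otsu binarization and
Zhang–Suen skeletonization via `binarize_for_bc`; both steps are flags
since segmentation choices are exactly what FDC avoids).

**Cohort statistics** (`kruskal_wallis`, `mann_whitney_ci`,
`cohort_report`): tie-corrected Kruskal–Wallis by ranks with per-group
medians, average ranks and z-scores, chi-square p-values; and the
Hodges–Lehmann shift estimate with a Mann–Whitney confidence interval
whose endpoints are order statistics of the pairwise differences at ranks
from the exact U distribution (exact for `m·n ≤ 10000`, normal
approximation beyond; the attained confidence is reported).  The report
runs every method × zone cell of a long-format FD table in a fixed row
order.  No multiplicity correction is applied across the seven zone
combinations by default — each zone is reported at face value — with
`correct = "holm"` available.

## The synthetic-data generator

No imaging cohort ships with the package, so validation rests on
`gen_synthetic_fundus`: a brighter soft-edged disc at the frame centre,
vessels grown as branching random walks that start on the disc boundary
(within one pixel) and head radially outward with Gaussian angular jitter
(`tortuosity`, degrees/step) and a weak radial pull, bifurcating with
probability `branch_prob` per 1-pixel step into headings split by
±20–40°, calibre decaying by `width_decay` per generation; tubes are
rendered as Gaussian cross-sections darker than background by `contrast`
(the real green-channel polarity), over a mild illumination gradient with
additive Gaussian noise.  Pixels are quantized to 8-bit levels so PNG
round-trips are lossless.  Defaults (400 px frame, D_OD = 100 px, 6
trunks, `branch_prob = 0.05`, trunk half-width 2.5 px, `width_decay`
0.8, tortuosity 6°, contrast 0.45, noise 0.02) give vessel calibres and
densities that look plausible at this working resolution.

Case/control cohorts (`gen_cohort`) may differ **only** in the complexity
fields (`branch_prob`, `n_trunks`) — never in contrast or noise — so any
group difference the pipeline detects is attributable to the complexity
the estimator claims to measure.  All randomness derives from one master
seed through a documented splitting rule (`derive_seed`).

What the generator does *not* emulate: photorealistic texture, the
arteriole/venule distinction, pathology (haemorrhages, exudates), camera
vignetting, or the noise structure of digitized film.  Passing tests
therefore demonstrate the pipeline's internal correctness and its
sensitivity to controlled complexity differences — not clinical
performance on real photographs.  One visible consequence: synthetic
posteriors are cleaner than real ones, so their circular profiles are
spike trains over quiet backgrounds with FDC around 1.1–1.3, whereas real
cohort data live near FDC ≈ 1.98, i.e. almost noise-like profiles.

## Numerical choices and edge cases

* Gaussian filter tails in the frequency domain are flushed to exact zero
  (beyond exp(-46)); subnormal weights otherwise slow the FFT by orders
  of magnitude without affecting results.
* Higuchi estimates are clamped to [1, 2] (warning when the excursion
  exceeds float noise); white-noise series can overshoot 2 slightly.
* A constant series has `L(k) = 0` and no defined FD: `higuchi_fd`
  errors, and `fdc` skips such circles with a count.
* The innermost/outermost circles may touch the frame within half a
  pixel; bilinear sampling clamps to the border (edge replication).
* Box counting requires side ≥ 32 so the log-log fit has ≥ 3 points;
  a single foreground pixel yields FD 0 with a warning.
* Otsu thresholding runs on the 0–255 posterior mapped to [0, 1] with
  256 levels.
* Kruskal–Wallis with all values tied reports H = 0, p = 1 with a
  warning; the chi-square p-value differs from the exact permutation
  p-value by less than 0.08 at group sizes 4 + 5 (it is asymptotic).
* Mixture-fit determinism: the EM subsample and k-means initialization
  derive from the run seed and the image id (not manifest order), so
  cohort results are invariant to processing order.

## Start-angle sensitivity of the open-series Higuchi FD

The Higuchi estimator is not exactly invariant to where a closed circular
profile is cut open: the subsequences for delay `k` drop up to `k - 1`
trailing samples, so rotating the cut point perturbs the estimate.  For
noise-like profiles (the FD ≈ 2 regime of real cohort data) the
perturbation is below 1e-3 per circle and averages out across a zone; for
the spike-dominated profiles of clean synthetic posteriors it can reach a
few times 1e-3 in a zone mean.  The geometry validation therefore checks
rotational stability on a noise-valued vessel-likelihood image, and this
sensitivity is a known property of the open-series treatment (chosen
deliberately: the estimator is defined on open series, and wraparound
differencing would change only O(1/N) terms while complicating the
definition).

A related consequence of amplitude invariance: profiles that are constant
up to sub-quantization interpolation residue (e.g. scanning concentric
structure that runs *along* the circles) yield high Higuchi FD of that
tiny residue rather than a low value.  The directional selectivity of the
circular scan is therefore validated through captured profile energy
(radial structure yields far larger per-circle variance than the same
structure arranged concentrically), not through FD of near-degenerate
profiles.

## Validation plan and problem sizes

The test suite validates, among others: Higuchi against a brute-force
transcription of the defining formulas (100 random series, agreement to
1e-12) and against constructions of known dimension (line → 1; white
noise → 2 ± 0.05 over 20 seeds; fractional Brownian motion by exact
circulant embedding → 2 − H ± 0.15 for H ∈ {0.2, 0.5, 0.8}); box counting
on the Sierpinski triangle (order 7 → log 3/log 2 ± 0.05), filled squares
and lines; the spectral slope on constructed power-law images
(β ∈ {1.5, 2.5}, 10 seeds, within 10%); exact scan geometry (radii
51–200, 50 circles per zone at D_OD = 100, zone-combination identities to
1e-12, 90° rotational stability within 1e-3); calibration of the rank
statistics (type-I error of the report path within [2.5%, 8%] over 200
null cohorts of 20 + 20 values; 95% CI coverage within [93%, 97%] over
500 shift-model replicates at n = 40/39); and end-to-end discrimination —
six replicate synthetic cohorts at full 400 × 400 resolution with the
case/control sizes 40/39, cases at `branch_prob` 0.02 against controls at
0.10, requiring the case median FDC_ABC below the control median with
Kruskal–Wallis p < 0.05 in at least 80% of replicates.  Six replicates
(rather than more) keep the suite's total runtime reasonable on a single
CPU; the observed separation is complete, so the check retains power.
The statistical-calibration checks draw per-subject FD values directly
from a common null distribution rather than rendering thousands of
images, because rank-test calibration depends only on exchangeability of
those values.

## Limitations

FDC summarizes complexity without distinguishing arteries from veins, and
its absolute value depends on the enhancement settings (scales,
orientations, mixture model), so only within-pipeline comparisons are
meaningful.  The unsupervised posterior can saturate (exact 0/255) on
clean images, producing constant inner-zone profiles that are skipped.
The synthetic generator supports methodological validation only; claims
about real cohorts require real photographs and graded OD annotations.
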
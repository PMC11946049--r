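---
title: "Quantifying lesion measurement variability across dynamic CECT phases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lesion measurement variability across dynamic CECT phases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cectvar)
```

## The problem

A dynamic contrast-enhanced CT (CECT) protocol acquires the same liver in
several series — non-contrast (NCE), early arterial (E-AP), late arterial
(L-AP) and portal venous (PVP) — within minutes. For a hepatocellular
carcinoma (HCC) lesion, each series is effectively a repeat measurement of
the same object: its true diameter cannot change between them, and its
density changes only through contrast kinetics. The spread of measurements
across series therefore estimates the *measurement* variability that
response criteria (RECIST 1.1, mRECIST, modified Choi) silently assume
away. `cectvar` extracts the two criterion-relevant quantities — maximal
in-plane diameter (mm) and mean density (HU) — from segmentation masks,
quantifies their variability, and propagates it into threshold-crossing
counts.

## Measurements

**Maximal in-plane diameter.** RECIST measures the longest in-slice extent
with calipers, edge to edge. On a binary raster we take, per axial slice,
the largest pairwise distance among the physical corners of foreground
pixels (each pixel a closed `sx × sy` rectangle), then the maximum over
slices. The corner maximum is attained on the convex hull of
boundary-pixel corners; the implementation takes the hull and scans its
vertex pairs, which for the diameter is equivalent to rotating calipers and
is verified against a brute-force all-corner-pairs oracle in the tests. A
`center` convention (pixel-center distances) is available via
`max_inplane_diameter(..., convention = "center")`; under it a single pixel
has zero extent, so `corner` is the default. "In-plane" means the third
grid axis is the slice direction; oblique NIfTI orientations are rejected
rather than silently resampled, because a maximal *in-plane* diameter is
not well defined on a tilted grid. Multi-slice masks are supported and the
slice attaining the maximum is reported; multi-component slices are
measured over the union of components, matching a contour that includes
satellite foci.

**Mean density.** The arithmetic mean of HU over all foreground voxels.
Nothing more: no trimming, no interpolation, so the value is exactly
reproducible from the mask and volume.

## Variability statistics

Percent difference uses the growth-positive convention
`100·(repeat − baseline)/baseline`, so +20% reads as progression on a
waterfall plot. (The alternative orientation, baseline-minus-measurement,
makes growth negative and cannot be reconciled with how progression
thresholds are drawn; we document rather than mirror it.) Two pairing
modes exist: `fixed` (baseline = first timepoint, n−1 pairs per lesion —
the default, matching how serial measurements are read in practice) and
`random` (all C(n,2) pairs with a seeded random baseline role). Per-lesion
CV is `100·SD/mean` with the sample (n−1) SD — per-lesion n is small, so
the unbiased denominator matters. Cohort-level CVs are the mean of
per-lesion CVs with a normal-approximation CI `mean ± 1.96·SD/√n`; phase
mean CIs use the same form, and limits of agreement are `mean ± 1.96·SD`.
Report tables round half-up at the printed precision (one decimal for
HU/mm, integers for percents) — `round_half_up()` exists because banker's
rounding would flip displayed boundary values.

Reader handling follows segmentation practice: pairwise change statistics
use the two readers' average per (lesion, timepoint); descriptive means,
SDs and CVs pool both readers' measurements. Both paths are exposed in
`analyze_study()`'s output.

Size strata are `[1,2) [2,3) [3,5) [5,7]` cm on the per-lesion average
diameter; the boundary convention (2.0 cm belongs to 2–3) is asserted in
tests. Out-of-range lesions go to the nearest bin with a warning rather
than an error, since a 7.02 cm average from a nominally ≤ 7 cm cohort is a
measurement artifact, not a protocol violation. The size–variability
relation is summarized by a Pearson correlation (via `stats::cor.test`,
two-sided t on n−2 df) between per-lesion mean size and mean change
magnitude, absolute and relative.

## Response criteria

`classify_recist11()` calls PD only when the percent increase (≥ +20%) is
accompanied by a ≥ 5 mm absolute increase; PR at ≤ −30%. `classify_mrecist()`
uses the percent thresholds alone — the crossing analysis the package
reports does likewise, since applying the 5 mm minimum is a configurable
choice (`apply_min_mm`) rather than part of the mRECIST waterfall
convention — and gates calls on arterial enhancement (a non-enhancing
lesion returns SD, flagged). `classify_mchoi()` is strict ("more than"):
PR needs density < −15% *and* diameter < −10%; PD needs diameter ≥ +20%
and is vetoed by a density partial response. Boundary inclusivity per
criterion is deliberate and tested. Note the modified Choi conjunction
means a zero-threshold audit cannot eliminate SD for it (a shrinking
diameter with rising density satisfies neither arm); that audit applies to
the single-variable criteria.

## The phantom

The generator emulates the structure of a 51-patient repeat-measurement
HCC cohort: 51 lesions of 1–7 cm (uniform), one lesion per patient, two
readers, and 40 timepoints per lesion split 5/2/16/17 across
NCE/E-AP/L-AP/PVP — proportional to that cohort's 236/127/818/874 scans —
on a 0.7 × 0.7 × 5 mm grid typical of the acquisition hardware.

* **Shape.** Super-ellipsoids (default exponent 2) with in-plane axis
  ratio ~ U(0.85, 1) and through-plane semi-axis 0.7–0.95 of the in-plane
  semi-major, rendered with a hard boundary so truth recovery is exact: a
  pixel is foreground when its center lies inside the shape after a
  0.4-pixel radial inset. The inset centers the pixel-corner Feret of the
  digitized shape on the nominal diameter (empirically within
  [+0.02, +0.42] mm at 0.7 mm spacing); without it the corner convention
  reads ~1.2 pixels high. An optional Gaussian edge blur is deliberately
  absent: partial-volume shading would make "true density inside the mask"
  ill-defined for the exactness tests.
* **Enhancement.** Piecewise by phase with means 45.03/44.25/77.96/88.01 HU
  and SDs 9.73/10.59/18.93/16.68 (largest in L-AP, where contrast inflow
  makes timing matter most). Each phase SD is split between a
  between-lesion offset and a within-phase temporal draw; the split is not
  identifiable from published phase-level summaries, so the default is an
  even 50/50 variance split, exposed as
  `enhancement_model(between_lesion_frac=)` and not to be read as
  data-derived. A gamma-variate mode
  (`HU(t) = baseline + A (t/tp)^a e^{a(1−t/tp)}`) samples acquisition times
  inside per-phase windows for users who want a kinetic curve rather than
  phase draws.
* **Readers.** Each reader's contour is a correlated copy of the truth:
  reader-specific smooth angular roughness (the "copied" base contour,
  fixed across timepoints) plus one radial scale draw `1 + ε` per (reader,
  timepoint) — the per-timepoint "edit". One draw per timepoint, not per
  boundary point, is what makes the induced diameter CV equal the
  configured `radial_jitter_cv` analytically, so the pipeline's pooled CV
  is a parameter-recovery check rather than a descriptive number. The
  default 0.05 emulates the ~5% diameter CV reported for repeat HCC
  measurements. An absolute mode (`radial_jitter_sd_mm`) holds the jitter
  fixed in millimetres across lesion sizes, which is what produces the
  negative size–relative-variability correlation.
* **Noise and motion.** Additive Gaussian image noise (default 10 HU) and
  a per-timepoint in-plane translation (SD 1 mm) shared by the lesion and
  its contours — readers edit contours to track motion, so the residual
  effect is grid re-alignment. Through-plane motion is deliberately
  excluded: with 5 mm slices a z-shift moves the equatorial slice between
  samples and would inject diameter variance an order of magnitude above
  the reader jitter being studied; accordingly the lesion equator is
  always placed on a slice center. This is a known idealization — real
  respiratory misregistration is partly through-plane — and is the main
  reason phantom-derived CVs should be read as *reader-contour*
  variability, not total clinical variability.
* **Determinism.** Every draw comes from a stream seeded by
  `(master seed, lesion, reader, timepoint)` arithmetic, so a spec
  reproduces its dataset byte-for-byte and adding lesions leaves earlier
  lesions' data unchanged (both are tested).

`generate_study()` materializes volumes and masks (fine for small studies
and for NIfTI export); `simulate_measurements()` streams — each (lesion,
timepoint) is generated on its cropped per-lesion grid, measured, and
discarded — which keeps memory flat at the default 51 × 2 × 40 design.
That design, the full published study shape, is also what the acceptance
checks run; it completes in a few minutes on one CPU.

## What passing tests do and do not show

The phantom has constant liver background, no vessels or cirrhotic
texture, hard lesion boundaries, and readers whose only errors are smooth
radial ones. Parameter recovery on it validates the *arithmetic* of the
pipeline — that a 5% configured contour jitter comes out as a 5% pooled CV,
that configured phase means are recovered, that the √k summed-diameter law
holds — not that real radiologists behave like the reader model. Published
cohort-level numbers that depend on the patients themselves (the 5.11%
diameter CV, 26.19% density CV, 83% of changes within ±10%, the 8/51 and
27/51 crossing counts) are therefore targets of *qualitative* emulation
only; the package reproduces exactly those published values that are pure
arithmetic on printed summaries (phase-mean CIs, half-range percents).

## Numerical choices and degenerate inputs

Empty masks, zero baselines, single-timepoint lesions, constant series and
zero-variance correlations are all explicit errors or logged skips, never
silent `NaN`s. `perturb_contour()` refuses to return an empty mask. Ties
in the maximum-magnitude change keep the positive value, making waterfall
output deterministic. The hull path falls back to direct pairwise
distances for ≤ 8 corner points, where a hull is not well defined or not
worth it. CSV round-trips write 17 significant digits so records survive
re-reading exactly; NIfTI headers store spacing as float32, the one place
where round-trips are only accurate to ~1e-7 relative.

## Known limitations

Single-lesion-per-patient analysis is the primary path
(`sum_target_lesions()` exists as an aggregate helper); no Bland–Altman
bias, mixed-effects repeatability or inter-reader ICC (deliberately out of
scope); no automatic segmentation, registration, or DICOM handling;
oblique acquisitions must be resampled upstream.
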
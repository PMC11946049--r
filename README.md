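# cectvar

Test–retest variability of hepatocellular carcinoma (HCC) lesion
measurements across dynamic contrast-enhanced CT (CECT) phases.

Tumor response criteria treat imaging measurements as if they were exact:
RECIST 1.1 calls a ≥ +20% diameter increase (with a 5 mm minimum)
progressive disease and a ≥ −30% decrease partial response; mRECIST adds an
arterial-enhancement gate; modified Choi combines a > 15% density drop with
a > 10% diameter drop. But every series in a dynamic CECT protocol
(non-contrast NCE, early arterial E-AP, late arterial L-AP, portal venous
PVP) is effectively a repeat scan of the same lesion, and the spread of
measurements across those repeats sets a floor on what change can be called
real. `cectvar` implements that analysis as a reusable pipeline, for
imaging scientists and trialists who need to know how much of an observed
change is attributable to measurement variability alone:

* **measurement** — maximal in-plane (Feret) diameter from binary
  segmentation masks, computed on the convex hull of boundary-pixel corners
  (pixels as closed rectangles, anisotropic spacing respected), and mean
  density in Hounsfield units; NIfTI in, CSV out.
* **variability** — per-lesion coefficients of variance
  (CV = 100·SD/mean, sample SD), pooled across lesions with normal 95% CIs
  (mean ± 1.96·SD/√n), percent differences under fixed-baseline or
  random-baseline pairing, limits of agreement (mean ± 1.96·SD) with their
  half-range percent, per-lesion maximum changes for waterfall plots, size
  strata (1–2, 2–3, 3–5, 5–7 cm), and the Pearson correlation between
  lesion size and change magnitude.
* **response criteria** — RECIST 1.1 / mRECIST / modified Choi calls and
  per-phase threshold-crossing counts.
* **phantom** — a synthetic dynamic-CECT generator (super-ellipsoid lesions,
  phase-dependent enhancement, two correlated readers with seeded radial
  jitter, image noise, in-plane motion) with a ground-truth table, so the
  whole pipeline is verifiable without patient data.

## Worked example

```r
library(cectvar)

# a synthetic study with the default design: 51 lesions of 1-7 cm,
# two readers, 40 timepoints per lesion split 5/2/16/17 across
# NCE / E-AP / L-AP / PVP, 5% radial reader jitter
spec <- phantom_spec(seed = 1)
sim  <- simulate_measurements(spec)          # generate + measure, streaming
rep  <- analyze_study(sim$records)           # the variability report
rep
```

```
Variability report: 51 lesions, 4080 records (pairing: fixed)
  diameter: mean 37.9 +/- 17.41 mm, CV 5.06% (95% CI 4.92-5.20%)
  diameter changes within +/-10%: 95%
  density: CV 27.35% (95% CI 26.30-28.41%); most variable phase: L-AP
  size vs relative change: r = -0.048 (p = 0.739)
```

The configured 5% reader jitter is recovered as a 5.06% pooled diameter CV,
and 95% of paired changes stay within ±10% — a change of that size in a
single lesion is indistinguishable from repeat-measurement noise. Density
is far more variable than diameter, worst in the late arterial phase where
contrast is still flowing in. Because the default jitter is *proportional*
to lesion size, size and relative change are uncorrelated here; switch the
reader model to a fixed jitter in millimetres
(`reader_model(radial_jitter_sd_mm = 0.8)`) and small lesions show the
large relative changes seen clinically (r strongly negative). Classify the
per-lesion maxima:

```r
cls <- classify_study(rep, sim$records)
cls$crossings[, c("phase", "pd_label", "pd_percent")]
#   phase pd_label pd_percent
#     NCE     0/51          0
#    E-AP     0/51          0
#    L-AP     0/51          0
#     PVP     0/51          0
```

At 5% reader jitter no lesion's maximum change crosses the +20%
progression threshold under fixed-baseline pairing — crossings appear as
jitter grows or under all-pairs pairing.

Worked-example reproductions of published summary tables ship with the
package (`reference_density_by_phase()`, `reference_diameter_by_size()`);
for instance `phase_mean_ci(45.03, 9.73, 51)` returns `c(42.4, 47.7)` and
`half_range_percent(77.96, 114.4)` returns `47`.

An end-to-end run (records, report JSON/CSVs, calls, plots, manifest) is:

```r
run_pipeline(run_config(mode = "simulate", spec = spec, out_dir = "run1"))
```

A thin CLI wrapper with `simulate`, `measure`, `analyze`, `classify` and
`run` subcommands is installed at `inst/scripts/cectvar`.

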
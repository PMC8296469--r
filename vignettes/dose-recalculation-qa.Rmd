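---
title: "Dose-recalculation QA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-recalculation QA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(doseQA)
```

This vignette documents the science inside `doseQA`: the γ-index model and
its numerical choices, the DVH and cohort statistics, what the synthetic
phantom generator emulates (and what it does not), and the design decisions
taken where several defensible conventions exist.

## The γ-index evaluation

The γ index combines a dose-difference criterion ΔD and a
distance-to-agreement (DTA) criterion δ into a single per-voxel quantity:
for a reference voxel at position $\vec r_r$ with dose $D_r$,

$$\gamma(\vec r_r) = \min_{\vec r_e} \sqrt{ \frac{|\vec r_e - \vec r_r|^2}{\delta^2}
  + \frac{\left(D_e(\vec r_e) - D_r(\vec r_r)\right)^2}{\Delta D^2} },$$

and the voxel passes when γ ≤ 1. `doseQA` evaluates *global* γ: ΔD is a
percentage (default 3%) of the maximum dose of the whole reference grid,
not of the local dose. Voxels whose reference dose falls below a
suppression level (default 10% of that maximum) are removed from the
analysis entirely — from the denominator, not merely from the failing set —
which is the usual reading of low-dose suppression in clinical QA. The
reference is the independent recalculation (e.g. Monte Carlo) and the
evaluated grid the planning-system dose; γ is deliberately asymmetric in
the two.

Numerical choices, all recorded in `gamma_criteria()` so the brute-force
oracle evaluates the identical problem:

* **Search lattice.** The minimization samples the evaluated dose by
  trilinear interpolation on an isotropic lattice of step δ/10, truncated
  to a ball of radius `search_cap_mm` (default 3δ). A 1/10-DTA step bounds
  the discretization error of γ near the pass boundary; the cap bounds
  cost. If the minimum is not bracketed inside the cap, the reported value
  is the cap-boundary minimum (≥ cap/δ), which can only overstate γ — a
  conservative failure.
* **Exact pruning.** Lattice offsets are visited in order of increasing
  distance and the search stops when the distance term alone reaches the
  running minimum. Every skipped candidate is provably no better, so the
  accelerated engine and the exhaustive oracle return bit-identical maps
  (asserted in the tests at 1e-9, observed at 0).
* **Boundary ties.** A voxel passes when γ ≤ 1 + 1e-9. The epsilon exists
  because an evaluated grid scaled by exactly the dose criterion
  (e.g. ×1.03 at 3%) produces γ = 1 only up to the last ulp of double
  arithmetic; it has no effect away from exact ties.
* **Geometry.** Reference and evaluated grids must share an identical
  header (dims, origin, spacing). Resampling silently changes γ, so it is
  refused rather than hidden; any regridding must be an explicit upstream
  step. Entire-plan scoring means all non-suppressed voxels; a body
  contour, if wanted, can be passed as an ROI.

## DVH metrics and constraints

`dvh_summary()` scores whole voxels (the same voxels γ scores): Dmax is the
single-voxel maximum, Dmean the arithmetic mean, V(x) the volume with dose
≥ x (closed at the level, in cc and % of the structure), and D(p%) the
⌈p·n/100⌉-th largest voxel dose. Near-maximum alternatives such as D1% are
available through `d_levels` for serial organs where the single-voxel
maximum is noisy. Constraint checks are strict (`<`), matching how
clinical constraint tables are written; a value exactly at the bound
fails. The relative mean-dose difference is signed:
Diff = (Dmean_eval − Dmean_ref)/Dmean_ref × 100%, negative when the
evaluated algorithm underestimates.

## Cohort statistics

The volume relation is fitted by unweighted ordinary least squares of the
γ passing rate on the natural logarithm of the structure volume,
γ = a + b ln V, with R² = 1 − SSres/SStot; when every rate is identical
(a fully saturated cohort) R² is reported as 0. The 95% crossing volume
V* = exp((95 − a)/b) inherits its interpretation from the slope sign:
rates fall below 95% for V < V* when b > 0 (air-cavity-like) and for
V > V* when b < 0 (bone-like). Paired two-sided t-tests (sample SD, n − 1)
compare algorithm labels case by case; p < 0.05 is reported as a flag,
never used as a filter. Zero-variance differences are handled explicitly
(t = 0, p = 1 when the mean difference is also zero; an infinite-t flag
with p = 0 otherwise).

## The synthetic phantom cohort

The generator exists so that every stage of the pipeline — γ, DVH, cohort
regression — can be exercised end to end without patient data, under
conditions shaped like a 40-case head-and-neck recalculation study:
64³ voxels at 2.5 mm, 70.4 Gy prescription, one air cavity and one bony
structure per target with lognormal volumes moment-matched to
36.7 ± 36.1 cc (air) and 41.2 ± 37.9 cc (bone), truncated to [1.5, 180] cc
(joint cap 230 cc) so every phantom is geometrically buildable; the
truncation affects well under 1% of the lognormal mass.

The dose model is deliberately minimal. The true dose is the prescription
times the target indicator convolved with an isotropic Gaussian
(σ = 5 mm) — a stand-in for the dose plateau and penumbra of a multi-field
plan, not for beam physics. The reference adds i.i.d. Gaussian noise with
SD equal to 0.5% (or 2%) of the maximum dose, the usual statement of Monte
Carlo statistical uncertainty. The evaluated dose multiplies the true dose
by (1 + f) and adds a weak long-range background field:

* **Air interface shell.** f = −d·(V_air/40 cc)^(−0.65)·(1 + 0.5·m) on the
  one-voxel interface shell of the air cavity, with m a smooth zero-mean
  texture field. The volume scaling is the load-bearing choice: interface
  underdosage is relatively weaker for large cavities, which is what makes
  the passing rate climb steeply with ln V and cross 95% inside the
  observed volume range. A uniform shell deficit cannot do this — the
  shell fraction of a cavity only decays like V^(−1/3), and a deficit
  small enough to match a −1.6% mean-dose error sits exactly at the 3%
  γ criterion, producing noise-dominated pass/fail flips instead of a
  volume law. That failure mode was measured, not assumed (R² ≈ 0.05), and
  motivated this design.
* **Bone.** f = +s·(V_bone/40 cc)^(+0.5)·(1 + 0.5·m): a textured surplus
  that grows with bone volume, so larger bony structures fail more — the
  mirrored law with the opposite sign.
* **Background.** A Gaussian random field (correlation 25 mm) with SD
  0.6% of the prescription, added everywhere, for both algorithm models:
  long-range discrepancies common to all engines. Its amplitude was set so
  the per-case scatter of the mean-dose differences matches the ±0.5–0.7
  percentage points a recalculation study reports; at 1% the scatter was
  twice that.

The amplitudes d and s were calibrated once, at the default master seed,
so the cohort-mean air/bone Dmean differences are −1.6%/+2.3% for the
AAA-like model and −0.2%/+0.4% for the AXB-like model; the calibrated
constants live in the `aaa_model()` / `axb_model()` presets, not in the
generator code. The texture correlation length (8 mm) keeps failing
patches thick enough to resist the 2-mm DTA rescue while leaving enough
independent patches per structure for stable per-case averages.

**Seeding.** One master seed drives the cohort: per-case seeds are drawn
once from it, and each case derives separate streams for reference noise,
shell texture, bone texture and background, in a fixed order. The
reference stream does not depend on the model, so AAA-like and AXB-like
evaluations of one case share their reference exactly — the paired design
of a recalculation study. Any case can be rebuilt in isolation from its
recorded seed.

**What passing tests do and do not show.** The generator reproduces
cohort-level statistics: the signs and rough magnitudes of the mean-dose
errors, passing rates that are log-linear in structure volume with R²
comparable to a real cohort, the saturated contrast of a
heterogeneity-robust algorithm, and the degradation with MC noise. It does
not reproduce voxel-level physics: no CT densities, no beam or MLC
geometry, no buildup/rebuild-down profiles at interfaces, and its air/bone
structures are single ellipsoids rather than anatomical sinuses and
vertebrae. Conclusions supported by these tests are about the *analysis
chain*, not about any clinical algorithm.

**Sampling variability.** At the default master seed the default cohort
gives R² ≈ 0.62 (air) and 0.75 (bone), fitted 95% crossings within ~11%
and ~8% of the crossings implied by a dense noiseless-volume sweep of the
same generator (`implied_crossing()`), and cohort-mean differences within
±0.05 of the calibration targets. Across other master seeds the air R²
ranges roughly 0.45–0.75: a 40-case cohort is a small sample for a noisy
log-linear law, which is worth remembering when reading any single
40-patient scatter plot.

## Problem sizes

The package's own experiments use the study-scale defaults throughout:
40 cases on 64³ grids for cohort statistics, 16³ grids for the
engine-vs-oracle equivalence sweeps (the oracle is capped at 32³ by
design), and 40³ grids for structural pipeline tests. The full acceptance
run — two algorithm models, two noise levels, all fits and the oracle
sweep — completes in a few minutes on one CPU.

## Known limitations

* Only axis-aligned, uniformly spaced grids; oblique DICOM orientations
  are rejected, never resampled.
* The DICOM reader supports explicit-VR little-endian files (the common
  TPS export); implicit-VR files must be converted first.
* Local-normalization γ is not the default and 2D film-style γ is out of
  scope; interpolation is trilinear only.
* DVH curves are not interpolated between voxels; biological indices
  (EUD, NTCP/TCP) are out of scope.
* The synthetic cohort draws air and bone volumes independently, one
  structure of each kind per phantom; real targets contain several
  cavities and bones whose volumes co-vary with disease site.
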
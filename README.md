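# doseQA

Patient-specific dose-recalculation QA for radiotherapy, in R.

When an IMRT plan is recalculated with an independent dose engine (typically
Monte Carlo), the recalculated distribution becomes the reference and the
planning-system dose the evaluated distribution. `doseQA` implements the
analysis chain that turns such a pair into QA statistics:

- **Global 3D γ-index evaluation** with a distance-to-agreement (DTA)
  search. For each scored reference voxel,

  γ(r⃗ᵣ) = min over r⃗ₑ of √( |r⃗ₑ − r⃗ᵣ|² / δ² + (Dₑ(r⃗ₑ) − Dᵣ(r⃗ᵣ))² / ΔD² )

  with ΔD a percentage of the global reference maximum (default 3%),
  δ the DTA (default 2 mm), and voxels below a suppression level (default
  10% of the reference maximum) excluded from scoring. A voxel passes when
  γ ≤ 1; the passing rate is the percentage of scored voxels that pass. The
  DTA search evaluates trilinearly interpolated doses on a δ/10 lattice
  inside a capped radius, with an exact pruned minimization (a brute-force
  oracle, `gamma_bruteforce()`, enumerates the identical lattice and is used
  in the tests to verify bitwise agreement).
- **DVH metrics and constraint checks**: Dmax, Dmean, V(x Gy) in cc and %,
  D(p%) by the order-statistic rule, strict (`<`) organ-at-risk constraint
  checks, and the relative mean-dose difference
  Diff = (Dmean_TPS − Dmean_MC) / Dmean_MC × 100%.
- **Cohort statistics**: per-structure mean ± SD tables with paired
  t-tests between two algorithm labels, ordinary least-squares fits of
  γ = a + b·ln(V) against the volumes of air cavities and bony structures
  inside the target, and the volume V* = exp((95 − a)/b) at which the
  fitted relation crosses the 95% action level.
- **A synthetic phantom cohort generator** that emulates a head-and-neck
  recalculation study without patient data: ellipsoidal targets holding an
  air cavity and a bony structure (lognormal volumes, 36.7 ± 36.1 cc and
  41.2 ± 37.9 cc), a Monte-Carlo-like noisy reference dose (0.5% or 2% of
  the maximum), and algorithm-specific heterogeneity error fields — an
  interface-shell dose deficit in air and a volume-scaled surplus in bone —
  calibrated so the AAA-like model underestimates the air-cavity mean dose
  by ≈1.6% and overestimates bone by ≈2.3%, while the AXB-like model stays
  within −0.2%/+0.4%.
- **I/O**: DICOM RT Dose and RT Structure Set readers (axis-aligned grids),
  contour-to-mask rasterization, and a plain-text grid exchange format
  (DGRID v1) used for all pipeline artifacts.

## Worked example

```r
library(doseQA)

spec <- phantom_spec(v_air_cc = 36.7, v_bone_cc = 41.2)  # 64^3 @ 2.5 mm, 70.4 Gy
ph   <- build_phantom(spec, seed = 42)
pair <- make_dose_pair(ph, aaa_model(), spec$rx_gy, seed = 42)

rec <- run_case(pair$reference, pair$evaluated,
                list(target = ph$target, air = ph$air, bone = ph$bone),
                run_config(), case_id = "c1", algorithm = "AAA-like")
round(rec$gamma_pct, 2)
#> entire_plan      target         air        bone
#>       99.08       98.68       97.49       89.00
round(rec$diff_pct, 3)
#> target    air   bone
#>  0.145 -0.934  2.332
```

The γ passing rate drops inside the heterogeneities (97.5% in the air
cavity, 89.0% in bone, versus 99.1% for the entire plan), and the mean-dose
differences carry the characteristic signs: this phantom's AAA-like model
underdoses the air cavity by 0.9% and overdoses bone by 2.3% relative to
the MC-like reference (per-case values scatter around the calibrated
cohort means of −1.6% and +2.3%).

At cohort scale:

```r
res <- evaluate_synthetic_cohort(cohort_config())  # 40 cases, both models
res$summary$fits[["AAA-like"]]$air
#> <log_linear_fit> gamma = 66.626 +8.206 ln(V), R^2 = 0.622, n = 40
res$summary$thresholds[["AAA-like"]]$air
#> [1] 31.74477   # cc: fitted 95% crossing volume
```

The AAA-like passing rate rises with the log air-cavity volume and falls
with the log bone volume; the AXB-like cohort shows no volume dependence
(R² ≤ 0.025) and stays above 95% everywhere.

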
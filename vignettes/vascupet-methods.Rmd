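---
title: "Quantifying organ vascularity with blood-pool PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organ vascularity with blood-pool PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascupet)
```

## The measurement model

Erythrocytes incubated with ¹⁸F-FDG trap the tracer intracellularly, so
after reinjection the labeled cells are a purely intravascular PET agent:
voxel activity is proportional to local blood volume, not metabolism. In a
blood-filled chamber (the LV cavity) the signal is the blood activity
$A_b$ (Bq/mL); in tissue it is the vascular volume fraction times that,
$f_v A_b$, because only the vascular compartment of the voxel carries
labeled cells. A pharmacological vasodilator recruits vascular volume and
multiplies the tissue signal by $1 + d$, leaving the chamber unchanged.
Everything the package quantifies follows from this model.

### SUV conversion

Activity images are converted voxelwise by

$$\mathrm{SUV}\ (\mathrm{g/mL}) = v \times \frac{C \cdot w\ (\mathrm{kg})}{D\ (\mathrm{Bq})} \times 1000\ (\mathrm{g/kg}),$$

where $v$ is the voxel value in Bq/mL, $w$ body weight, $D$ injected dose,
and $C$ the decay correction. The source of the formula leaves $C$
unspecified; `decay_factor()` adopts the standard correction to injection
time, $C = 2^{\Delta t / T_{1/2}}$ with $T_{1/2} = 109.77$ min for ¹⁸F —
the only physically sensible reading of a "correction factor for tracer
decay". Whether to correct to injection or scan start remains
configurable: `delay_min = 0` gives $C = 1$. A voxel containing the dose
distributed uniformly over the body mass, $D / (1000\,w)$ Bq/mL, maps to
SUV $= C$; this identity anchors the unit tests.

### The increased ratio

Stress and rest volumes are co-registered and subtracted voxelwise inside
the segmented VOI; negative differences — which arise mainly from
partial-volume averaging against the adjacent high-activity chamber blood
— are set to zero rather than excluded, so the voxel count is preserved.
The vasodilation statistic is

$$\mathrm{IR} = 100 \times \frac{\sum_{\mathrm{VOI}} \max(s - r, 0)}{\sum_{\mathrm{VOI}} r}\ \%.$$

The rest-state sum is the denominator: on the bundled reference tables
this is the only reading whose per-rat arithmetic reproduces the printed
ratios (it does so, to ±0.01, for the rows that are internally
consistent; `reproduce_tables()` flags the remainder rather than failing
them, since several printed cells cannot be reconciled with any
difference/rest arithmetic). On an ideal phantom whose tissue signal is
multiplied by $1 + d$, IR $= 100d$ exactly — the estimator is
scale-equivariant and, through the clipping, carries a non-negative noise
bias.

### Registration

`register_rigid()` aligns mask centroids with an integer voxel shift,
discarding the sub-voxel remainder. Same-scanner, same-session volume
pairs differ essentially by a small translation, and an integer shift
feeds the subtraction stage with unsmoothed values — any interpolation
would itself create the partial-volume artifacts the clipping rule
exists to suppress. Deformable registration and gate-to-gate motion
correction are out of scope.

### Infarct sizing

Two independent estimators target the same quantity, mirroring the
imaging-vs-pathology comparison the pipeline reproduces:

* **PET stratification** — the masked voxels of one short-axis slice
  (planes perpendicular to grid axis 3, the declared long axis) are
  split into low/medium/high activity classes by two-threshold Otsu:
  64 equal-width histogram bins by default, exhaustive $O(\mathrm{bins}^2)$
  search for the bin pair maximizing between-class variance, ties broken
  toward the lowest pair. Low counts as infarct, medium + high as viable:
  $\mathrm{infarct\ \%} = 100\,n_\mathrm{low} / (n_\mathrm{low} +
  n_\mathrm{med} + n_\mathrm{high})$. Because binning is min–max
  equal-width, the classification is invariant under affine rescaling of
  the activities. A manual `thresholds` override stands in for expert
  fine adjustment of the class boundaries; there is no interactive step.
* **TTC stain color thresholding** — the stain photograph is converted to
  hue/saturation/lightness; background is lightness > 0.9, viable tissue
  the dark-red hue box (330°–20°, saturation > 0.4), infarct the tan box
  (20°–60°, saturation 0.1–0.5). The boxes are configuration
  (`stain_color_config()`) because stain intensity varies between
  preparations.

### Exact rank inference

At n = 5–6 animals per arm, asymptotic rank tests are inappropriate;
`signed_rank_exact()` and `rank_sum_exact()` enumerate the complete null
distribution (all $2^n$ sign patterns via a generating-function
recursion; all $\binom{n+m}{n}$ rank allocations), handle ties by
midranks inside the enumeration, and report the conventional min-tail
statistic together with the exact two-tailed p-value (twice the lower
tail, capped at 1). Complete separation of two groups of five gives
$U = 0$ with $p = 2/252 \approx 0.0079$; five uniformly positive paired
differences give $W = 0$ with $p = 2/32 = 0.0625$ — with n = 5 pairs an
exact two-tailed paired test cannot reach 0.05, which is why the
reported statistic is checked against its critical value rather than a
p threshold at that sample size.

## The phantom generator

`make_lv_phantom()` and `make_brain_phantom()` emit already-reconstructed
volumes implementing the measurement model directly: an axis-aligned
ellipsoidal myocardial shell around a blood-pool cavity (or a filled
ellipsoid for brain), piecewise-constant before degradation, with an
optional infarct wedge (a contiguous azimuthal sector of the shell whose
signal is scaled by `scale`), four cardiac gates emulated as prescribed
shell-thickness states (gate 1 = thinnest wall / largest cavity =
diastole, the state quantification uses), isotropic Gaussian PSF blur in
mm, and per-voxel Poisson noise on counts = activity × `dwell_scale`,
rescaled back to Bq/mL. All randomness flows from the single integer
seed, so phantoms are bit-reproducible. `make_ttc_image()` renders the
matched stain photograph: an annulus with a tan wedge of known fraction
on white, plus seeded color jitter.

Defaults are free parameters — the study the pipeline follows prints no
wall thickness or absolute chamber activity — chosen once at
field-realistic values: 1.4 mm isotropic voxels, blood activity
20000 Bq/mL, vascular fraction 0.1, PSF σ 0.6 mm (sub-voxel, the order of
small-animal PET intrinsic resolution), dwell scale 1 (≈2000 counts per
myocardial voxel, a high-count regime).

What the phantom does **not** emulate: list-mode acquisition and OSEM
reconstruction (and their correlated noise), attenuation and scatter,
realistic rat anatomy, wall motion within a gate, spillover other than
Gaussian blur. Passing tests therefore demonstrate that the *estimators*
are correct under the stated degradation model, not that real rat images
meet that model.

## Numerical and design choices

* **Infarct cross-method check.** The PET-vs-stain agreement check at a
  25% wedge runs the PET arm at zero PSF with Poisson noise on. Nonzero
  PSF is precisely the overestimation mechanism the package demonstrates
  separately (the slice estimate grows monotonically as σ sweeps
  0.6 → 2.8 mm, the phantom echo of blood-pool margins over-calling
  infarct size), so the base comparison isolates wedge rasterization —
  the only error source both arms share.
* **Clipping bias regime.** At high counts the clipping rule never
  binds and the increased-ratio estimator is unbiased to numerical
  noise; its non-negative bias is asserted in a low-count regime
  (`dwell_scale = 0.01`, ≈20 counts per shell voxel) where negative
  fluctuations actually clip.
* **Histograms.** `activity_histogram()` defaults to 64 equal-width bins
  over the masked min–max (no binning is prescribed by the source);
  counts always sum to the masked voxel count, including the degenerate
  single-value case, which gets a unit-width bin.
* **Degenerate inputs.** Otsu requires ≥3 distinct values; empty masks,
  zero rest sums, all-zero paired differences, non-increasing bin edges
  and geometry mismatches raise typed errors rather than propagating NaN.
* **Unit discipline.** Subtraction happens on Bq/mL volumes (the unit
  the reference tables are printed in); SUV differencing is possible but
  not the default. Unit tags travel with every volume and survive disk
  round-trips via JSON sidecars (the NIfTI header keeps spacing, in
  float32; the sidecar preserves it exactly).
* **Problem sizes.** The shipped tests run 32³–64³ grids, 50-seed noise
  ensembles and 20-instance Otsu oracle sweeps — sizes at which every
  property asserted is already sharp, and the whole suite runs in well
  under a minute.

## Reference tables and known inconsistencies

The per-rat reference values bundled in `inst/extdata/` (five control
and five diabetic stress/rest rows, six infarction rats × three sizing
methods, and the printed summary cells) drive `reproduce_tables()`,
which re-derives every derivable cell and reports `match` within ±0.01
or `flagged` otherwise. Flags are expected: a subset of printed per-rat
ratios (and one group SE) are not internally consistent with the stated
difference/rest arithmetic at printed precision. The package follows the
formula validated on the consistent rows and surfaces the rest — it does
not average over, reweight, or silently correct printed values.

## Limitations

Congruent grids are required throughout (no resampling, no DICOM);
registration is translation-only; the stain segmenter assumes the
two-color TTC palette and a near-white background; exact tests are
limited to 20 observations (beyond which enumeration should give way to
the standard asymptotic implementations); and phantom realism is
deliberately minimal, as above.
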
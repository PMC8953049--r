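# vascupet

Quantification of whole-organ vascularity from blood-pool PET imaging
with tracer-labeled erythrocytes.

FDG-labeled red blood cells are a purely intravascular PET agent: voxel
activity is proportional to local blood volume, so imaging an organ
before and after a pharmacological vasodilator measures recruitable
vascular volume — including the microvasculature that most modalities
cannot see. `vascupet` implements the full analysis chain behind this
kind of small-animal study:

* **SUV conversion** with decay correction:
  `SUV (g/mL) = v × C·w(kg)/D(Bq) × 1000`, `C = 2^(Δt/T½)`, T½ =
  109.77 min for ¹⁸F.
* **VOI quantification** — masked activity sums, means, physical volumes
  and histograms on NIfTI volumes with strict unit and geometry tracking.
* **Stress–rest difference imaging** — centroid-based rigid
  co-registration, voxelwise subtraction with negative clipping, and the
  vasodilation statistic
  `IR = 100 × Σ max(stress − rest, 0) / Σ rest  (%)`.
* **Infarct sizing** two independent ways: three-class Otsu
  stratification of PET short-axis slices
  (`infarct % = low / (low + medium + high)`), and color thresholding of
  TTC (tetrazolium) stain photographs.
* **Exact small-sample Wilcoxon tests** — signed-rank and rank-sum by
  complete enumeration with midrank tie handling, reporting the min-tail
  statistic and exact two-tailed p.
* **Synthetic gated phantoms** — ellipsoidal LV shell + blood-pool
  chamber (or filled brain ellipsoid) with known vasodilation, infarct
  wedge, Gaussian PSF and Poisson noise, plus matched synthetic TTC
  images, so every stage is testable with known ground truth.

## Worked example

A five-rat stress/rest phantom study (64³ grid, Poisson noise, 0.6 mm
PSF), analyzed exactly like the animal data:

```r
library(vascupet)
spec <- phantom_spec(grid_shape = c(64, 64, 64), noise = "poisson")
study <- run_vasodilation_study("lv",
                                deltas = c(0.45, 0.52, 0.58, 0.49, 0.55),
                                base_spec = spec, seeds = 1:5)
study$table
#>   subject delta stress_sum rest_sum clipped_diff_sum increased_ratio_pct
#> 1       1  0.45   65292253 46111272         19180981             41.5972
#> 2       2  0.52   68258886 46118331         22140555             48.0081
#> 3       3  0.58   70813644 46109210         24704434             53.5781
#> 4       4  0.49   66984846 46106978         20877868             45.2814
#> 5       5  0.55   69535251 46097266         23437985             50.8446
study$test
#> <rank_test_result> signed_rank: statistic = 0, n = 5 (0 zero pairs dropped),
#>   p = 0.0625 (exact, two-tailed)
```

Each row is one subject: the masked stress and rest activity sums, the
clipped pixelwise difference sum, and the increased ratio. The ratios
sit a few points below `100 × delta` — partial-volume blur spills
chamber activity into the myocardial mask and inflates the rest-state
denominator, exactly the artifact the clipping rule addresses (set
`psf_sigma_mm = 0` and the recovery is exact). All five stress sums
exceed their rest sums, so the exact paired signed-rank statistic is 0 —
with n = 5 the strongest paired result obtainable.

Comparing the bundled control vs diabetic reference ratios:

```r
tabs <- reference_tables()
rank_sum_exact(tabs$control$increased_ratio_pct,
               tabs$diabetic$increased_ratio_pct)
#> <rank_test_result> rank_sum: statistic = 0, n = 5, m = 5,
#>   p = 0.0079365 (exact, two-tailed)
```

The two groups separate completely (every control ratio exceeds every
diabetic ratio), giving U = 0 with exact p = 2/252.
`reproduce_tables()` re-derives every derivable reference-table cell and
reports each as `match` (±0.01) or `flagged`; flags mark printed cells
that are not internally consistent with the stated arithmetic, which the
package surfaces rather than corrects.

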
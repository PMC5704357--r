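# BMEquant

Quantification of bone marrow inflammatory edema in STIR MRI of the spine
and sacroiliac (SI) joints by intensity thresholding.

On short tau inversion recovery (STIR) images, inflammatory edema is
hyper-intense relative to normal marrow. Given a STIR volume, a manual
bone-marrow segmentation and a reference ROI in visibly healthy marrow
(≥ 200 voxels), BMEquant masks every bone voxel whose intensity exceeds

    T = mean(ROI) + k · SD(ROI)

groups the supra-threshold voxels into 3D connected components, discards
components smaller than 10 voxels as artefacts, and reports per image set:

* `volume_hyper` — total lesion volume in cm³,
* `n_objects` — the number of lesions,
* pooled relative intensities `S_RelHyper = (S_hyper − mean(ROI)) / mean(ROI)`
  summarized by mean, median, 75th and 90th percentile.

The SD multiplier is anatomy-specific (`k = 4.15` spine, `k = 2.64` SI
joints, chosen by ROC calibration against reader labels); `sweepK()`
re-runs that calibration on any labelled cohort and picks the Youden
optimum. Agreement with a semi-quantitative reference such as the SPARCC
score is assessed with confusion tables, sensitivity/specificity, Spearman
rank correlation and cohort aggregation. A synthetic STIR phantom
generator with ground-truth lesion masks makes the entire pipeline
testable without patient data.

Intended users: imaging scientists and rheumatology researchers evaluating
quantitative alternatives or companions to reader scoring of axial
inflammation.

## Worked example

Quantify a synthetic phantom carrying one ~1000-voxel lesion of contrast
10 noise-SDs:

```r
library(BMEquant)

ph <- generatePhantom(phantomConfig(
  lesions = list(list(center = c(32, 32, 9), semiAxes = c(8, 8, 3.7),
                      delta = 10))), seed = 1)
quantifyEdema(ph$image, ph$bone, ph$roi, preset = "spine")
#> QuantResult 'phantom'
#>   threshold T = 140.5 (ROI mean 99.8 + k = 4.15 x SD 9.813, n = 225)
#>   lesions: 1, volume_hyper = 3.98 cm^3
#>   S_RelHyper: mean 1.005, median 1.009, p75 1.070, p90 1.135
```

The 225-voxel reference ROI measured healthy marrow at 99.8 ± 9.8, so the
spine threshold is 140.5; one lesion survives the 10-voxel filter. Its
995 voxels of 0.004 cm³ give `volume_hyper` = 3.98 cm³ — the ground-truth
ellipsoid has 995 voxels, so recovery is exact here — and its voxels are
on average twice as bright as normal marrow (mean `S_RelHyper` ≈ 1.0,
matching the simulated contrast of 10 × SD 10 on a mean of 100).

Agreement statistics work directly from published-style marginal counts.
For a cohort of 85 spine image sets with 60 reader-positive sets, 56
threshold-positive sets and 19 sets negative by both methods:

```r
confusionFromCounts(85, 60, 56, 19)
#> AgreementTable (reference in columns)
#>           reference
#> test       positive negative
#>   positive       50        6
#>   negative       10       19
#>   sensitivity = 0.833, specificity = 0.760

round(aggregateCohort(rep(10.5, 60), nTotal = 85), 2)
#>  mean   min   max
#>  7.41  0.00 10.50
```

i.e. sensitivity 83%, specificity 76%, and a positive-subset mean score
of 10.5 spread over all 85 sets (zeros included) gives a cohort mean of
7.41.

Calibrating `k` on a separable phantom cohort:

```r
cases <- phantomCohort(4, 4, delta = 12, seed = 2)
sweepK(cases, kGrid = seq(1, 6, by = 0.25))
#> ThresholdROC: 21 grid points, 4 positive / 4 negative cases
#>   AUC = 1.000, optimal k (Youden) = 6
```

(with fully separable classes every k in the separating interval is
optimal; ties break toward the larger, more specific k).

## Command line

A thin CLI over the same functions is installed with the package:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "bmequant", package = "BMEquant"))')
Rscript $cli simulate  --seed 5 --out-dir phantom1
Rscript $cli quantify  --image phantom1/image.nii.gz \
                       --bone-mask phantom1/bone.nii.gz \
                       --roi 32,32,8.5,3 --preset spine --out result.json
Rscript $cli run       --inventory phantom1/manifest.csv --preset spine \
                       --out results.csv
Rscript $cli calibrate --cases cases.csv --out roc.csv
Rscript $cli agree     --results results.csv --labels labels.csv \
                       --out agreement.json
```

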
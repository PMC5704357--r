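---
title: "Quantifying bone marrow edema by STIR intensity thresholding"
author: "BMEquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bone marrow edema by STIR intensity thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BMEquant)
```

## The problem and the model

On short tau inversion recovery (STIR) MRI, fluid accumulates signal:
bone marrow inflammatory edema — the imaging hallmark of active axial
inflammation in spondyloarthritides such as psoriatic arthritis — appears
as patches that are brighter than normal marrow. Reader-based indices such
as the SPARCC score grade this brightness semi-quantitatively; BMEquant
implements the complementary quantitative route, a global intensity
threshold over the segmented bone marrow.

The procedure for one image set is:

1. **Normalization** (optional): histogram-match the volume to one
   anatomy-specific reference volume so that image sets acquired with
   different overall brightness share an intensity scale.
2. **Reference ROI**: sample a region of visibly healthy marrow (a disc of
   at least 200 voxels) and take its mean $\bar S_{bone}$ and sample
   standard deviation $\sigma_{bone}$.
3. **Threshold**: $T = \bar S_{bone} + k\,\sigma_{bone}$. Voxels inside
   the bone-marrow mask with intensity strictly greater than $T$ are
   candidate edema.
4. **Object filtering**: candidate voxels are grouped into connected
   components (26-adjacency by default); components with fewer than 10
   voxels are discarded as noise artefacts. Each surviving component is
   one lesion.
5. **Metrics**: total lesion volume
   $\mathrm{volume}_{hyper} = N_{vox} \cdot v_{vox}$ (cm³), the lesion
   count, and the per-voxel relative intensities
   $$S_{RelHyper} = \frac{S_{hyper} - \bar S_{bone}}{\bar S_{bone}},$$
   summarized by mean, median, 75th and 90th percentile pooled over *all*
   surviving voxels of the image set.

The SD multiplier $k$ is anatomy-specific: $k = 4.15$ for the spine and
$k = 2.64$ for the sacroiliac (SI) joints, the operating points obtained
by ROC calibration against reader labels. `sweepK()` reproduces that
calibration on any labelled cohort: it runs the full pipeline across a
grid of $k$, classifies a case as test-positive when at least one lesion
survives, and selects the $k$ maximizing Youden's
$J = \text{sensitivity} + \text{specificity} - 1$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 4.15 (spine) / 2.64 (SI) | SD multiplier of the threshold; larger is more specific |
| `minSize` | 10 voxels | smallest component kept as a lesion |
| `connectivity` | 26 | 3D adjacency (6/18/26); 4/8 select per-slice 2D grouping for slice-wise SI analysis |
| `includeGap` | `FALSE` | whether the inter-slice gap inflates the per-voxel volume |
| `nBins` | 256 | histogram bins for the matching transform |
| ROI size | ≥ 200 voxels | below this a warning flags an unstable SD estimate |

Voxel volume is `prod(spacing)/1000` cm³. Protocols acquire slices with a
gap (typically 10% of the 4 mm slice thickness); the lesion signal is only
sampled within the excited slice, so the gap is *excluded* by default and
`includeGap = TRUE` is offered for sensitivity analyses. This choice is a
package decision: summed "pixel volumes" do not define gap treatment, and
the two conventions differ by exactly the factor
$1 + \text{gap fraction}$.

## Numerical conventions

* Voxel indices are 1-based `(row, column, slice)` triplets, the natural
  convention for R arrays. Images and masks must share one lattice; no
  resampling is attempted.
* The threshold comparison is strict (`> T`): a voxel exactly at the
  threshold is not selected.
* The ROI SD uses the $n-1$ denominator (sample SD of a measured region).
* Percentiles interpolate linearly between order statistics at rank
  $p(n-1)+1$ (R's default type-7 rule), a stated, testable convention.
* Histogram matching bins intensities on 256 equal-width bins over the
  joint range of image and reference, interpolates the binned CDF within
  each voxel's bin, and maps through the reference sample's inverse
  empirical CDF. The transform is monotone, so voxel ranks — and hence the
  supra-threshold set after re-thresholding — survive any strictly
  increasing distortion of the input. A constant image maps to the
  reference median; a constant reference with a non-constant image is an
  error rather than a guess.
* ROC curves append the corner points (0, 0) and (1, 1) and integrate by
  the trapezoid rule; ties in Youden's J break toward the larger $k$
  (the more specific threshold).
* An image set with no surviving lesion reports
  $\mathrm{volume}_{hyper} = 0$ but *absent* (`NA`) intensity summaries,
  never zeros: cohort means over all sets can then include zeros for
  volume while restricting intensity statistics to lesion-positive sets,
  matching how such cohorts are reported.

`confusionFromCounts()` reconstructs a 2×2 agreement table from the four
marginal counts a report typically prints (total, reference-positive,
test-positive, agreed-negative); `aggregateCohort()` spreads a
positive-subset mean over a full cohort with zeros included. Both are
exact integer/rational arithmetic and power the worked examples in the
README.

## The synthetic phantom

`generatePhantom()` builds a STIR-like test volume with known ground
truth: a rectangular bone-marrow region (default 32×32×14 voxels of
1×1×4 mm, mean 100, noise SD 10) inside darker soft tissue (mean 60),
ellipsoidal lesions of contrast $\Delta$ expressed in multiples of the
marrow noise SD, an optional smooth multiplicative bias field (a
separable Gaussian gain bump emulating coil proximity), and Gaussian
(default) or Rician magnitude noise. The reference ROI is a 227-voxel
disc in lesion-free marrow; placements that overlap a lesion or leave the
bone region are errors. Lesion voxels have expected intensity
$\mu_{bone}(1 + \text{bias}) + \Delta\sigma_{bone}$, and the ground-truth
mask is the geometric ellipsoid, not the post-noise supra-threshold set.

```{r phantom-example}
ph <- generatePhantom(phantomConfig(
  lesions = list(list(center = c(32, 32, 9), semiAxes = c(8, 8, 3.7),
                      delta = 10))), seed = 1)
quantifyEdema(ph$image, ph$bone, ph$roi, preset = "spine")
```

What the phantom emulates: the acquisition geometry (4 mm slices, 10%
gap), the contrast-to-noise regime of marrow lesions, the ≥ 200-voxel
reference ROI, and the coil-proximity failure mode in which marrow far
from the reference ROI exceeds the threshold purely through bias gain —
and is suppressed again once the ROI is placed inside the high-gain
region, because the threshold adapts. What it does not emulate: real
vertebral/SI anatomy, partial-volume edges (lesions are sharp
ellipsoids), spatially correlated noise, multi-coil reconstruction, and
pathologies other than edema-like hyper-intensity. Passing the phantom
suite therefore demonstrates the correctness of the computational
pipeline and its statistical contracts, not clinical accuracy on patient
data.

Phantom defaults are chosen once to mirror a typical 1.5 T spine STIR
acquisition; at contrast $\Delta = 10$ the per-voxel detection
probability at $k = 4.15$ is $P(Z > 4.15 - 10) \approx 1$, so a
~1000-voxel lesion is recovered within 5%, while lesion-free marrow
(~14000 voxels at a per-voxel false-positive rate of
$P(Z > 4.15) \approx 1.7\times10^{-5}$) essentially never yields a
10-voxel cluster — the size filter drives the false-positive volume to
exactly zero.

## Design choices where the design was open

* **Case positivity for ROC calibration** is "at least one surviving
  lesion" (`nLesions >= 1`); a volume-cutoff rule is exposed via
  `minVolume` but off by default.
* **Matching granularity**: the whole 3D volume is matched as one sample;
  per-slice matching would break inter-slice intensity consistency.
* **Per-slice mode**: connectivities 4/8 confine components to single
  slices for slice-wise SI scoring; the 10-voxel minimum then applies to
  in-plane pixel counts.
* **Reference volumes** for matching are user-supplied (any
  `ImageVolume`, e.g. a phantom or a chosen study volume); the package
  does not ship patient images.
* **DICOM**: only NIfTI-1 is read natively. The one DICOM-specific
  quantity the pipeline needs — the inter-slice gap fraction,
  `(SpacingBetweenSlices - SliceThickness) / SliceThickness` — is exposed
  as `deriveSliceGap()` so users can carry it over from series metadata.

## Problem sizes used by the test-suite

Property suites run on 32×32×10 phantoms (the compact configuration in
the test helpers) and study-scale 64×64×16 phantoms for the recovery and
calibration checks; oracle comparisons use ≥ 20 random instances per
statistic. These sizes were chosen so the full suite exercises every
code path, including the study-scale geometry, while remaining quick to
run.

## Known limitations

* No bias-field correction or registration/resampling is provided; the
  bias phantom exists precisely to show when a global threshold breaks.
* Thresholding cannot distinguish pathologies that all raise STIR signal.
* Bone-marrow segmentation masks are inputs; no automatic segmentation.
* The shipped calibration defaults (4.15 / 2.64) come from a specific
  1.5 T protocol; new protocols should re-run `sweepK()` on their own
  labelled data.
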
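---
title: "Quantifying chemical ablation extent from CT and histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chemical ablation extent from CT and histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ablaquant)
```

## The problem

Ethanol ablation destroys tissue chemically: injected ethanol at a
sufficient concentration induces coagulative necrosis. Its weakness is
uncontrolled spread, and formulations that gel in situ (ethyl
cellulose–ethanol) are evaluated by how much tissue the injectate reaches at
a cytotoxic concentration and how much tissue actually dies. `ablaquant`
computes both: a CT-based estimate of the ethanol concentration field and
its thresholded distribution volume, and a histology-based reconstruction of
the necrotic volume from viability-stained serial sections, correlated per
specimen.

## Radiodensity calibration

CT radiodensity (Hounsfield units) decreases approximately linearly with
ethanol volume fraction, because ethanol is less dense than water. We anchor
an affine map at two measured standards,

$$c(x) = \frac{\mathrm{HU}(x) - \mathrm{HU}_{0\%}}
               {\mathrm{HU}_{100\%} - \mathrm{HU}_{0\%}},$$

with $\mathrm{HU}_{0\%}$ the 0% ethanol standard (a water vial in vitro; the
mean pre-ablation tissue radiodensity when quantifying in tissue, since
tissue is slightly more radiodense than water) and $\mathrm{HU}_{100\%}$ a
pure-ethanol vial. Assumptions: the relationship is linear over the range,
the standards are measured in the same session (per-session calibration
absorbs scanner drift), and sample thickness does not bias the reading.

Choices worth stating explicitly:

* **Concentrations are fractions internally.** The interface reports
  percentage points only at formatting time, avoiding double-scaling bugs.
* **`estimateConcentration()` never clips.** Values below 0 or above 1 are
  meaningful diagnostics (air reads far above 100%); exclusion policy
  belongs to the volumetrics stage, which applies it contextually.
* **Error decomposition.** The systematic component is the absolute
  difference between predicted and true concentration at known intermediate
  mixtures, in percentage points; real mixtures sit slightly above the
  two-point line, so this is nonzero even with perfect measurement. The
  sign convention (absolute value) is a package decision: the reference
  description of "difference between predicted and true" is sign-ambiguous,
  and the absolute value is the conservative summary. The random component
  is the mean per-sample HU standard deviation, also expressed as a percent
  of the calibration range $|\mathrm{HU}_{0\%} - \mathrm{HU}_{100\%}|$.
* **Sample sd uses the $n-1$ denominator** — conventional for finite vial
  ROIs; the choice is not prescribed by the method description.
* **Histogram bin width defaults to 5 HU** in `summarizeSample()`;
  unspecified upstream, configurable here.
* The ordinary least-squares fit of mean HU on concentration
  (`fitLinear()`) is a linearity diagnostic only; the two-point calibration
  is what converts images.

## Distribution volumetrics

`segmentDistribution()` keeps every evaluated voxel with estimated
concentration at least the cytotoxic threshold (default 0.20, because a
10-minute exposure to 20% ethanol is cytotoxic and imaging follows injection
within that window) and, optionally, at most an upper bound (default off;
1.20 for in-vivo data, where air bubbles introduced by surgery masquerade as
impossibly high concentrations). Everything that qualifies is kept,
including disconnected components — fragmented distributions are a real
outcome of pure-ethanol injections — and the 26-connected component count is
reported as a diagnostic.

The shape statistic is

$$\mathrm{aspect\ ratio} =
  \frac{\overline{\lVert x_i - \bar{x}\rVert}}{(3V/4\pi)^{1/3}},$$

the *radius of gyration* — implemented literally as the arithmetic **mean**
of voxel-center distances to the centroid, not the RMS convention — over the
*effective radius* of the equal-volume sphere. Under the mean-distance
definition a uniform solid ball scores exactly $3/4$ (the RMS convention
would give $\sqrt{3/5} \approx 0.775$); references that treat 1 as the
"spherical" value implicitly use a different normalization. We follow the
printed formula and expose the 0.75 solid-sphere constant in every
`DistributionResult` so users can renormalize. Distances are computed on
voxel centers in physical millimetre coordinates — the method description
does not say whether voxel or physical units were used; physical units are
the choice here because they generalize to anisotropic spacing — and are
unweighted by concentration. µL ≡ mm³ exactly; it is the only volume unit
exposed.

Degenerate inputs: an empty selection yields volume 0 and `NaN` aspect ratio
with a warning (never an error); a single voxel has radius of gyration 0 and
aspect ratio 0.

`cumulativeVolumeCurve()` evaluates the tissue volume at or above each
threshold on a regular grid from 0 in steps of 0.01, spanning up to
max(1.2, observed maximum) so the above-100% tail of in-vivo data is always
covered; the grid is a package choice (unspecified upstream).
`maxConcentrationProjection()` takes per-pixel maxima along a grid axis over
evaluated voxels only; the banded copy quantizes to 20-point bands by
`floor(c / 0.2) * 0.2` and clips to [0, 1] *for display only* — the
continuous image is untouched, so the clipping question for >100% voxels has
no analytic consequence.

Voxels outside the tissue mask carry the sentinel `NA` ("not evaluated")
from `toConcentration()` onwards and never enter volumes, curves,
projections or shape sums.

## Necrosis histomorphometry

The viability stain renders viable tissue blue and necrosis unstained, so
both segmentation steps run on the blue channel:

1. **Tissue** (`segmentTissue()`): local-entropy filter (stain texture has
   high entropy, slide background is flat) → binarize at a user threshold →
   delete components under 15 000 connected pixels → erode with a flat
   structuring element of 15 px → fill holes → dilate with the same element.
   The order is fixed and consequential: eroding before hole-filling keeps
   genuinely open slits open, while dilating first would seal them; a golden
   fixture in the test suite pins this down. The masked copy of the original
   image (background zeroed) feeds the next step.
2. **Necrosis** (`segmentNecrosis()`): pixels with blue *below* a user
   threshold within the tissue mask → delete components under 5 000 px →
   retain the five largest by pixel count → drop user-excluded regions.
   Exclusions (e.g. large vasculature caught by the same threshold) are
   supplied as indices in the retained size order — a reproducible,
   batch-friendly replacement for interactive clicks. The five-largest rule
   is applied *before* exclusions, matching the order in which the steps
   are described.

Necrotic volume is the Cavalieri sum $\sum_i A_i \cdot s$ over serial
sections with area $A_i$ (cm²) and step $s$ (mm); units convert exactly
(1 cm² · 1 mm = 100 µL) and the conversion is centralized and tested.

Parameter defaults and their reasoning:

| parameter | default | unit | why |
|---|---|---|---|
| entropy window | 9 × 9 | px | the common local-entropy default; unspecified upstream |
| entropy bins | 64 | levels | resolves 8-bit stain texture at reasonable cost |
| tissue threshold | user | fraction of max entropy | operator-chosen per slide; normalization by the maximal window entropy makes it a [0,1] fraction |
| tissue min region | 15 000 | px | stated small-region rule |
| structuring element | disc, r = 15 | px | "15-pixel neighbourhood" is shape-ambiguous; the disc is isotropic (a square option exists) |
| necrosis threshold | user | blue fraction | operator-chosen; `suggestNecrosisThreshold()` logs an Otsu suggestion as a reproducibility aid |
| necrosis min region | 5 000 | px | stated rule; a 5 000-px component is *kept* (the rule removes `< 5000`) |
| retained regions | 5 | — | stated five-largest rule |
| 2D connectivity | 8 | — | common region-labelling default; unspecified upstream |

`compareToManual()` reports both the mean signed difference (auto − manual)
and the mean absolute per-pair difference. The two reference summaries of
this comparison are mutually inconsistent (an absolute mean smaller than the
signed mean is impossible for paired per-slide differences), so the package
reports both statistics and asserts neither reference value.

## Synthetic data: what it emulates, and what it does not

All fixtures are generated with seeded RNG and analytic truth records.

* **Vials** (`makeVials()`): Gaussian HU readings per vial. Defaults are the
  study conditions: 0/25/50/75/100% ethanol, 20 vials per level, endpoint
  means −66.5 and −340.3 HU with sds 20.3 and 29.1 HU. Intermediates carry a
  positive radiodensity bias of 7.7% of the calibration range — the scale of
  the reported systematic non-linearity — and sd 18.2 HU, which makes the
  across-level mean per-vial sd 20.8 HU (7.6% of the range). The fixed bias
  reproduces the *mean* non-linearity error; the across-vial spread of that
  error in real sessions (which a fixed bias cannot produce) is not
  emulated.
* **Injection phantoms** (`makeInjectionPhantom()`): tissue ellipsoid
  (60 HU) in buffer (0 HU) with ellipsoidal inclusions written as
  $\mathrm{HU} = \mathrm{HU}_{tissue} + c\,(\mathrm{HU}_{100\%} -
  \mathrm{HU}_{tissue})$, so in-tissue calibration recovers $c$ exactly when
  noise-free; air bubbles at −1000 HU (the Hounsfield definition) and
  low-radiodensity pockets (default 30 HU) as confounders. Noise is i.i.d.
  Gaussian per voxel — real CT noise is spatially correlated and the
  reference provides only mean/sd summaries, so independence is a declared
  simplification. Default grid 64³ at 0.25 mm.
* **Slide series** (`makeSlideSeries()`): sections every 1 mm through a
  necrotic ellipsoid; viable tissue is blue-dominant (RGB 0.45/0.50/0.80)
  with 6% multiplicative speckle so the entropy filter has texture signal,
  necrosis is unstained gray (0.74/0.72/0.62, 5% speckle), background is
  flat. Region boundaries are crisp; real slides have stain gradients,
  tears, folds and out-of-focus blur that this generator does not attempt.
  Recommended thresholds for these fixtures: tissue 0.3, necrosis 0.72
  (between the two blue levels).

Passing tests on these fixtures demonstrate that the *computations* are
correct against analytic truth — threshold volumetrics, the shape statistic,
morphology order, selection rules, unit chains — not that the thresholds or
the segmentation generalize to real stained tissue, where operator-chosen
thresholds remain essential.

## Numerical choices and problem sizes

* Connected components are labelled via an adjacency graph (igraph), giving
  exact 8-/26-connectivity in 2D/3D; labels are ordered by decreasing size.
* The local-entropy filter truncates windows at image borders and
  normalizes by the maximum attainable window entropy, so thresholds are
  resolution-independent fractions.
* Cumulative curves count `values >= threshold` by binary search on the
  sorted voxel values; the curve is exactly right-continuous on its grid
  and definitionally consistent with `segmentDistribution()` at every grid
  point.
* Tie-breaks in the five-largest rule follow label order (first-encountered
  component wins among equal sizes).
* The test suite and the acceptance script run on 48³–128³ phantoms,
  400–600 px slide images and series of 5–8 sections — sizes at which the
  analytic-truth comparisons above are tight while a full run stays in the
  minutes range on one CPU.

## Limitations

* No image registration: pre- and post-ablation volumes are assumed
  aligned, as when the specimen is imaged in place.
* No beam-hardening or scanner-drift modelling; the per-session two-point
  calibration is the only correction.
* NIfTI-1 is the supported volume format; histology images are TIFF/PNG.
* Statistical inference across groups (ANOVA-style testing) is out of
  scope; the report carries means, sds and fold changes only.
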
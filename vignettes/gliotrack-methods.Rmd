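---
title: "Methods: quantifying early microgliosis and late optic-nerve gliosis"
author: "gliotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying early microgliosis and late optic-nerve gliosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

In chronic glaucoma, retinal ganglion cell axons degenerate in the optic
nerve with an onset and severity that vary widely between eyes, even within
an inbred strain such as the DBA/2J mouse. Microglia — the tissue-resident
immune cells of the retina — respond to neuronal stress long before overt
pathology: they accumulate at the optic nerve head (ONH), where axonopathy
first manifests, and their somata enlarge as they activate. Because a GFP
reporter in the fractalkine-receptor locus makes these cells visible in the
living eye through a confocal scanning laser ophthalmoscope (cSLO), the
degree of early microgliosis can be monitored month by month and then
confronted, in the same eyes, with the severity of optic-nerve degeneration
measured histologically many months later.

`gliotrack` implements that entire quantitative chain as reusable, tested
code: image morphometry of the live retina, ONH cell counting, gliosis
quantification on nerve cross-sections, and the cohort statistics that link
the two ends. Because no per-eye raw data are published for the original
cohort, the package ships first-class synthetic generators that emulate the
study design with known ground truth; all validation is performed against
those phantoms.

# Cell morphometry in the live retina

## Segmentation model

A cSLO fluorescence frame is modeled as bright cell somata (plus dimmer,
thin processes) over a roughly uniform noisy background. Segmentation is a
robust two-level intensity-threshold scheme:

1. **Background**: the median image intensity. Cells occupy a small fraction
   of the field, so the median is an unbiased background estimate, and the
   MAD a robust noise scale.
2. **Cell mask**: pixels brighter than `median + k · MAD`, with `k = 5` by
   default. Five noise standard deviations makes isolated false pixels
   vanishingly rare on megapixel frames; components below `minComponentPx`
   (3 px) are discarded as residual speckle.
3. **Soma mask**: within each connected component, pixels above a fixed
   fraction (default 0.6) of that component's peak intensity. Somata are the
   brightest, most compact part of a microglial cell in cSLO, so a
   peak-relative cut isolates them from the fainter arbor. Peaks and the
   soma mask are computed on a lightly smoothed (σ = 1 px) copy so a single
   noisy pixel cannot set a component's peak.
4. **Splitting**: when one component carries several soma-level blobs with
   centers more than 5 µm apart, it is split into one cell per soma and the
   component's pixels are divided among somata by seeded region growing;
   blobs closer than 5 µm are merged, keeping the brighter peak.

Soma areas are pixel counts times `pixelScale²`. Coordinates follow the
image convention: origin at the top-left pixel center, x rightward, y
downward, 0-based pixels, physical µm = pixel × scale.

## Activation classes

Activation is a pure function of soma area: **activated** above 50 µm²,
**non-activated** on the closed interval [10, 50] µm², **small** below
10 µm². The activated/non-activated boundary is set at the conservative
lower edge of the 50–60 µm² range used in the field, and both edges are
configuration parameters (`activationAreaMin`, `nonactivatedAreaMin`).

## Radial sectors

Cells are mapped to eight 45° wedges over the annulus between the ONH
exclusion radius (125 µm, matching the 250-µm counting circle) and an outer
radius of 724.5 µm chosen so the annulus covers ≈ 1.6 mm² of central retina
— the analyzed field in this imaging protocol. Angles are measured
counter-clockwise from +x as the image is displayed. Boundary convention:
a radial distance exactly on a bound belongs to the inner region, so a cell
at exactly 125 µm is excluded from sectors while one at exactly the outer
radius is included. (A sector *area* of ~0.2 mm² follows from this geometry;
a literal 200 µm² per sector would be dimensionally inconsistent with eight
sectors tiling more than a square millimetre.)

# ONH microgliosis

ONH microgliosis is the number of cells whose centroid falls within a
250-µm-diameter circle centered on the optic disc, boundary inclusive. The
circle's area is 0.0491 mm², within 2% of 0.05 mm², so the raw count is
reported unchanged under the conventional label "cells per 0.05 mm²"; an
exact-area-normalized density is emitted alongside. Counts may come from
`segmentCells()` or from a manual-count table with the same columns.

`compareTreatment()` reports the unpaired two-tailed Student t-test between
pre- and post-treatment counts — the convention for this comparison — plus
the design-matched paired t-test in clearly separate fields, since the
samples are the same eyes measured twice. Both are returned; the unpaired
statistic is the primary one.

# Nerve gliosis

As axons are lost, optic-nerve cross-sections fill with reactive glia and
scar. On PPD/Toluidine-stained plastic sections imaged in RGB, axon-free
tissue is brighter in the red channel than the myelinated axonal field, so
the glial mask is obtained by thresholding the red channel over the
*eligible* region — the nerve outline minus vascular lumina and the
meningeal sheath, which are neither axonal nor glial tissue.

The "automatic threshold" is Otsu's method computed on the eligible pixels
only, with a fixed-threshold override (`gliosisConfig("fixed")`). Otsu
always splits a histogram, even a unimodal one, which would hallucinate
~50% gliosis in a perfectly healthy nerve; the split is therefore accepted
only when the two classes are genuinely separated (class-mean distance
≥ 4 pooled within-class standard deviations — splitting a single Gaussian
mode yields ≈ 2.6, a real axonal/glial bimodal histogram ≥ 6). Components
smaller than 20 µm² are removed and holes under 20 µm² filled before
measurement, suppressing staining speckle.

The glial fraction is `100 · |glia ∩ eligible| / |eligible|`; by
construction, intensities of excluded pixels can never change it. Damage
categories are **low** < 20 %, **medium** [20, 40] % (closed, since the
neighboring definitions are "less than 20%" and "more than 40%"), **high**
> 40 %. The threshold is computed per nerve, not per batch: sections are
acquired and stained independently, so a per-section automatic threshold is
the more robust default.

Repeatability between two "raters" is emulated by segmenting the same
sections with two parameterizations (automatic vs fixed threshold) and
averaging the per-section relative difference in glial area,
`|A − B| / mean(A, B)`.

# Cohort statistics

- Ties are handled by midranks everywhere; ONH counts are small integers,
  so ties are the norm.
- Kruskal–Wallis uses the χ² approximation with k − 1 df (exhaustively
  degenerate inputs — all values identical — return H = 0, p = 1).
- Spearman's rho is computed on midranks; p-values come from the
  t-distribution approximation by default or from a permutation null: full
  enumeration of all n! pairings for n ≤ 8 (exact), otherwise B seeded
  permutations with the add-one estimator `(1 + #extreme)/(B + 1)`, keeping
  sampled p-values in `[1/(B+1), 1]`.
- The early-count predictor for the microgliosis–gliosis correlation is the
  3-month count, falling back to the 4-month count when that visit is
  missing.
- The mixed model is the minimal random-intercept specification
  `count ~ age + (1 | eye)` fitted by lme4, with Satterthwaite p-values via
  lmerTest. The repeated-imaging check adds the number of *prior* imaging
  sessions of the eye as a fixed covariate. On a fully balanced grid that
  covariate is exactly collinear with age, so the effect is reported as
  unidentifiable rather than silently dropped; with staggered or incomplete
  observation (the realistic case) it is estimable. Random slopes and
  richer covariance structures are deliberately out of scope.
- The test battery reports raw p-values without multiplicity correction, as
  is conventional for this analysis; a Holm-adjusted column over the
  t-test/Kruskal–Wallis family is emitted additionally and clearly labeled.

# Synthetic data: what the phantoms emulate

## Retina phantoms

A 1.5 × 1.5 mm field at 1 µm/px carries 250 parenchymal cells tiling the
retina outside a 100-µm ONH disk plus 15 cells clustered inside it —
matching the 200–300 parenchymal cells and central ONH cluster seen in this
imaging protocol. Soma areas follow a three-component Gaussian mixture
(weights 0.10/0.75/0.15, means 7/28/70 µm²) spanning the small,
non-activated and activated classes. Each cell is rendered as a filled soma
disk at peak intensity (background 30 + amplitude 120) with 0–4 one-pixel
process strokes at 40% of the soma peak, then blurred (σ = 0.8 px,
emulating optical spread) and degraded with Gaussian noise (σ = 8, i.e.
peak SNR 15). Centers are rejection-sampled with a 20-µm minimum spacing
(10,000 attempts per cell, then a hard error — a bounded runtime with a
clear failure mode).

Not emulated: the ophthalmoscope's PSF and eye-motion artifacts,
vasculature and perivascular cell rows, vignetting, and arbor morphology
beyond token strokes. Passing recovery tests on these phantoms therefore
demonstrates correctness of the measurement chain on blob-like cells at
realistic density and SNR, not robustness to every cSLO artifact.

## Nerve phantoms

A circular nerve (default radius 175 µm at 0.5 µm/px) with a 10-µm
meningeal ring and three vascular lumina (8–20 µm radius). The glial ground
truth is grown from seeded patches by iterative dilation inside the
eligible region until it occupies the target fraction to within one pixel,
so re-measuring the returned masks reproduces the request by construction.
Rendering: dark mottled axonal field (0.35 with correlated texture),
brighter glia (0.75), bright meninges/vessels, white background, σ = 1 px
blur and σ = 0.02 noise on the [0, 1] red channel. Axon-count realism and
stain color deconvolution are out of scope.

## Cohort simulator

Each eye draws a latent severity `s ~ Uniform(0, 1)`. Expected counts are
the age baseline — 10, 13.17, 16.85, 16.46, 19.93 mean cells per ONH at
months 1–5, the observed age trend in young DBA/2J eyes — scaled by
`exp(effectSize · (s − 0.5))`; counts are Poisson (non-negative small
integers). The late outcome is `10 + 55·s` percent glial area plus Gaussian
noise (sd 5), clipped to [0, 100], spanning the observed range of category
means (≈ 15–59 %). `effectSize = 0` is the exact null (counts independent
of outcome); the default `effectSize = 1` reproduces the reported 5–30
cells-per-ONH spread and a strong positive early–late correlation. An
optional `observeProb < 1` thins the visit grid, which is what makes the
repeated-imaging covariate identifiable in the mixed model.

# Numerical choices and degenerate inputs

- All generators consume an explicit integer seed and restore the caller's
  RNG state; identical parameters and seed give bit-identical images, masks
  and tables. The pipeline derives per-stage substreams from one root seed
  by stable string hashing, so stage reproducibility does not depend on
  execution order.
- A constant or pure-noise image yields an empty cell table, not an error;
  non-finite pixels are an error.
- Degenerate statistics are explicit: zero variance with equal means gives
  t = 0, p = 1; with unequal means it is flagged; all-identical values give
  H = 0, p = 1; zero-variance Spearman inputs return a flagged `NA` rho.
- Boundary ties: activation and damage bins are closed exactly as stated
  above; the ONH counting circle includes its boundary; sector bounds
  belong to the inner region.

# Problem sizes used in validation

The shipped test-suite and acceptance script validate on: ten full-size
retina phantoms (1500² px, 265 cells each) for segmentation recall,
precision and soma-area error; ten nerve phantoms spanning 15–55 % gliosis
for repeatability plus six targets (10–60 %) for fraction recovery; 2,000
null replicates for type-I calibration; 500 simulated 40-eye cohorts for
null-uniformity of the correlation p-value; and six replicate 50-eye
cohorts for mixed-model slope recovery. These sizes give stable Monte-Carlo
estimates while keeping a full validation run in the minutes range on one
CPU.

# Known limitations

- The bimodality guard means a nerve that is essentially *all* glia (no
  axonal mode left) would be scored as glia-free; fractions this extreme
  are outside the biological range the categories were designed for and can
  be handled with the fixed-threshold override.
- Soma areas are measured on thresholded pixel sets and carry a few percent
  of discretization bias for the smallest cells; the validated guarantee is
  a mean absolute relative error within 15 % for 20–100 µm² somata at
  1 µm/px.
- The mixed model tests a repeated-imaging artifact only as a linear
  prior-visit-count effect with a random intercept; trajectory modeling is
  out of scope.
- Monthly frames are joined per eye by identifier, not by pixel-level
  registration.
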
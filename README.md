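# gliotrack

Quantitative analysis linking **early retinal microgliosis**, observed in the
living eye, to **late optic-nerve degeneration** in chronic glaucoma.

In the DBA/2J mouse, an inherited model of pigmentary glaucoma, retinal
ganglion cells degenerate with an onset and severity that vary widely between
eyes. Months before any detectable nerve pathology, microglia (imaged in vivo
with a GFP reporter by confocal scanning laser ophthalmoscopy, cSLO) cluster
and enlarge at the optic nerve head (ONH). `gliotrack` implements the full
quantitative pipeline for testing whether that early microgliosis predicts
later damage:

- **Cell morphometry** — intensity-threshold segmentation of GFP⁺ cells in
  retinal images, per-cell soma areas, activation classes by soma area
  (*activated* > 50 µm², *non-activated* 10–50 µm², *small* < 10 µm²), and
  mapping to eight 45° radial sectors over the central-retina annulus around
  the excluded ONH.
- **ONH microgliosis** — cell counts inside a 250-µm circle on the optic disc
  (area 0.0491 mm², so the count doubles as "cells per 0.05 mm²"), per-eye
  longitudinal timelines, and pre/post treatment comparisons.
- **Nerve gliosis** — automatic (Otsu) threshold segmentation of the
  non-axonal (glial/scar) area on the red channel of nerve cross-sections,
  with vessel and meninges exclusion; the glial fraction
  `100·|glia ∩ eligible| / |eligible|` is the severity readout, categorized
  as low (< 20 %), medium (20–40 %) or high (> 40 %) gliosis.
- **Cohort statistics** — group mean ± s.e.m. summaries, unpaired two-tailed
  Student t-tests, Kruskal–Wallis rank tests (midrank ties, χ² p), Spearman
  rank correlation with an exact/sampled permutation option, and a linear
  mixed model (`count ~ age + (1 | eye)`) with a repeated-imaging covariate
  check.
- **Synthetic phantoms** — seeded generators for retina mosaics (200–300
  cells with known soma areas plus an ONH cluster), nerve sections with a
  controllable glial fraction, and longitudinal cohorts in which a latent
  per-eye severity drives both early counts and the late glial fraction.
  Every stage of the pipeline is validated against this ground truth.

## Worked example

Score a synthetic nerve section and correlate early counts with late outcome
on a simulated 41-eye cohort:

```r
library(gliotrack)

ph <- generateNervePhantom(nervePhantomParams(targetGlialFraction = 30, seed = 7))
scoreNerveSection(ph$section)
#> GliosisResult 'phantom': glial fraction 30.05% of 8.36e+04 um^2 eligible
#>   nerve area -> medium gliosis

tab <- simulateCohort(cohortSimParams(nEyes = 41, seed = 7))
eo  <- earlyCountOutcome(tab)      # 3-month count (4-month fallback) per eye
spearmanCorr(eo$early_count, eo$glial_fraction_pct)
#> StatResult 'spearman': rho = 0.8035, p = 2.55e-10 (n = 41;
#>   t-distribution approximation (two-sided))

groupSummary(eo$early_count, classifyDamage(eo$glial_fraction_pct))
#>    group  n     mean      sem
#> 1   high 16 22.31250 1.368450
#> 2    low  9 11.77778 1.037863
#> 3 medium 16 14.87500 1.217494
```

The phantom's recovered glial fraction (30.05 %) reproduces its constructed
30 % target; on the simulated cohort, eyes heading for high gliosis showed
the highest early ONH counts (22.3 vs 11.8 mean cells per ONH), and the
early-count/late-gliosis Spearman correlation is strongly positive.

`runDemo(seed, outDir)` executes the whole study end to end (cohort
simulation, phantom imaging, morphometry, ONH counts, nerve scoring, the
statistics battery) and writes all CSV tables plus a checksummed run
manifest; identical seeds give byte-identical tables. A thin command-line
wrapper lives at `inst/scripts/gliotrack.R`.

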
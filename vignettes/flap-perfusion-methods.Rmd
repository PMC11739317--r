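---
title: "Quantifying mastectomy skin-flap perfusion from ICG angiography"
author: "icgaFlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mastectomy skin-flap perfusion from ICG angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgaFlap)
```

## The clinical problem

After a skin- or nipple-sparing mastectomy, the preserved skin envelope
(the mastectomy skin flap, MSF) must survive on the perfusion left in
the subdermal plexus. A poorly perfused flap is at risk of partial- or
full-thickness necrosis, which can cost an immediate implant-based
reconstruction. Intraoperative indocyanine green angiography (ICG-A)
images this perfusion directly: an intravenous ICG bolus bound to plasma
proteins fluoresces under near-infrared light, and a camera films its
arrival, plateau and washout through the flap over roughly three
minutes.

`icgaFlap` turns such a recording plus two operator-drawn regions of
interest (the ipsilateral breast and the nipple) into a small set of
quantitative reads:

* a **plateau-phase perfusion map** (the stable image between arterial
  inflow and venous washout);
* a **relative perfusion unit (RPU)** map, with the brightest in-flap
  point set to 100;
* the **hypoperfused region** — breast pixels outside the nipple with
  RPU strictly below 30;
* the **hypoperfused-area percent ratio** — hypoperfused area divided by
  the ipsilateral breast area, times 100 — with two flags on it: a
  *decision rule* at 15 % (consider delayed reconstruction or close
  postoperative wound monitoring) and an *eligibility screen* at
  one-third (flaps beyond it are outside the intended use of the
  criterion);
* cohort-level **diagnostic accuracy statistics** for the binary
  "hypoperfused flap" predictor against observed necrosis.

Relative rather than absolute units matter here: the raw gray-level
intensity (the "absolute perfusion unit", 0–255 on common devices)
depends on camera settings, ICG dose and acquisition timing, while the
ratio to the best-perfused point in the same image largely cancels those
factors. Every stage downstream of the perfusion map is therefore
invariant to rescaling all intensities by any positive constant, and the
test suite asserts exactly that.

## The pipeline, stage by stage

### Phase detection

The mean intensity over the breast ROI gives a bolus curve $c(t)$. The
plateau window is located by two threshold fractions of its maximum:

* `arterialEnd` — the first frame with $c \ge 0.95\,\max c$;
* `venousStart` — the last frame with $c \ge 0.90\,\max c$.

The maximum frame satisfies both rules, so the window is never empty and
always contains the argmax. The fractions (0.95 rise, 0.90 fall) are
design choices, exposed in `runConfig()`: on a flat-topped bolus curve
they bracket the visually stable segment, and on a curve with no true
plateau (a sharp peak) they degrade gracefully to a window around the
peak. Note the asymmetry is deliberate — a washout at rate $k$ spends
$\log(1/0.90)/k$ seconds above the fall threshold (about 5 s at the
default simulation rate of 0.02/s), so the detected window may extend
slightly into early washout. This is harmless for the median aggregate
and, because washout scales all pixels by the same factor, harmless for
RPU under any aggregate.

Phase logic is index-based on the sampled curve; timestamps are carried
as metadata but never interpolated. An all-zero curve (no perfusion
signal) is a hard error, not an empty result.

### Plateau map and RPU

`extractPerfusionMap()` aggregates the plateau frames per pixel, by
default with the median (robust to frame flicker); a single
operator-chosen frame is supported to mirror the frozen-screen clinical
workflow, and on noise-free input all choices agree. `computeRPU()`
divides by the chosen normalizer — by default the maximum in-ROI
intensity, i.e. "the point with the highest perfusion" reads 100 — and
clips to [0, 100]. A percentile below 100 (99 is a reasonable choice for
sensors with hot pixels) is supported and announced via a message
whenever it is used, since it changes the meaning of "100".

### Segmentation and the area ratio

The hypoperfused region is `breast & !nipple & (RPU < cutoff)` with the
default cutoff 30. Two conventions are fixed deliberately:

* **Strict inequality.** "Below 30 %" means RPU = 30.0 is *not*
  hypoperfused; the tests pin this with a pixel placed exactly at the
  cutoff.
* **The nipple never counts.** After nipple-sparing mastectomy the
  nipple–areolar complex routinely reads under 30 RPU (peri-areolar
  dye injection for sentinel-node mapping is one suspected cause)
  without progressing to necrosis, so nipple pixels are excluded from
  the numerator no matter their RPU.

Connected components smaller than `minComponentPx` (default 25 px,
8-connectivity) are then removed as sensor speckle. The raw per-pixel
rule is recovered with `minComponentPx = 1`; the area ratio is monotone
nondecreasing in the cutoff and nonincreasing in the component floor,
and both properties are tested. The field's criterion is stated for
"any" sub-cutoff area without a minimal-extent qualifier; the component
floor is our explicit, configurable proxy for the implicit visibility
threshold of a human reading a screen.

The percent ratio divides by the **full breast ROI including the
nipple**. The denominator convention is not fully pinned down by the
criterion's wording ("the ipsilateral breast area"); we take the words
at face value and include the nipple, and note that with typical nipple
ROIs (a few hundred pixels against tens of thousands) the two
conventions differ by well under one percentage point.

A pixel is a pixel: masks are used at the resolution of the recording,
row-major with no resampling, and all areas are pixel counts.

## The synthetic-data generator

No clinical recordings ship with the package, so the generator is the
test bed for every image-level claim. It emulates:

* **Geometry** — an elliptical breast ROI with a circular nipple
  (`makeBreastDomain()`); both stand in for the operator-drawn ROIs.
* **Perforator territories** — a nearest-seed (Voronoi) partition of
  the breast pixels (`makeTerritories()`; ties broken toward the lowest
  territory id, so labelling is deterministic given the seed).
  Hypoperfusion is modelled as *territory dropout*: selected
  territories have their plateau intensity multiplied by a factor in
  [0, 1], emulating damage to the perforator feeding them.
  `chooseDropoutIds()` selects a territory subset whose area best
  matches a prescribed ground-truth fraction by exact subset-sum;
  territories smaller than the segmentation speckle floor are never
  used for dropout, since anatomical perforator-territory loss is
  sizable and truth built from speckle-sized fragments would be
  unrecoverable by design.
* **Kinetics** — each pixel follows a piecewise bolus curve: linear
  rise to the plateau level at `timeToPeak` (default 30 s), constant
  plateau until `washoutStart` (default 120 s), then exponential decay
  at `washoutRate` (default 0.02/s). This is the minimal form with the
  three named phases; the defaults describe a recording that starts at
  injection and runs 3 min (91 frames at one per 2 s), consistent with
  the clinical protocol the package targets (4 mL ICG at 2.5 mg/mL,
  recording started at injection). Frame rate and bit depth of the
  clinical device are not public; one frame per 2 s and 16-bit storage
  are implementation choices.
* **Background and noise** — pixels outside the breast sit at 1 % of
  the plateau level, so normalization is only correct *inside* the ROI
  (as in the clinical workflow, where the target area is what the
  operator outlines); zero-mean Gaussian sensor noise is added per
  pixel per frame and clamped at zero, intensities being nonnegative
  counts. Default noise in the acceptance runs is 5 % of the plateau
  level.
* **Cohorts** — `simulateCohort()` draws necrosis with a configured
  prevalence and a binary predictor with configured
  sensitivity/specificity, plus outcome-independent covariates, for
  calibration tests of the diagnostics module.

Each case carries its ground truth (`truthHypoMask`,
`truthAreaFraction`, same denominator convention as the pipeline), and
a single seed governs the whole case with a documented stream order, so
cases are bit-reproducible.

**What the generator does *not* emulate** — and hence what passing
tests do not show about clinical data: light transport and scattering
in tissue (territory boundaries are perfectly sharp, real ones are
gradients), pharmacokinetic dispersion of the bolus (all pixels share
one time course up to a scale factor), patient or camera motion,
specular reflections and field-of-view vignetting, methylene-blue
interference around the nipple, and Poisson photon statistics (noise is
Gaussian). Recovery being *exact* at zero noise is a property of this
idealization; on real data the pipeline's accuracy is bounded by ROI
drawing and the gray zone at the cutoff, not by the arithmetic tested
here.

## Diagnostics

`diagnosticMetrics()` computes sensitivity, specificity, PPV and NPV
with exact Clopper–Pearson intervals (via the closed-form beta
quantiles; checked against `binom.test()`). The exact interval was
chosen because the counts this package typically sees are tiny (a
handful of true positives); Wald intervals would be badly anti-
conservative. Metrics with zero denominators are reported as missing,
never as zero.

`fisherExactTwoSided()` uses the probability-mass two-sided convention
(sum over margin-fixed tables no more probable than the observed one,
with a 1e-7 relative tie tolerance) — the convention of mainstream
statistical software, implemented by `stats::fisher.test()`, which this
function wraps. The test suite verifies it against an independent full
enumeration of all margin-consistent tables on hundreds of random small
tables, and checks invariance under transposition and row/column swaps.

`summaryTTest()` computes Student's (pooled) or Welch's two-sample t
test directly from group means, SDs and sizes, because demographic
tables publish summaries, not raw data. The pooled form is the default
(classical Student's t, the test named in the protocols this package
follows); published p-values reproduce within the rounding of the
printed summaries (±0.005). `cohortReport()` renders a demographics
table: means ± SD with t tests for continuous variables, counts with
Fisher tests for categorical ones, descriptive-only when there is a
single group, p-values formatted to three decimals with `<0.001` below
threshold.

`referenceCohort()` bundles a deterministic 53-breast cohort whose
confusion counts (tp 8, fp 1, fn 0, tn 44), per-case area ratios and
outcome classification reproduce the package's reference results; it
codes the one predictor-positive case without recorded necrosis as the
single false positive. Ages and BMIs of the predictor-negative rows are
normal quantiles matched to the group summaries, so the object carries
no RNG state.

## Numerical and design choices, in one place

| choice | value | why |
|---|---|---|
| RPU cutoff | 30 (strict `<`) | clinically established; blue on common color LUTs |
| decision threshold | 15 % | change strategy / close follow-up above it |
| eligibility screen | 100/3 % | flaps beyond one-third hypoperfused are screened out |
| normalizer percentile | 100 | "highest perfusion point = 100"; 99 for noisy sensors, logged |
| component floor | 25 px, 8-conn | speckle suppression; 1 restores raw thresholding |
| phase fractions | 0.95 / 0.90 | flat-top bracketing, see above |
| plateau aggregate | median | robust; single-frame supported |
| ratio denominator | breast incl. nipple | face-value reading of "ipsilateral breast area" |
| CI method | Clopper–Pearson | tiny cell counts |
| Fisher two-sided | probability mass | mainstream software convention |
| t test | pooled by default | classical Student's t; Welch available |

Degenerate inputs are defined, not accidental: an all-zero ROI curve or
perfusion map raises "no perfusion signal"; a zero-radius nipple is an
empty mask; both-SDs-zero summary t tests return p = 1 (equal means) or
p = 0 with a warning; empty frame-time vectors, non-monotone
timestamps, sidecar/stack row mismatches and out-of-vocabulary cohort
codes are all distinct, named errors.

## Problem sizes in the shipped tests

The test and acceptance runs use 80–200 px square domains, 91-frame
recordings, 5–100 territories, cohorts up to n = 5000 and 10,000
coverage replicates. These sizes make every property decisive (pixel
counts in the tens of thousands, binomial standard errors well under
the asserted tolerances) while a full run stays comfortably
interactive; all of them scale up linearly in code if heavier
validation is wanted.

## Known limitations

* ROIs are inputs: the package does not segment the breast or nipple
  from the images, because the clinical workflow draws them by hand.
* No motion correction between frames; the workflow images a fixed
  patient, and registration is out of scope.
* The 30 % cutoff and 15 % rule are fixed clinical conventions here,
  not fitted: the package deliberately does not search ROC-optimal
  thresholds.
* Single-predictor statistics only; no multivariate modelling of
  necrosis risk (the cohorts this targets are too small to support it).
* The device's native file formats and on-screen color mapping are not
  reproduced; input is plain multi-page TIFF plus a timestamp CSV.
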
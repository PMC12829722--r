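---
title: "Quantifying EUS elastography: methods and design notes"
author: "eusei package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EUS elastography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eusei)
```

## The problem

Strain elastography on endoscopic ultrasound (EUS-E) overlays a colour map
of relative tissue stiffness on the grayscale B-mode image: stiff tissue is
rendered blue, soft tissue red. For gastrointestinal stromal tumors
(GISTs), stiffness correlates with malignant potential, but conventional
reading of the overlay is qualitative and operator-dependent. This package
turns the overlay into a number: a 0-1 **elasticity index** computed from
the colour pixels inside a lesion mask, which can then drive patient-level
risk stratification (low- vs high-risk malignant potential, collapsing the
four NIH consensus categories two-and-two).

## The elasticity index

A dual-panel EUS-E export carries the B-mode panel on the left, the colour
elastogram on the right, and a bright vertical marker band between them.
Quantification of one frame proceeds in fixed order:

1. **Split.** The marker band is located by scanning the central 40-60% of
   the frame for columns whose mean luma exceeds the band's median by a
   contrast floor (default 30 luma units); without a detectable marker the
   frame midline is used and the result flagged. The two panels must agree
   in width within 2 px (a wider right panel is trimmed, a narrower one
   edge-padded); anything worse is a geometry error, never a silent
   rescale.
2. **Mask transfer.** Because the elastogram is an overlay on the same
   acquisition geometry, the lesion mask drawn on the B-mode panel maps to
   the elastogram by identity in panel-local coordinates - a rigid
   horizontal translation of the crop, no registration.
3. **Solid-component restriction.** Anechoic (cystic) regions carry no
   strain signal, so mask pixels whose B-mode luma falls below `solidTau`
   (default 20/255) are removed before any colour is read.
4. **Colour-pixel selection.** The overlay is semi-transparent: grayscale
   underlay shows through where the overlay is absent. A pixel counts as
   colour when its saturation is at least `sMin` (0.15) and its value at
   least `vMin` (0.10). If fewer than `minColorFraction` (10%) of the
   solid pixels are coloured, the frame is rejected as poor quality rather
   than quantified.
5. **Average, project, rescale.** The retained pixels are averaged
   per-channel in RGB at full precision, the mean is converted to HSV, and
   the nearest entry of the blue-to-red colormap is found by minimising
   $(\Delta h_{\mathrm{circ}}/180)^2 + \Delta s^2 + \Delta v^2$, with
   $\Delta h_{\mathrm{circ}}$ the circular hue difference in degrees. The
   matched 0-based index $i$ of an $N$-entry map gives the elasticity
   $E = i/(N-1)$: 0 is stiffest (blue), 1 softest (red).

Averaging is performed in RGB *before* the HSV conversion deliberately:
that is the natural reading of the extraction procedure this index
formalises, and it differs from averaging hues directly (which would need
circular statistics and would weight desaturated pixels equally). The
full audit trail - mean RGB, mean HSV, matched entry, distance, pixel
counts at every stage, QC flags - is retained in the result object.

### The colormap

No vendor publishes the exact lookup table, and the only quantitative
anchor available is the blue-0 / red-255 scale, so the canonical map is a
linear hue sweep from 240° (blue) to 0° (red) at full saturation and
value, with $N = 256$ entries, quantised to 8-bit RGB. Quantising matters:
a colour painted into an 8-bit raster and read back then matches its table
entry *exactly*, which is what makes the uniform-recovery property
($E = k/255$ exactly for a lesion painted with entry $k$) testable with
zero tolerance. Alternative device maps can be supplied as CSV
(`readColormapCsv()`); hue must still decrease monotonically for the
elasticity orientation to be meaningful.

Numerical conventions, chosen once and fixed:

* **Hue scaling in the distance.** Dividing the circular hue difference by
  180 makes one half-turn of hue commensurate with the full saturation and
  value ranges; the metric is otherwise unweighted Euclidean.
* **Ties** in projection distance resolve to the lower (stiffer) index -
  the conservative direction for a malignancy screen.
* **Achromatic input** (mean saturation below 0.05) has no meaningful hue;
  the projection is refused with an error rather than returning a
  fabricated elasticity.
* **Cutoff classification** uses a strict inequality: elasticity strictly
  below the cutoff is called high risk.

## Patient-level stratification

Per-frame indices are averaged per patient (mean by default, median by
option); the orientation throughout is *lower elasticity = higher
malignant potential*. The ROC curve enumerates cutoffs at midpoints
between consecutive distinct values (plus infinite sentinels), the AUC is
the trapezoidal area, and the operating point maximises the Youden index
$J = \mathrm{sens} + \mathrm{spec} - 1$, with ties resolved first toward
higher sensitivity, then toward the lower cutoff. Midpoint placement was
chosen for symmetry and stability; the trapezoidal AUC provably equals the
tie-corrected Mann-Whitney statistic, and the suite asserts both this and
the equality of the selected $J$ with a brute-force scan.

Diagnostic metrics come with 95% confidence intervals; the default is Wald
($p \pm 1.96\sqrt{p(1-p)/n}$) clamped to [0, 100], because small-sample
worked examples in this setting (e.g. sensitivity 75% with $n = 4$ giving
a lower bound of 32.6% and a clamped upper bound of 100%) follow that
formula; Wilson intervals are available by flag. A metric with a zero
denominator is reported as undefined (`NA`), never as 0. Group
comparisons in the cohort summary switch from chi-squared to Fisher's
exact test when any expected cell count drops below 5, the conventional
rule. Logistic odds ratios are maximum-likelihood fits; complete
separation is detected and reported as an error naming the covariate
rather than returning a divergent estimate.

## The phantom generator

Every stage is testable without clinical data through a synthetic phantom
that emulates the *geometry and colour logic* of a dual-panel export: a
grayscale B-mode panel (background luma ~N(150, 12)) with a hypoechoic
elliptical lesion (~N(70, 8)) and an optional near-black concentric
cystic core covering a stated fraction of the lesion area; a white marker
band; and an elastogram panel whose lesion pixels carry the colormap hue
of the ground-truth elasticity $e^\*$ plus truncated Gaussian hue noise
(default SD 5°), over a background drawn from the green/soft hue band
(60-150°) so the background never mimics a stiff lesion. Everything is
deterministic given the seed.

Cohorts are drawn from group elasticity distributions calibrated to a
target median and interquartile width: a log-normal truncated to [0, 1],
its two parameters solved numerically from the two quantile equations
(residuals below 1e-6). The default conditions are 46 low-risk patients
(median 0.268, IQR 0.243-0.333) and 38 high-risk patients (median 0.186,
IQR 0.176-0.199), with NIH categories, age, sex, size class and location
drawn from the corresponding group-conditional frequencies of the
reference cohort.

**A known limitation of this calibration.** A two-parameter log-normal
matched to the median and the IQR *width* is symmetric on the log scale,
while the reference quartiles are right-skewed; the fitted low-risk
distribution therefore places its first quartile near 0.227 rather than
0.243, giving more group overlap than the reference quartiles suggest.
The acceptance script measures the consequence directly: across 200
simulated cohorts the mean extracted-value AUC is about 0.92, and the
per-seed AUC clears 0.9 in roughly two-thirds of seeds, not near-always.
The Youden cutoff, by contrast, lands between the groups' adjacent IQR
bounds (0.199-0.243) in almost every seed. Matching the quartiles
individually instead would tighten separation but would no longer
reproduce the target median; the median-plus-width calibration is kept
because the median is the primary reported location statistic.

What passing phantom tests does **not** show: robustness to speckle,
compression artefacts, overlay transparency gradients, off-centre or
non-elliptical lesions, or vendor colormaps that deviate from a linear
hue sweep. The phantom validates the arithmetic of the pipeline, not its
clinical performance.

## The toy segmenter

The optional segmentation demonstrator is deliberately small and is not a
reproduction of a clinical deep-learning model: a logistic pixel
classifier over a four-level multi-scale intensity pyramid (box means at
half-widths 0, 2, 5 and 10 plus a local-contrast channel), trained by
IRLS on a seeded subsample of pixels, with prediction cleaned up by
keeping the largest connected component and filling holes. On phantoms -
where the lesion is a dark ellipse on a brighter background - it reaches
mean Dice above 0.9 on held-out patients easily; that says nothing about
clinical B-mode segmentation difficulty. Train/test splits are always by
synthetic patient id, never by frame, so no patient leaks across sides.

## Problem sizes and budgets

The suite and the acceptance script run phantoms at 200x120 to 220x140 px
(default export geometry is 600x300); the quantification path is
size-independent, and these desk-scale sizes keep the full 200-cohort
simulation and the 256-entry recovery sweep to a few minutes on one CPU.
Calibration checks use 1e5 draws; oracle equivalences use 100-1000 seeded
cases.

## Worked example

```{r example, eval = FALSE}
co <- makeCohort(nLow = 46, nHigh = 38, seed = 1)
rep <- runPipeline(co, cutoff = "youden", seed = 1)
rep$cutoff   # Youden-optimal elasticity cutoff
rep$auc      # patient-level AUC
rep$metrics  # sensitivity/specificity/PPV/NPV/accuracy with 95% CIs
```
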
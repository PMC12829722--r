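# eusei

Quantitative elasticity extraction and risk stratification for dual-panel
EUS elastography (EUS-E) of gastrointestinal stromal tumors (GISTs).

Strain elastography overlays a stiffness colour map on the B-mode
ultrasound image — blue for stiff tissue, red for soft. Reading that
overlay by eye is subjective; `eusei` turns it into a number. Given a
dual-panel EUS-E frame (B-mode left, colour elastogram right, marker line
between) and a lesion mask on the B-mode panel, the package computes a
0–1 **elasticity index**: the mask is transferred to the elastogram panel
by panel-local translation, anechoic (cystic) pixels are excluded via a
B-mode luma floor, the coloured overlay pixels are averaged per channel
in RGB, the mean colour (R̄, Ḡ, B̄) is converted to HSV and projected by
minimum distance onto a blue(0)→red(255) colormap, and the matched index
*i* gives

&nbsp;&nbsp;&nbsp;&nbsp;*E = i / (N − 1)*, with *E* = 0 stiffest (blue) and *E* = 1 softest (red).

On top of the per-frame index sit patient-level tools: NIH risk
categories collapsed into low- vs high-risk malignant potential, ROC/AUC
with a Youden-optimal cutoff (*J* = sens + spec − 1, lower elasticity ⇒
high risk, strict `<`), diagnostic metrics with Wald/Wilson 95% CIs,
Spearman correlation, logistic odds ratios, cohort summary tables, and
segmentation evaluation (Dice, IoU, detection precision/recall at an IoU
threshold). A calibrated phantom generator renders synthetic dual-panel
frames with known ground truth so the entire pipeline is testable without
clinical images; see the methods vignette
(`vignettes/elasticity-quantification.Rmd`) for the model, parameter
defaults, and design decisions.

## Worked example

```r
library(eusei)

## one synthetic frame with known elasticity 0.42
ph  <- makePhantom(eStar = 0.42, width = 600, height = 300, seed = 7)
res <- computeEusEAi(ph$frame, ph$mask)
res
#> ElasticityResult: EUS-E-AI = 0.4196
#>   mean rgb (0.0, 255.0, 81.5) -> colormap index 107
#>   pixels: mask 17547, solid 17547, colour 17547

## a calibrated 84-patient cohort (46 low-risk / 38 high-risk)
co  <- makeCohort(nLow = 46, nHigh = 38, width = 220, height = 140, seed = 1)
rep <- runPipeline(co, cutoff = "youden", seed = 1)
sprintf("cutoff %.4f  auc %.4f", rep$cutoff, rep$auc)
#> "cutoff 0.2157  auc 0.9479"
rep$metrics
#>        metric estimate lower upper
#>   sensitivity     97.4  92.3 100.0
#>   specificity     82.6  71.7  93.6
#>           ppv     82.2  71.1  93.4
#>           npv     97.4  92.5 100.0
#>      accuracy     89.3  82.7  95.9
```

The frame result reads: all 17 547 mask pixels were solid and coloured,
their mean colour projects to colormap entry 107, hence elasticity
107/255 ≈ 0.4196 — within one quantisation step of the generating truth.
The cohort run selects an elasticity cutoff of ≈0.216 by Youden's index
and separates the malignant-potential groups with AUC ≈0.95 on this seed;
metrics are percentages with 95% confidence intervals.

A thin CLI wraps the same functions
(`inst/exec/eusei synth|extract|seg-eval|stratify|run`).

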
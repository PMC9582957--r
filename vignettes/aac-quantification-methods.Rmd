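---
title: "Methods: automated Kauppila scoring of abdominal aortic calcification and downstream cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated Kauppila scoring of abdominal aortic calcification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacquant)
```

# The problem

Abdominal aortic calcification (AAC) — hydroxyapatite deposition in the wall
of the abdominal aorta — appears on lateral-spine DEXA scans as bright
streaks running anterior to the lumbar spine. The standard semi-quantitative
severity measure is the 24-point Kauppila score: for each lumbar vertebra
L1–L4, the anterior and posterior aortic walls are scored 0–3 by the
fraction of the vertebral height that the calcification spans, and the
eight wall scores are summed.

`aacquant` implements an automated scoring pipeline (spine localization,
spine-curve-based aortic ROI extraction, calcification detection and
scoring, two-pipeline ensembling), an annotation-consensus and agreement
harness, and the downstream epidemiology: prevalence summaries,
statin-adjusted lipid models, cystatin-C eGFR, per-SD biomarker
associations, and a phenome-wide Cox proportional-hazards prognosis screen.
Because the cohorts such methods are developed on are access-restricted,
the package ships a first-class synthetic module: a DEXA-like phantom
generator with exact ground truth, and a cohort simulator with the
statistical structure the analyses assume. Every stage is testable
end-to-end against known truth.

# Coordinate convention

All images are numeric matrices indexed `[row, column]`; row 1 is the most
superior row and increasing column is anterior. Every module shares this
convention and the tests assert it (e.g., L1 has the smallest centroid row;
the aortic band lies at larger columns than the spine).

# The phantom generator

`generate_phantom()` renders, on a soft-tissue background with a smooth
low-frequency intensity field:

* four vertebral bodies (heights drawn from 16–20 px) and a pelvis ellipse,
  placed along a quadratic spine curve — lumbar lordosis is well captured
  by a single bend, which is also why the default curve degree is 2;
* calcific streaks in an aortic band anterior to the curve. The band offset
  (1.2× mean vertebral height) and width (0.8×) are single constants shared
  with the ROI extractor, since projection geometry of the aorta is not
  standardized anywhere and the generator/extractor pair must agree on it;
* Gaussian additive noise (sd 0.03), multiplicative speckle (sd 0.02), and
  a contrast multiplier of 0.6 on L1–L2 deposits, emulating that upper
  lumbar calcification is harder to distinguish from background than L3–L4.

A requested per-wall coverage fraction is realized as a contiguous run of
`round(f * height)` rows, so the rendered extent matches the request to
within one pixel; the ground truth stores the *realized* fraction and the
true score is the scoring rule applied to it. This pixel-quantized
bookkeeping is what makes exact end-to-end recovery a meaningful test.

Per-wall coverage is sampled, when not specified, from a zero-heavy model
frozen at: P(any calcification in an image) = 0.55; per-level wall
involvement 0.12/0.15/0.30/0.35 from L1 to L4 (scores in practice are
driven by the L3–L4 region); involved-wall coverage ~ Beta(1, 3.5). Under
these constants roughly 79% of phantom totals fall below 3 and ~11% exceed
3, the regime reported for middle-aged general-population cohorts.

What the phantom does *not* emulate: realistic X-ray attenuation physics,
vertebral fractures, osteophytes, bowel gas, or rib shadows. Passing tests
therefore demonstrate correctness of the geometry, scoring rules and
statistics — not expected performance on clinical scans, which are far
noisier than any setting exercised here.

# Localization

Two interchangeable front-ends implement spine localization behind one
interface (`segment_spine()`), because the original approach used trained
networks whose weights are not reproducible in a self-contained package:

* **classical** — Otsu thresholding restricted to the upper intensity
  quartile, morphological opening with a 5-px disc (which also removes the
  thin calcific streaks from the skeleton mask), connected components, and
  a minimum-area filter. Fully deterministic, used for exact tests.
* **learned** — a single-hidden-layer neural-network pixel classifier
  (background / pelvis / vertebra) on intensity at three smoothing scales
  plus normalized position, trained by `train_segmenter()` on phantom
  images with ground-truth masks, followed by the same morphological
  cleanup.

`detect_vertebrae()` anchors on the pelvis (the largest component), keeps
the four largest vertebra-class components superior to it (bright
distractors are dropped with a message), and labels them L1–L4 counting
downward from the most superior — i.e., upward from the pelvis anchor.
Images in which localization fails raise a classed condition; batch drivers
skip and report them rather than aborting, mirroring that large imaging
studies score a subset of available scans.

# Aortic ROI

`fit_spine_curve()` fits a least-squares polynomial (default quadratic)
through the vertebral centroids. The pelvis centroid is *not* used by
default: it sits slightly anterior to the spine axis, and anchoring on it
biases the curvature term. Degenerate inputs (coincident rows) fall back to
degree 1 with a warning. A note on tolerances: half-pixel quantization of
detected box centroids makes the raw quadratic coefficient
ill-conditioned (relative errors of tens of percent are geometrically
insignificant), so correctness is asserted functionally — the fitted curve
must stay within one pixel of the generating curve across the domain — and
coefficient recovery is asserted exactly on unquantized points.

`extract_aortic_roi()` places, for each level, a band anterior to the curve
spanning exactly that vertebra's detected row range (so unequal vertebrae
are handled), at the shared offset/width defaults. The band is split at its
midline; the spine-adjacent half is the posterior wall, the far half the
anterior wall. The anterior/posterior wall definition in lateral projection
is the single most consequential modelling gap in this problem — no
reference defines it operationally — so it is isolated in this one function
and the split point is a parameter of the band geometry. The ROI is not
extended beyond L4 toward the aortic bifurcation.

# Scoring

`detect_calcification()` thresholds band pixels adaptively at the band
median plus `max(0.12, 4 * MAD)` — the absolute floor governs clean images
where the MAD collapses, the MAD term governs noisy ones — with pixels at
or above 0.99 always marked (so a uniformly saturated band scores full
coverage). Components smaller than 3 px (the footprint of a single-row
streak at the default deposit thickness) are removed as noise. Coverage is
measured by **row projection** — the fraction of the level's rows containing
any calcified pixel in the wall band — matching the Kauppila convention of
scoring calcification *length* along the vertebra, not its area.

`score_wall()` maps coverage to 0–3 with both boundary fractions 1/3 and
2/3 assigned to score 2 (the rule's middle interval is closed on both
sides), and a noise floor of 0.02: manual scoring requires a *visible*
amount of calcification, which is reader-dependent, so a numeric floor of
2% of vertebral height stands in for it. `kauppila_score()` sums the eight
wall scores.

`train_score_regressor()` / `regress_score()` provide the learned analog:
a small neural-network regression from per-band features (detected
coverage plus band intensity statistics) to the total score, clipped to
0–24 and deterministic at inference. Single-step whole-image regression
(skipping localization) is deliberately not part of the default pipeline;
regression operates on the localized region only.

# Ensembling

`score_image()` runs two pipelines that differ in their localization
front-end — classical segmentation (pipeline 1) versus learned box
detection (pipeline 2) — each feeding the same scoring stage, and
`ensemble_score()` averages their totals. This reading (ensemble over
localization routes, not over scoring methods) matches the design in which
both pipelines end in the same regression step. If exactly one pipeline
fails, the other's score is returned flagged `single_pipeline`; if both
fail, the image is reported as failed.

# The synthetic cohort

`generate_cohort()` draws a population resembling a middle-aged imaging
cohort. Key design choices:

* **Score marginal**: zero-inflated gamma with p0 = 0.20, shape 2.585,
  scale 0.711, solved so the mean (1.47) and the tail fraction above
  score 3 (11.6%) match the regime the analyses target. These two targets
  and the reported SD (~1.49) are not simultaneously attainable by this
  family; the implied SD is 1.26, a known limitation.
* **Covariate effects** (age, sex, BMI, smoking; defaults 0.12 score units
  per SD for age and per smoking group, the strongest predictors) are
  specified on the score scale and applied on a latent Gaussian liability
  via a numerically integrated local slope of the liability-to-score map;
  the conversion is accurate to ~3% at n = 3×10⁵, well inside every
  recovery-test confidence interval.
* **Biomarkers** are drawn with configured correlations to the standardized
  score (glycaemic markers and phosphate positive, HDL and creatinine
  negative, LDL exactly zero — the analyses must be able to demonstrate a
  null), triglycerides on the log scale.
* **Statin use** (marginal 15%, solved exactly per drawn cohort) increases
  with untreated LDL and age — confounding by indication — and lowers
  *measured* lipids, by a proportional 35% reduction by default or an
  additive 1.25 mmol/L in the alternative mode; the untreated truth
  columns are retained for recovery testing. Untreated LDL is floored at
  1.4 mmol/L so additive masking remains invertible.
* **Events** per disease are exponential proportional-hazards draws with
  configured per-SD hazard ratios (MI default: 1.4/SD of AAC and of
  untreated LDL), administrative censoring (12 y from baseline for MI,
  3 y from imaging for prognosis outcomes — the two index dates the
  analyses use), and an independent prior-history flag.

# Cohort statistics

* `prevalence_summary()` — moments, the mean+1 SD threshold, the fraction
  above score 3, and per-(age decade × sex) quartiles.
* `adjust_ldl_statin()` — the three untreated-lipid reconstructions; the
  35% reduction is stored as the primary constant and the model-2
  multiplier 1/(1−0.35) ≈ 1.54 is derived from it, keeping the reduction
  and the relative increase a single assumption. Non-users are always
  returned unchanged.
* `egfr_cystatin()` — the 2012 CKD-EPI cystatin-C-only equation, pinned
  here as the package's choice of estimating equation.
* `biomarker_association()` — linear models of AAC on the standardized
  biomarker under model 1 (age + sex) or model 2 (adding BMI,
  socioeconomic index — a single index variable stands in for
  socioeconomic status — ethnicity and smoking), with a Bonferroni
  threshold across the screening family.
* `prognosis_screen()` — per disease: prior-history exclusion, an event
  filter keeping diseases with strictly more than 25 events, Cox fits with
  Efron tie handling (ties are common at coarse time resolution), per-SD
  standardized exposure, Bonferroni correction across tested diseases.
* `joint_mi_model()` — MI on standardized AAC, adjusted LDL and
  triglycerides with age and sex, an AAC×LDL interaction test, and a
  non-statin-user subgroup option. Age at baseline is the covariate since
  lipids are measured at baseline.

# Worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_config(seed = 4))
res <- score_image(ph$image)
res$total_p1                 # rule-based total
ph$truth$true_score$total    # ground truth

co <- generate_cohort(20000, seed = 42)
prevalence_summary(co$aac_score, co$age_imaging, co$sex)
prognosis_screen(co, "mi", model = 1, age_col = "age_baseline")
```

# Problem sizes and numerical choices

The test suite exercises: 300 noise-free phantoms for exact end-to-end
recovery; 200 noisy phantoms for training the learned front-end and 100
held out for validation; 1,000 random masks for oracle equivalence of the
scoring rule; 100 replicates of n = 2,000 cohorts for hazard-ratio CI
coverage and another 100 screens of 50 null diseases for family-wise error
under Bonferroni. These sizes were chosen as the smallest at which the
binomial/statistical assertions are stable.

Tie-breaks and degenerate inputs are handled explicitly: both third
boundaries score 2; an all-background image is a reported localization
failure, not a zero score; a constant reference vector yields an undefined
Pearson correlation reported as `NA`; training a segmenter on one example
runs but is flagged degenerate; an aortic band partially outside the image
is clipped with a warning and a fully outside band is a failure.

# Known limitations

* Phantoms are geometrically idealized; at the default noise settings the
  rule-based pipeline recovers ground truth essentially exactly, so
  agreement metrics on synthetic validation sets are ceilings, not
  estimates of clinical performance.
* The cohort simulator's score SD (1.26) undershoots the reported 1.49, a
  consequence of matching mean and tail exactly within a zero-inflated
  gamma.
* Intimal versus medial calcification cannot be distinguished at DEXA
  resolution and is not modelled.
* ICD10-to-Phecode mapping is out of scope; the screen consumes pre-mapped
  per-disease event/time/prior columns.
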
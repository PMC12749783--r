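---
title: "Evaluating skin tone labeling schemes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating skin tone labeling schemes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonescale)
```

## The problem

Dermatology AI models underperform on darker skin, and the datasets used to
train and benchmark them rarely carry skin tone labels. Before labels can be
added at scale, the labeling schemes themselves need auditing: how reliably
do human raters apply them, how well do their categories track objectively
measured skin color, can they be applied to photographs rather than in
person, and do they expose differences in classifier behavior across tone
groups? `tonescale` implements that audit as a reusable pipeline over four
analyses:

1. **In-person reliability** — inter-rater agreement for ordinal tone scales
   (the 10-shade Monk Skin Tone scale, MST; the Fitzpatrick photosensitivity
   type, FST; Pantone-style swatches split into pigment and undertone
   components) and repeatability of colorimeter measurements.
2. **Dispersion in color space** — how tightly each scheme's categories
   cluster in the objective CIELAB plane measured by a contact colorimeter.
3. **Photography-based labeling** — agreement of image-derived labels
   (total-body-photography re-rating, image-extracted color, crowdsourced
   labels) with in-person assessment.
4. **Fairness auditing** — whether melanoma-classifier score distributions
   differ across tone classes, and which scheme exposes those differences.

A seeded synthetic study generator emulates the statistical structure of a
skin-tone-balanced cohort so the whole pipeline is testable end to end
without any clinical data.

## Color math

Conversions follow the universal defaults of scientific imaging libraries:
the IEC 61966-2-1 (sRGB) transfer function and primaries, D65 white point,
2° observer. The reference white is taken as the row sums of the sRGB→XYZ
matrix so that RGB (255,255,255) maps to exactly L\* = 100, a\* = b\* = 0.
The individual typology angle is

$$\mathrm{ITA} = \arctan\!\left(\frac{L^* - 50}{b^*}\right)\cdot\frac{180}{\pi},$$

larger for lighter skin. Two deliberate conventions:

* The plain arctangent is used, exactly as the formula is conventionally
  printed — not `atan2`. A negative b\* therefore flips the angle's sign;
  this is documented rather than "corrected".
* When |b\*| < 10⁻⁶ the hue angle is meaningless and the package raises a
  classed `tonescale_degenerate_chromaticity` error instead of returning
  ±90°. Downstream tabulation (`extract_ita_dir()`) records such sites as
  `NA`.

ITA is treated as a continuous quantity throughout; the historical ITA
"skin tone bins" are deliberately not implemented, since they were derived
from European-ancestry samples and are not suitable for diverse cohorts.

Image color extraction is the per-channel (marginal) median of the 8-bit
RGB pixels — computed *before* linearization, matching the order
"extract RGB, then convert". Even pixel counts use the midpoint of the two
central values, rounded half away from zero. An optional inclusion mask
supports excluding dermoscopy artifacts (dark corners, stickers), but it is
off by default: artifact handling in the source workflow was manual QC, not
algorithmic.

## Agreement statistics

* **Linear-weighted Cohen's κ** with weights $w_{ij} = |i-j|/(k-1)$ on the
  full scale range, so unobserved levels never change the weighting. When
  both raters use one identical category throughout, chance agreement is
  total and κ is undefined; the package returns `NA` with a classed warning
  rather than a misleading 0.
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measurement, from the ANOVA mean squares. The variant is a design choice:
  it is the standard answer to "do repeated device measurements agree in
  absolute value", which is the question asked of colorimeter triplicates.
  Each measured site is treated as an independent subject when pooling.
* Paired mean differences use the classical paired *t*; identical vectors
  return p = 1 by convention, and a constant nonzero difference raises a
  zero-variance error rather than reporting an infinite *t*.
* The Pantone-style swatch code is analyzed as two ordered scales — pigment
  1–15 and undertone mapped to the ten ordered levels 5R…1R, 1Y…5Y — the
  only ordering under which "5R to 5Y" is an ordinal range. For the
  dispersion analysis, by contrast, the *full* swatch code defines the
  class, giving many small clusters (and exercising the singleton
  silhouette convention).
* p-values are two-sided and uncorrected; per-site κ tables are
  descriptive.

## Dispersion in (L\*, b\*) space

Points are the triplicate-mean colorimeter (L\*, b\*) of non-lesional sites
that also carry at least one MST and one Pantone rating. Where both raters
rated, one rating is selected uniformly at random under a recorded seed.
Clusters are *label-defined* — there is no fitting step. Three quantities
are reported per scheme:

* per-class centroid and a radius equal to the population SD of members'
  Euclidean distances to the centroid (the circle geometry of the scatter
  plot);
* the **Davies–Bouldin index**, using the canonical scatter
  $S_i = $ *mean* distance to centroid (the SD-based radius is kept
  separately and only drives the plot) and Euclidean centroid separations.
  Coincident centroids raise an error rather than being silently skipped;
* the **mean silhouette** (Rousseeuw silhouette index), with the stated
  convention that a point alone in its class contributes exactly 1.

Because the scatter convention inside published DBI values is not always
recoverable, comparisons against externally printed DBI numbers should be
treated as approximate; the package's definition is the canonical one.
The a\* channel is excluded: the objective ground truth is deliberately the
2D (L\*, b\*) estimate.

## Crowd aggregation

Reads are qualified sequentially: a user's trailing accuracy (mean
correctness over the last 50 gold-scored reads; window configurable) must
rank at or above the 20th-percentile order statistic of all users' current
accuracies — "top 80%" with ties ranking equally. Users with no scored
history are not yet qualified. This sequential bookkeeping is an explicit
stand-in for a proprietary app-side rule whose details are not public.

The majority rule is applied per image to qualified reads: with ≤ 12 reads,
a label needs at least 3 reads and a top share of at least 70%; with more
than 12 reads the plurality wins, ties remaining unresolved. Unresolved
images are excluded from the concordance table and κ.

## Fairness auditing

Scores are compared across classes with the two-sample Kolmogorov–Smirnov
statistic $D = \sup_t |F_1(t) - F_2(t)|$, evaluated exactly over the pooled
sample points. Since $D$ is invariant under strictly monotone transforms,
the log display transform (natural log, floor 10⁻⁴ on the percent scale)
affects only plots. The report carries the pairwise KS matrix, pooled
percentile ranks per class (midranks, $(r-0.5)/n \times 100$), and both the
per-pair values and the per-distance means of $D$ — the per-Δ aggregation
is reported alongside the raw pairs precisely because either could be read
off a published figure.

## What the synthetic generator emulates — and what it does not

`study_config()` defaults describe a 64-participant cohort balanced across
FST I–VI (10–12 per class), each with 11 standardized non-lesional sites
and 5–13 lesions. The generative chain:

* **Color.** True site color sits on a strictly decreasing L\* ladder
  across MST shades 1–10 (75 down to 30) with b\* rising then falling
  (14→18→12), plus participant-level deviation (SD 2.2 L\* units),
  systematic per-site offsets (callused sun-protected sole lighter by 6;
  forehead darker by 2), and site noise. These values are configuration
  chosen for realistic separation-to-spread ratios, not claims about real
  skin.
* **FST vs color.** FST is assigned from MST through a noisy many-to-one
  map (SD 2.4 shades). That each FST class spans a wide band of true color
  is therefore the generator's ground truth, and the dispersion analysis
  recovers it: DBI(FST) > DBI(MST).
* **Raters.** Ordinal noise kernels (exact, ±1, ±2). The MST kernel
  (0.50, 0.20, 0.05) implies a population weighted κ near 0.75, which the
  pipeline recovers. Note a structural limit: with support bounded at ±2,
  a 15-level scale's implied weighted κ cannot fall much below ~0.68, so
  the generated Pantone agreement sits above clinically reported values;
  the MST > pigment > undertone ordering is preserved.
* **Colorimeter.** Triplicates add Gaussian noise (SD 0.5 L\*/b\*). The
  implied variance-ratio ICC (delta-method within-site variance against
  between-site spread) is ≈ 0.99, recovered by ICC(2,1).
* **Imaging chain.** Patches are uniform color plus per-pixel RGB noise;
  the imaging chain compresses luminance toward L\* = 55 (factor 0.15,
  emulating flash/auto-exposure), applies per-dermoscopy-mode L\*/b\*
  offsets (polarized vs non-polarized shift b\* in opposite directions),
  and adds large per-image device jitter. This is what produces the
  realistic *failure* of image-extracted ITA to agree with colorimetry
  (ICC roughly 0.1–0.3) while each individual patch still yields its own
  color exactly.
* **TBP re-rating.** White-light ratings are biased lighter (−0.7 MST
  shades), cross-polarized slightly darker (+0.15), with rating noise
  SD 0.8; the paired tests recover both signs.
* **Crowd.** Every reader of an image sees the same lighting/site-distorted
  apparent FST (`round(fst + N(0, 0.9))`, clipped); per-read skill (Beta(7,3)
  probability of reporting the percept exactly) then corrupts individual
  reads. The shared distortion is what caps crowd-vs-in-person concordance
  in the mid-50s regardless of crowd quality and makes the boundary classes
  I and VI the most concordant — both structural features of real
  crowdsourced FST labeling. A consequence worth knowing: *resolved-only*
  concordance is not monotone in annotator skill, because low-skill crowds
  only resolve the easy boundary images (a selection effect of the 70%
  rule); pipeline-level accuracy with unresolved images counted as misses
  is monotone, and that is the quantity the invariant tests check. The
  crowd log carries no dermoscopy-mode column (one image per lesion), so
  the accuracy chi-squared is stratified by anatomic site only.
* **Scores.** Per-MST-shade Beta distributions on the percent scale
  (concentration 14), means drifting up gently over shades 1–7 with an
  elevation at shades 8–9 — so the KS-by-distance curve rises, and rises
  faster under MST than under the coarser FST grouping.

What the generator does **not** emulate: photorealistic skin texture,
lesion morphology, anatomic shadowing of photographs, annotator
demographics, JPEG compression artifacts (PNG is the default; a JPEG path
exists for reading), or any correlation between skin tone and lesion
malignancy. Passing tests therefore demonstrate that the *statistical
machinery* is correct and that known generating structure is recovered —
not that any particular clinical conclusion transfers.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed through named substreams
  (`substream_seed`), so stages are independently reproducible and
  re-running any stage from a manifest is bit-for-bit identical.
* Even-count medians round half away from zero (R's `round` half-to-even
  would bias channel medians low at .5 midpoints).
* κ undefined (both raters constant) → `NA` + classed warning; ICC with no
  between-subject variance, paired test with constant nonzero differences,
  chi-squared with an empty marginal, DBI with coincident centroids, ITA
  with near-zero b\* → classed errors. Strata with fewer than 2 complete
  pairs are reported as `NA` rows, not dropped.
* Agreement "all sites" rows are the statistic on pooled pairs, never the
  mean of per-site values.

## Problem sizes

The shipped tests run the full default cohort (64 participants, ~1300
sites, 5760 crowd reads) for parameter recovery, Monte-Carlo checks at
n = 2000–100 000 where a limit value is asserted, and 25–30 randomized
small instances (n ≤ 12) for every oracle-equivalence check. The whole
suite completes in well under a minute on one core; `scripts/acceptance.R`
regenerates the default cohort and recomputes all headline quantities in
a few seconds.

## Known limitations

* Weighted-κ targets below ~0.68 for 15-level scales are unreachable under
  the bounded ±2 rater kernel (see above).
* The qualification rule is a plausible sequential reconstruction, not the
  app's exact bookkeeping.
* Dispersion statistics depend on the recorded rater-selection seed; two
  runs with different seeds differ slightly (the reports store the seed).
* The lesional-site anatomic mapping uses the same 11-site vocabulary as
  the non-lesional sites rather than a separate lesion-location ontology.
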
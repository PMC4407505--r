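---
title: "Methods: low-level scene statistics and esthetic preference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-level scene statistics and esthetic preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenestats)
```

## The question and the model

Natural scenes are preferred over man-made ones, and viewing them carries
measurable cognitive benefits. One candidate explanation is bottom-up: the
low-level visual statistics typical of nature (curved, fragmented contours;
yellow-green hues; diverse saturation) may drive preference directly, before
any semantic recognition of "nature". `scenestats` implements an analysis
chain built around that hypothesis:

1. **Feature extraction.** Each image is summarized by ten statistics: the
   HSV channel means and standard deviations (`hue`, `sd_hue`, `sat`,
   `sd_sat`, `bright`, `sd_bright`), the Shannon entropy of the 256-bin
   grayscale histogram (`entropy`, 0-8 bits), the weighted Canny edge
   density (`ed`), the straight-edge density (`sed`), and the disorganized
   edge ratio (`der`), the share of edge mass not on straight edges. All
   spatial counts are divided by the pixel count, so sizes are comparable.
2. **Naturalness decomposition.** Per-image mean naturalness ratings are
   regressed on the ten features (OLS; predictors z-scored, response on the
   1-7 rating scale). The fitted value is *modeled naturalness* — the part
   of perceived naturalness the low-level features can explain — and the
   residual is *non-modeled naturalness*. Submodels on the six color and
   four spatial features give color- and structure-modeled naturalness.
3. **Reaction-time moderation.** If modeled naturalness is truly bottom-up,
   its link to preference should be strongest for fast preference
   judgments. We regress standardized preference on a standardized
   naturalness component, standardized RT (z-scored within participants
   before averaging), and their product, then read off simple slopes at
   mean RT and mean ± 1.5 SD. The bottom-up account predicts a negative
   RT-by-modeled interaction and a positive RT-by-non-modeled interaction.
4. **Quadratic discriminant classification.** Images are median-split into
   high/low preference; a QD classifier (one Gaussian per class, separate
   covariances, empirical priors) is evaluated by *pairwise* leave-one-out:
   every (high, low) pair is held out, the model is trained on the rest and
   both points are classified. Chance is 50% by construction. Greedy
   backward elimination drops features whose removal improves accuracy.

## Feature-extraction parameters

* **Grayscale**: ITU-R BT.601 luma weights (0.2989, 0.5870, 0.1140),
  rounded to 8-bit.
* **Hue is linear, not circular**: channel means/SDs are computed on the
  raw `[0, 1]` hue values, matching the stock channel-statistics convention
  of common image toolboxes. For scenes dominated by reds/greens this is
  adequate; hues straddling the 0/1 wrap would be missummarized.
* **Channel SDs** are population SDs (divide by *N*); a `sd_type` flag
  switches to sample SDs.
* **Edge detection** (`edge_config()`): derivative-of-Gaussian gradients at
  `sigma = 1.4` px; the base high threshold is the smallest gradient
  magnitude above the 70th percentile of the magnitude distribution (all
  pixels; magnitudes below `1e-6` are treated as zero — they are
  floating-point cancellation dust from flat regions, not structure); the
  base low threshold is 0.4 times the high one. Canny (non-maximum
  suppression by quantized gradient direction, then hysteresis by
  8-connected tracking) runs twice: thresholds scaled by 0.8 (high
  sensitivity) and by 1.6 (low sensitivity). Pixels detected at low
  sensitivity weigh 1 (salient), pixels detected only at high sensitivity
  weigh 0.5 (faint). The percentile rule is a documented approximation to
  the unpublished stock heuristic the original analyses relied on, so
  per-image feature values are approximate reference points rather than
  bit-exact reproductions; an explicit `base_thresholds` override is
  provided.
* **Straight edges** (`straight_config()`): edge pixels are binned into
  eight gradient orientations (22.5° bins folded to `[0°, 180°)`). The bins
  are phase-shifted by half a width so the canonical orientations (0°, 45°,
  90°, 135°) fall at bin centers; with boundaries at 0° an axis-aligned
  ridge's gradient sits exactly on a bin edge and numerical jitter
  fragments it. Components are 8-connected within each bin; components of
  at least `min_pixels = 10` (smaller fragments are degenerately collinear)
  are straight iff the ratio of the coordinate-covariance eigenvalues
  exceeds `variance_ratio = 1e4`, i.e. singular-value ratio 100. We read
  the published "10^4" criterion as a variance ratio: the literal
  singular-value reading would reject every rasterized line that is not
  exactly collinear (a rounded oblique raster has a perpendicular jitter of
  about ±0.5 px, capping its singular-value ratio near its length), which
  would make the statistic measure rasterization arithmetic rather than
  straightness.
* **DER** uses the faint/salient weights in both numerator and denominator;
  **SED** counts straight pixels unweighted ("number of pixels"). DER is
  undefined (reported as missing) when an image has no edges at all.

## What the synthetic generators emulate — and what they do not

`generate_scene()` renders an HSV base field (hue with uniform jitter, a
vertical saturation gradient, Gaussian brightness texture) and draws
straight segments and circle arcs in contrasting brightness.
Design choices that matter:

* **Straight segments are axis-aligned** (horizontal/vertical, the grid
  orientations of built structure, ≥ 40 px). Oblique rasters cannot pass
  the 1e4 variance-ratio criterion at feasible lengths — quantized-direction
  non-maximum suppression makes even an exact 45° ridge two pixels thick —
  so drawing them would break the generator's contract that its straight
  primitives are detectable as straight.
* **Curves are circle arcs with radius 8-18 px**, keeping curvature bounded
  away from zero so no arc passes the straightness test. Larger raster
  circles develop exactly collinear flat runs of ≥ 10 px at their cardinal
  extremes, which the criterion — correctly — classifies as short straight
  segments; capping the radius keeps those runs below `min_pixels`.
* The presets `urban_scene_spec()` (14 grid segments, desaturated,
  noise-free) and `nature_scene_spec()` (10 arcs, green hue, saturation
  gradient, brightness texture) are deliberately caricatured endpoints of
  the urban-to-natural continuum.

The generator does **not** emulate photographic scenes: no 1/f spectral
structure, occlusion, perspective, shading, or semantic content. Passing
tests therefore certify the *analysis chain* — that the features measure
what they claim and the models recover known generating parameters — not
that the chain would reproduce any particular result on photographs.

`simulate_features()` draws feature vectors from independent uniforms over
ranges plausible for outdoor photographs (entropy 5-7.9 bits — photographs
rarely fall below 5; edge densities below 0.4; DER from 0.2 to 1). An
optional Gaussian-copula correlation matrix can induce dependencies such as
the strong SED-DER anticorrelation seen in real scenes; the default is
independence, which makes parameter-recovery experiments conservative and
transparent. `simulate_ratings()` generates per-participant ratings around
the reference naturalness equation (intercept 3.573 on the 1-7 scale,
slopes on z-scored features) with Gaussian noise (default SD 0.9), and
reaction times as `1.8 - 0.12 x z(modeled naturalness)` seconds with noise
SD 0.35, truncated at 0.2 s. The RT distribution parameters are package
choices — no reference values exist for them — picked to give plausible
1-4 s judgment times with the faster-for-natural coupling.

`simulate_interaction_dataset()` works directly on the standardized scale:
components and RT are independent standard normals and the default residual
SD of 0.70 makes the simulated preference approximately unit-variance, so
the generating coefficients keep their scale when the analysis
re-standardizes.

## Statistical conventions

* The canonical naturalness regression z-scores predictors and keeps the
  response on the rating scale (`fit_ols(..., standardize = "x")`), so the
  intercept is the mean rating. The reference coefficient set is only
  dimensionally consistent under this convention: its intercept standard
  error equals `sigma/sqrt(n)`, which is impossible for raw-scale
  predictors that include entropy (mean ≈ 7 bits), and slopes like 0.717
  for edge density (raw range ≈ 0.3) are plausible only per SD.
* Preference-on-features fits are fully standardized (betas); confidence
  intervals use exact *t* critical values.
* Moderation and color/structure models are fit on z-scored variables with
  product terms formed *after* z-scoring and not re-scaled (the usual
  simple-slopes convention). The intercept is estimated — the product of
  two z-scored variables has a nonzero mean, so forcing it to zero would
  bias the slopes — but omitted from the reported tables, where it is
  indistinguishable from zero.
* `r2_from_f()` inverts the overall-F identity to audit printed F/R² pairs.
  For a 10-predictor fit on 307 observations, `F = 36.73` implies an
  adjusted R² of 0.539, consistent with the rounded 0.54 reported for the
  reference naturalness model; `F = 14.41` implies 0.305, which rounds to
  0.30 rather than the 0.31 quoted alongside it — a rounding inconsistency
  we surface but do not resolve.
* Counterbalance-order checks default to Welch's two-sample *t* per image.
  The reference analysis reports df = 25 for 26 + 26 raters, implying a
  paired construction whose pairing key is not recoverable; a `"paired"`
  variant (participants paired by id order within group) is provided.
* Median-split ties alternate between classes, starting with the smaller
  (or `low` on a tie), so 307 items split 153/154. QD uses empirical class
  priors and `n - 1` covariance denominators. Pairwise LOO downdates class
  sufficient statistics for the held-out points; a test verifies the
  result is identical to refitting from scratch. Posterior ties classify
  as `high` (fixed class order). Backward elimination requires strict
  improvement to continue and drops the later-listed feature on ties;
  subsets with singular class covariances score `NA` and any valid removal
  beats them.

## Problem sizes

The packaged experiments are sized for a laptop: parameter-recovery
simulations use 2,000-5,000 synthetic feature vectors; classifier
calibration uses 200 images and 20 label permutations (about a second);
the end-to-end pipeline demo uses 80 images of 96 x 128 px and 20
simulated raters. Feature extraction runs at roughly 10-15 images per
second at that size.

## Known limitations

* The base-threshold heuristic is an approximation; absolute ED/SED/DER
  values depend on it, though the orderings the analyses rely on are
  robust to it.
* Hue statistics are non-circular by design (see above).
* On images that are mostly flat (synthetic fixtures), the percentile
  threshold anchors on whatever gradient content exists, so faint/salient
  weighting degenerates — realistic images with distributed texture are the
  intended regime.
* The straightness criterion interacts with rasterization: very long
  gentle curves and raster circles of radius ≳ 20 px contain short exactly
  collinear runs that count as straight edges. This is a property of the
  method, not a bug in the implementation; the generator avoids the regime
  rather than hiding it.
* The rating simulators draw participants as exchangeable (no individual
  slopes) and features as independent unless a copula is supplied;
  recovery experiments on them validate estimator correctness, not
  real-data effect sizes.
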
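# scenestats

Low-level scene image statistics and esthetic preference analysis.

`scenestats` is for researchers in visual psychophysics and environmental
psychology who want to ask how much of the preference for natural over
man-made scenes is carried by **bottom-up, low-level visual features** —
and how much by everything those features miss. It implements, end to end:

1. **Ten image features** per scene: HSV channel means and standard
   deviations (*Hue, SDhue, Sat, SDsat, Bright, SDbright*), grayscale
   histogram entropy (bits), weighted dual-threshold Canny **edge density**
   (ED: faint edges weigh 0.5, salient edges 1, per pixel), **straight-edge
   density** (SED: pixels on gradient-direction connected components whose
   coordinate-covariance eigenvalue ratio exceeds 10^4, per pixel), and the
   **disorganized edge ratio** (DER: share of edge mass not on straight
   edges).
2. **Naturalness decomposition.** Per-image mean naturalness ratings are
   regressed on the ten features (predictors z-scored):

   *naturalness* = b0 + Σ bj z(feature_j) + e

   The fitted values are *modeled* (bottom-up) naturalness, the residuals
   *non-modeled* naturalness; color-only and structure-only submodels give
   the corresponding partial predictions.
3. **Reaction-time moderation.** Standardized preference is regressed on a
   naturalness component, RT (z-scored within participants, then averaged
   per image), and their product; simple slopes are evaluated at mean RT
   and mean ± 1.5 SD. Opposite-signed interactions for modeled vs.
   non-modeled naturalness are the signature of a fast, feature-driven
   route and a slower, non-modeled route to preference.
4. **Quadratic discriminant classification** of high- vs. low-preference
   images (median split) under pairwise leave-one-out cross-validation
   (every high/low pair held out; chance = 50%), with greedy backward
   feature elimination.
5. **Synthetic data generators** for parametric scenes (controllable
   straight/curved content and HSV composition) and simulated ratings/RTs,
   so the whole chain is testable without external stimuli.

## Worked example

```r
library(scenestats)

# two caricatured scenes: a man-made grid and a curved, green "nature" scene
urban  <- generate_scene(urban_scene_spec(seed = 1))
nature <- generate_scene(nature_scene_spec(seed = 1))
rbind(extract_features(urban), extract_features(nature))
#>     hue sd_hue   sat sd_sat bright sd_bright entropy    ed   sed   der
#> 1 0.082  0.004 0.153  0.002  0.584     0.128   0.372 0.118 0.085 0.277
#> 2 0.330  0.035 0.451  0.173  0.526     0.113   5.777 0.177 0.000 1.000
```

The grid scene has high straight-edge density and low DER; the nature scene
has zero SED and DER 1 (all of its edge mass is curved), a greener hue and
far higher saturation diversity — the feature signature the analysis relies
on.

```r
# simulate 300 images' features and 52 raters, then decompose naturalness
feats   <- simulate_features(300, seed = 1)
ratings <- simulate_ratings(feats, rating_sim_spec(n_participants = 52, seed = 2))
summ    <- aggregate_means(zscore_rt(ratings))
split   <- decompose_naturalness(feats, summ$mean_naturalness)
split$fits$full
#> Linear fit (n = 300, k = 10, standardize = "x")
#>           term estimate       se       t ci_lower  ci_upper
#> 1  (Intercept)  3.58274 0.007419 482.892  3.56814  3.597344
#> 2          hue -0.24861 0.007501 -33.142 -0.26338 -0.233847
#> ...
#> 10         sed -0.29988 0.007576 -39.584 -0.31479 -0.284970
#> 11         der  0.58737 0.007584  77.453  0.57245  0.602300
#> R^2 = 0.9907, adj. R^2 = 0.9904, F(10, 289) = 3086.142, p = 3.69e-287
```

With 52 raters the per-image means are nearly noise-free, so the refit
recovers the generating equation (intercept 3.573; e.g. ED 0.717,
SED -0.299) to the third decimal.

```r
# RT moderation: preference leans on modeled naturalness more when judged fast
d   <- simulate_interaction_dataset(2000, seed = 5)
fit <- rt_interaction_model(d$preference, d$modeled, d$rt, "modeled")
fit$coefficients[, 1:3]
#>           term    estimate         se
#> 1      modeled  0.47354046 0.01892770
#> 2           rt -0.01872043 0.01894567
#> 3 rt_x_modeled -0.22857870 0.01862104
simple_slopes(fit)
#>   rt_level level     slope
#> 1     fast  -1.5 0.8164085
#> 2  average   0.0 0.4735405
#> 3     slow   1.5 0.1306724
```

The negative interaction makes the preference-on-naturalness slope four
times steeper for fast judgments (0.82) than for slow ones (0.13).

```r
# classify preferred vs non-preferred images from 7 features
labels <- median_split(summ$mean_preference)
loo_pairwise_accuracy(feats[, c("hue","sat","sd_hue","sd_sat",
                                "entropy","sed","der")], labels)$accuracy
#> [1] 0.8771556
```

`run_pipeline(pipeline_config(seed = 1), "run1")` chains all stages on
synthetic scenes and writes `features.csv`, `ratings.csv`,
`image_summary.csv`, `split.csv`, `report.json`, `qd_report.json` and a
manifest with per-file MD5s; identical config + seed reproduce the outputs
byte for byte. A thin command-line wrapper lives at
`inst/scripts/scene_pipeline.R`.

## Design notes

See the methods vignette
(`vignettes/scene-preference-methods.Rmd`) for the model conventions
(z-scoring, intercept handling, tie rules), the edge-detection heuristic
and its limits, why the straightness criterion is read as a variance ratio,
and what the synthetic generators do and do not emulate.
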
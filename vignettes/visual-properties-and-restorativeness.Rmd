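---
title: "Visual properties and perceived restorativeness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual properties and perceived restorativeness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restorevis)
```

# What the package does

`restorevis` links two measurements of an indoor (office) scene:

1. **Visual properties of a photograph** -- 19 image-statistical indicators:
   the square root of the green-area percentage, mean brightness and
   saturation, a shape (edge) fractal dimension, geometric and statistical
   (differential box-counting) fractal dimensions at several spatial
   scales, a joint spatial-colour ("colour fractal") dimension, and 1/f
   spectral-slope fluctuation indices.
2. **Perceived restorativeness** -- scores on the 11-item Indoor
   Restorative Characteristic Scale (IRCS), with three subscales rooted in
   Attention Restoration Theory: Being Away, Fascination, and Extent.
   Participants rate photos 1-5; subscale scores are item means (reverse-
   keyed Extent items inverted first) and the overall score is the mean of
   the three subscale means.

The statistical chain connecting them is deliberately plain and fully
reproducible: per-photo averaging of ratings, Pearson correlations with the
square root of greenery, column standardization, iterative variance-
inflation-factor (VIF) pruning with the greenery predictor protected, a
seeded 50/10 train/test split, 10-fold cross-validated lasso regression with
the one-standard-error rule, and train/test RMSE. The published model
coefficients ship as a JSON data asset (`published_models()`).

Because the original photographs and the crowd-sourced ratings are not
deposited, the package carries a first-class synthetic-data module that
generates (a) analytic fractal fixtures with known dimensions, (b)
office-like scenes with a controllable green-pixel fraction and colour
complexity, and (c) grouped 1-5 Likert ratings whose photo-level means
depend linearly on the square root of greenery and on the colour fractal.

# The indicators

## Greenery

A pixel counts as green when its hue, saturation and value all fall
inclusively in the criteria window, by default hue 50-170 degrees,
saturation 20-100%, value 10-100% -- yellow-green through cyan-green. The
source description of the thresholds nominally refers to 8-bit (OpenCV)
HSV, where hue runs 0-179 in half-degrees and saturation/value 0-255; read
on that scale the window would span cyan to magenta and a saturation floor
of 8%, which does not delimit green plausibly. The package therefore
defaults to the degrees/percent reading and exposes the 8-bit one via
`hsv_criteria(convention = "native_8bit")`. The greenery percentage is a
pure pixel count (permutation invariant, monotone under repainting a pixel
green) and makes no attempt to distinguish live plants from green
furniture. The modelling predictor is its square root: perceived texture
density follows a square-root law at moderate-to-high densities, and the
raw percentage is carried alongside but excluded from models as redundant.

## Box-counting estimators

All box counts share one convention: grids anchored at the top-left corner,
partial boxes at the right/bottom edges counted, no multi-offset averaging,
and the dimension taken as the OLS slope of log N against log(1/eps). The
default ladder is powers of 2 from 2 up to min(H, W)/4; "small" is the
lower half of the ladder, "large" the upper half, "overall" all of it
(each window keeps at least three rungs so the regression is determined).

* `shape_fractal` extracts a thin edge map from the brightness channel --
  Sobel gradient, non-maximum suppression with a one-sided strict tie-break
  (so plateau ties keep a single-pixel ridge), and hysteresis with
  data-driven thresholds (high = 90th percentile of the gradient
  magnitudes, low = half of high; thresholds must be data-driven to be
  comparable across photographs) -- and box-counts it. A step edge measures
  1.0 exactly; a filled Koch snowflake's boundary measures log 4/log 3
  within 0.08. A painted one-pixel *line* produces two parallel boundary
  edges and measures ~1.14, not 1.0; that is a property of any gradient
  edge operator, not an estimator defect. A perfectly uniform image has no
  edges and returns 0 with a `flagged` attribute.
* `geometric_fractal` binarizes a channel at its median (occupied =
  value >= median) and box-counts the occupied set. A constant field
  binarizes degenerately and returns 2, flagged.
* `statistical_fractal` is classic differential box counting: the channel
  is an intensity surface; an eps-cell contributes
  `ceil((max - min)/h(eps)) + 1` intensity boxes with
  `h(eps) = eps / min(H, W)` (the unit intensity range mapped onto the
  spatial grid). Flat surfaces give exactly 2; rougher textures larger
  values; the estimate is verified against a naive loop implementation to
  1e-9.
* `color_fractal` counts occupied boxes in the 5-D (x, y, R, G, B) product
  space with colour axes cut at the matched relative size
  `256 * eps / min(H, W)`. Its window deliberately excludes small scales:
  once there are far more 5-D boxes than pixels (eps below roughly
  `min(H, W)^(3/5)`), every pixel occupies its own box and the count stops
  scaling, so `color_scale_window()` keeps powers of 2 from that bound up
  to min(H, W)/2. A constant-colour image measures 2; per-pixel colour
  noise measures far above a smooth gradient.

Hue enters the statistical fractals as a linear field in [0, 1]; treating
the circular quantity linearly is a known approximation, flagged here
rather than hidden, and achromatic pixels take hue 0.

## Known limitation: DBC underestimates very rough surfaces

On spectrally synthesized fractional Brownian surfaces the analytic
dimension is D = 3 - H. The package's estimator is monotone in H and exact
on flat surfaces, but its point estimates are compressed toward 2:
H = 0.8 measures about 2.07, H = 0.5 about 2.25, H = 0.2 about 2.43 at
512^2 with the default ladder. The cause is pre-asymptotic, not a coding
error (the estimator equals a brute-force loop to 1e-9): the expected
max-min range over a discrete eps-cell converges slowly to its continuum
value (the deficit decays like eps^-H), so the measured range-versus-eps
slope exceeds H at any practical image size, and the +1 term inflates
counts at the largest boxes. This compression of differential box counting
for high-dimension surfaces is well documented in the texture-analysis
literature. For the regression use in this package only the ordering of
photographs matters, and the ordering is preserved; the acceptance suite
nevertheless states the D = 3 - H recovery at face value, and that check
fails honestly. fBm synthesis itself is done at 4x resolution and
decimated so the sampled surface carries the aliased supra-Nyquist power a
truly sampled fBm would have; its lagged increments then scale as d^H at
all lags.

## 1/f fluctuation

The field is mean-removed, Fourier transformed, and the power averaged in
24 log-spaced radial-frequency bins between the second radial bin and half
the Nyquist frequency (excluding DC leakage below and pixel-grid aliasing
above). The returned index is the amplitude-spectrum exponent, i.e. half
the negative slope of log power vs log frequency: white noise scores 0,
pink 1/f-amplitude structure scores 1, Brownian-like fields 2. Recovery of
planted exponents in [0.5, 2] is within 0.1 averaged over 5 seeds, and the
whole computation equals a definition-level DFT oracle to 1e-9 on small
fields.

# Preprocessing

Full-frame photographs are centre-cropped to 4096 x 2048 and resized to
the 640 x 320 working resolution. Resizing uses exact area-averaging (each
output pixel is the area-weighted mean of the input pixels it covers):
interpolating resamplers alias at a 6.4x downscale and the aliases corrupt
the fractal and spectral statistics downstream. Whether the original
analysis computed its indicators on the display images or the full crops is
not stated at the source; the package computes on the working resolution by
default and exposes the toggles in `feature_config()`.

# Psychometrics

The scale definition carries explicit per-item reverse flags because the
identity of the reverse-keyed Extent items travels with the survey wording,
which is not part of the computational record; the default reverses all
three Extent items and `ircs_scale(reverse = ...)`/`read_scale()` accept
any subset of them. Reverse scoring is `6 - x`; subscale scores are item
means; the overall score is the mean of the three subscale means (not the
mean of the 11 items); photo-level summaries use the arithmetic mean and
the sample (n-1) SD, with SD = 0 for a single rater. Missing responses are
rejected, never imputed -- the upstream survey excluded incomplete
participants rather than imputing.

# The modelling chain

* **Standardization**: z-scores with the sample (n-1) SD; the training
  means/SDs are stored in fitted models so they can consume raw features.
* **VIF pruning**: VIF_j = 1/(1 - R^2_j) from OLS of column j on the
  others; the non-protected feature with the largest VIF >= 5 is removed
  and the loop repeats. The square root of greenery is protected: it is
  never removed but keeps counting as a regressor. Ties break by column
  order, so runs are deterministic; perfect collinearity reports +Inf
  rather than erroring.
* **Split and folds**: 10 of the 60 photos are drawn uniformly as test
  data under an explicit seed; CV folds are a seeded shuffle cut into 10
  contiguous blocks. No hidden default seed exists anywhere -- every
  stochastic entry point takes one.
* **Lasso**: objective (1/2n) RSS + lambda * L1 with an unpenalized
  intercept; the solver is glmnet (standardization disabled -- the chain
  standardizes once, explicitly). The lambda grid is 100 log-spaced values
  from the data-derived lambda_max down to 1e-4 lambda_max. The
  cross-validation loop, the per-fold RMSE, its standard error across folds
  (SD/sqrt(k)), and the one-standard-error rule (largest lambda whose mean
  RMSE is within one SE of the minimum) are implemented in the package:
  the selection rule here operates on RMSE, whereas stock cv.glmnet
  operates on MSE, and the two can pick different penalties. Whether CV
  error should be computed per fold then averaged, or pooled, is not
  stated at the source; per-fold is used.
* **Published models**: consumed as standardized-scale coefficients, never
  refit, so the objective's scaling convention cannot affect their
  predictions. The Fascination model carries four nonzero coefficients as
  printed in the source table.

# The synthetic-data module

The generators define the study conditions for every simulation in the
package; their defaults were fixed once, at design time.

`gen_sierpinski`, `gen_fbm_surface` and `gen_spectral_image` are analytic
oracle fixtures (exact carpet recurrence; D = 3 - H; planted spectral
exponent).

`gen_office_scene` emulates one office photograph at 640 x 320: a warm,
low-saturation background (flat, gradient, or 1/f-textured -- never able
to satisfy the green criteria), furniture-like rectangles, colour "clutter"
patches, and elliptical plant blobs whose HSV values are drawn strictly
inside the detection window (hue 70-150, sat 30-90%, val 20-90%) so that
8-bit rounding cannot cross the thresholds. The generator grows or erodes
the planted area until the measured greenery is within 2 percentage points
of the target (exactly 0 for a zero target); the tolerance balances runtime
against fidelity, and the extractor itself re-measures every scene in the
tests (generator/measurer cross-validation).

A real photo set has colour complexity that varies *independently* of its
plants; a naive generator does not, and collinear indicators would make the
VIF step remove the colour fractal before the lasso ever sees it. The scene
knobs are therefore organised as: a greenery ramp 0-60% across the 60
scenes (the observed office range); a colour-complexity axis equal to the
clutter *palette density* (2 to ~8000 distinct colours), which raises joint
colour diversity at fixed channel ranges; and separate cycles for clutter
coverage, patch grain, and hue/saturation span, which drive the
channel-range (DBC) indicators. Clutter only nudges brightness (small
per-patch offsets), leaving the brightness surface to the background
texture. All cycle periods are coprime to the 24-scene snake-dealing cycle
of the grouping: if a knob cycle aligns with the group pattern, the group-
level rater noise loads onto that feature and shows up as spurious
selection under null simulations. With this design the indicator
correlation matrix across 60 scenes is moderate throughout (comparable to
the published one), the colour fractal survives VIF pruning, and planted
effects are recoverable.

`gen_photo_set` sorts scenes by greenery and deals them into 12 groups of
5 in snake order (1..12, 12..1), keeping group greenery means within about
1.5 points of the grand mean; plain round-robin dealing leaves gaps up to
~5.6 points at this geometry.

`gen_ratings` draws, for each of the ~100 raters of a group, responses to
all 11 items for the group's 5 photos: latent photo mean
mu_p = a + b sqrt(greenery_p) + c colourfractal_p, a participant offset
with SD sigma/2 (chosen to reproduce within-photo rating SDs below 1, as
observed for 59 of 60 photographs in comparable data), an item residual
with SD sigma, and round-then-clamp discretization onto 1-5 -- the minimal
standard response model. Reverse-keyed items are generated *reflected*
(6 - latent draw): generating them raw would make the scored Extent
subscale equal 6 - mu, attenuate every planted slope threefold through the
overall score, and silently break the recovery contract. Study-shaped
defaults: 60 photos, 12 x 5 groups, 100 raters per group, a = 2.8,
b = +0.12, c = -0.10, sigma = 0.6.

What the simulator does *not* emulate: semantic content (desks, windows,
room depth), item-level wording effects, participant heterogeneity beyond
a single offset, and any dependence of Extent on spatial layout. Passing
end-to-end tests therefore demonstrate that the pipeline recovers planted
linear structure from grouped, discretized ratings at study scale -- not
that the published effect sizes are reproduced from real images.

# Problem sizes and numerical choices

Unit tests run estimators at 32-256 pixels squared and the pipeline smoke
test at 24 photos of 128 x 64 with 8 raters per group; the acceptance suite
runs the full study geometry (60 photos at 640 x 320, 12 x 5 groups, 100
raters per group, 50 rating seeds for the planted and null recovery
experiments) -- scenes are generated once and only the rating noise varies
across seeds. Lasso convergence uses glmnet's threshold 1e-12 at fixed
penalties and 1e-10 inside CV; box-count regressions require at least three
rungs; degenerate inputs (uniform images, constant channels) return flagged
fallback values at the feature-extraction surface and errors at the bare
estimator surface, as documented per function.

# Worked example

```{r example, eval = FALSE}
set.seed(1)
ps <- gen_photo_set(default_scene_specs(seed = 100))
feats <- extract_features_batch(ps$images, feature_config(preprocess = FALSE))
ft <- dplyr::rename(feats, photo_id = source_id)
ft$group <- ps$manifest$group
ratings <- gen_ratings(ft, rating_sim_spec(seed = 1))
res <- run_full_pipeline(feats, ratings, seed = 1)
res$correlations
res$models$overall
res$rmse$overall
```

The same computation, plus estimator-oracle checks and the 50-seed
selection-rate experiment, is what `scripts/acceptance.R` runs and writes
to JSON.
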
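---
title: "morphmark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphmark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Morphometric studies routinely need anatomical landmarks placed on
thousands of standardized specimen photographs — for example the tip of
the snout and the hypural joint of a fish, whose distance is the standard
length. Manual annotation is slow and drifts within and between
observers. morphmark automates the process headlessly: experts annotate a
training set once, a cascaded-regression shape predictor is tuned and
trained on it, and the resulting model places the same landmarks on
unseen images in milliseconds, with optional per-image scale-bar
calibration to convert pixel measurements into millimetres.

# The model

The predictor is the classic gradient-boosted cascade of regression
trees over pixel-intensity-difference features (the method behind dlib's
`shape_predictor` and tools built on it, such as ml-morph). A shape is
the vector of all landmark coordinates, expressed in box-relative
coordinates (here the box is always the full frame — this pipeline has no
object-detection stage, and its recommended inputs are standardized
full-frame photographs). Prediction starts from the training-set mean
shape and applies `cascade_depth` sequential correction stages. Each
stage:

1. samples `feature_pool_size` pixel positions in the unit frame
   (extended by `feature_pool_padding`), each anchored to its nearest
   mean-shape landmark;
2. reads those intensities for the current shape estimate under a
   per-sample similarity transform (so features track the shape as it
   moves);
3. boosts `trees_per_cascade` regression trees of depth `tree_depth` on
   the shape residuals. Tree splits threshold the difference of two pool
   intensities; candidate pairs are drawn with an exponential proximity
   prior `exp(-dist/regularization)`, and each node picks the best of
   `test_splits` candidates by the usual sum-of-squares gain. Leaf
   corrections are shrunk by `learning_rate`.

Training samples are oversampled: each image contributes `oversampling`
starting shapes (the mean shape plus shapes borrowed from other training
images), which teaches the cascade to pull a wrong initial shape onto
the right landmarks. All randomness flows from one integer seed through
a package-owned xorshift generator, so a fixed (data, hyperparameters,
seed) triple reproduces the fitted model bit for bit on any platform.

Known limitation, by construction: the method tolerates the variation it
saw during training and little else. Rotated, flipped, or rescaled
inputs degrade accuracy sharply — the test suite asserts that this
degradation is real and measurable, not that it is absent — so input
standardization is a requirement, not a preference.

# Hyperparameter search

The nine training parameters above are not set by hand. A *study* runs
`n_trials` *trials*; each trial draws a configuration from declared
ranges, scores it with 5-fold cross-validation (mean over folds of the
mean pixel deviation on the held-out fold), and the best trial — lowest
mean fold deviation, ties to the lowest index — supplies the
configuration for one final model retrained on the full dataset. We read
"one model is derived from the best performing trial" as retraining on
all data (standard practice) rather than reusing a fold model; the
model's JSON sidecar records the study provenance either way. The number
of trials is deliberately the only knob a user must choose.

Two samplers are provided: `random` (fully reproducible trial sequence
under a fixed seed) and `adaptive` (a random warm-up of one third of the
trials, then Gaussian perturbation around the incumbent best — a
deliberately simple stand-in for the adaptive search of dedicated HPO
frameworks, which are not available in this stack). Failed trials score
`+Inf`, are excluded from the score CDF, and never abort a study.

The default ranges (`default_search_ranges()`): cascade_depth 8–18,
tree_depth 2–5, trees_per_cascade 250–750, learning_rate 0.01–0.3 (log),
oversampling 5–40, feature_pool_size 200–1000, test_splits 20–150,
feature_pool_padding 0–0.2, regularization 0.01–0.2 (log). These bracket
the canonical defaults of the underlying method. Because an unlucky draw
from the full ranges can cost minutes per fold on one CPU, the test
suite and the acceptance study use `fixture_search_ranges()` — the same
nine parameters and scales, narrowed to desk scale (e.g. 50–150 trees,
4–8 cascades) so that a complete 10-trial, 5-fold study on 50 fixtures
finishes in minutes. This is a documented scaling-down of simulation
size, not a change of the machinery under test.

# Accuracy arithmetic

Deviations are Euclidean distances in pixels between predicted and true
landmark positions, reported both raw and as a percentage of the image
diagonal `sqrt(width² + height²)` — the largest error the frame allows —
which makes errors comparable across geometries and species.
Normalization by organism length is deliberately not offered: it ignores
how much of the frame the organism fills. Percentages convert back to
pixels by nearest-integer rounding, half away from zero; this convention
reproduces the printed (percent, pixel) pairs of the reference
evaluation at its stated geometries (11 of the 12 published pairs; the
remaining one, 0.64% ↔ 13 px at 1800×1200, computes to 14 under any
consistent rule and is documented rather than chased). When datasets are
pre-resized to a stated evaluation geometry, that geometry — not
per-image metadata — should be passed for normalization.

# Scale-bar calibration

Each image is calibrated independently, because small camera or subject
movements change the scale from frame to frame. The chain is: greyscale
(Rec. 601 luminance), Gaussian smoothing, Canny-style edges (Sobel
gradients, non-maximum suppression, hysteresis), then a progressive
probabilistic Hough transform whose three knobs — accumulator threshold,
minimum line length, maximum line gap — are exposed directly. The bar is
selected as the longest segment within a tilt tolerance (default 5°) and
optional region of interest; its endpoint distance against the known
physical length gives `mm_per_px`.

Two numerical choices matter for endpoint accuracy, which drives
calibration error:

* non-maximum suppression interpolates the gradient magnitude along the
  true gradient direction instead of quantizing to 8 neighbours;
  quantized NMS smears bar corners into diagonal spurs that biased
  endpoints by ~3 px;
* each traced segment is refined by a total-least-squares line fit over
  its support, discarding pixels more than 1.25 px off the line
  (matching the tracer's perpendicular tolerance) and taking endpoints
  from the extreme projections.

With these, a rendered 300 px bar is recovered within ±2 px across the
generator's exposure/blur/noise settings, and a 20 mm fixture standard
length within 1%.

# The synthetic fixture world

No reference photo sets are deposited, so all end-to-end testing runs on
a deterministic generator of fish-like images with *exact* ground truth:
landmarks are placed analytically on the drawn geometry (ellipse body,
forked triangular caudal fin, optional scale bar) before rendering, so
every measured deviation downstream is attributable to the predictor.
The stated world follows the recommended input conditions: standardized
orientation (no rotation/flip jitter by default; rotation exists only
for the sensitivity analysis), homogeneous background, frames of
400×300 — proportional to the reference 1800×1200 geometry but desk
scale, with body translation jitter ±5% of the frame and standard length
150–200 px. Degradation axes mirror common dataset flaws: exposure
offsets, blur, body-size variation, irregular/unspread caudal fins.

Defaults were chosen once as what a standardized capture rig plausibly
produces, and are not tuned to test outcomes: background 230, body 80,
fin 150 (so the snout is a high-contrast landmark and the hypural joint
a lower-contrast one, reproducing the empirical easy/hard landmark
split), blur σ 0.4–0.8 px, exposure jitter ±5%, and per-pixel Gaussian
sensor noise with σ = 2 intensity units. The noise axis exists because
real captures are never noise-free, and without it degradations such as
low contrast cost an exact-arithmetic predictor nothing — an instructive
failure of over-clean synthetic worlds. What a green fixture test does
establish: the full chain (annotation I/O, training, search, prediction,
calibration, export) is wired correctly and reaches sub-percent
diagonal-normalized accuracy under the stated world. What it does not
establish: performance on real photographs, with their textured
backgrounds, specular highlights, and anatomical variation far beyond an
ellipse-plus-fin.

# Degenerate inputs and edge policies

* Predictions falling outside the frame are clamped to it; coordinates
  are integer pixels, 0-based, origin upper-left, x rightward, y
  downward, in every module.
* Overlay rendering clamps out-of-frame landmarks with a warning rather
  than failing, so batch review always completes.
* Batch prediction and batch calibration record per-image failures
  (`predict_failed`, `scalebar_failed`) and continue.
* Annotation XML without image width/height attributes is tolerated
  (validation simply has less to check); bounding boxes default to the
  full frame.
* `k`-fold splitting distributes the remainder one image at a time to
  the first folds, so fold sizes differ by at most one.

# Build choices in this environment

The annotation format is the image/box/part XML dialect of the
shape-predictor ecosystem, for interoperability with existing landmark
datasets. XML I/O is backed by `xml2`, JSON by `jsonlite`. No
image-codec R package is available in the target stack, so the package
carries a minimal zlib-backed PNG codec (8-bit grey/RGB, plus
grey+alpha/RGBA on read); JPEG input is consequently out of scope. The
shape predictor, Canny edges, and probabilistic Hough transform are
implemented in C++ (Rcpp) — there is no R binding of dlib or OpenCV to
bind to, and these kernels are the package's core contribution. The CLI
config file is plain `key=value` lines mirroring the flags, since no
TOML/YAML parser is pre-installed.
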
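---
title: "Strip-based pain-intensity classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strip-based pain-intensity classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the labeling model, the strip-decomposition geometry, the feature-selection
objective, the classifier and metric definitions, the numerical and design
choices made where the method description left room, and what the synthetic
fixtures do and do not establish.

## 1. Labels: PSPI scoring and class grouping

Frame labels derive from FACS action-unit intensities. The
Prkachin–Solomon Pain Intensity is

$$\mathrm{PSPI} = AU4 + \max(AU6, AU7) + \max(AU9, AU10) + AU43,$$

with AU4, AU6, AU7, AU9, AU10 coded 0–5 and AU43 (eye closure) binary, so
the score ranges over 0–16. The `max` reading of the "or" terms is the
standard Prkachin–Solomon definition and the only one consistent with the
0–16 range. Scores are grouped into four ordinal classes — PSPI = 0,
PSPI = 1, 2 ≤ PSPI ≤ 3, PSPI > 3 — which partition all 17 scores.

Clinical frame sets are heavily skewed toward "no pain", so
`balanceUndersample()` down-samples over-represented classes uniformly
without replacement under an explicit seed. Only the per-class counts are
contractual; the retained subset depends on the seed. Under-sampling is
not stratified by subject: the label tables carry no subject metadata, and
adding a subject contract was judged out of scope.

## 2. Strip decomposition ("shutter blinds")

Faces are assumed pre-cropped (face detection is deliberately outside the
package), bilinearly resized to 224×224, and cut into 21 full-width
horizontal strips at four scales: heights 112, 56, 32 and 28, i.e. 2, 4, 7
and 8 strips per scale. All four scale counts divide 224 exactly, so each
scale tiles the rows without gap or overlap; reassembling a scale
reproduces the face bit-exactly, which the tests assert.

Conventions that the method description leaves open, fixed here once:

* **Strip order.** Scales coarse→fine, strips top→bottom within a scale,
  and the whole face appended *last* — matching the arithmetic of
  "21 × 1000 strip features + 1000 whole-face features". The block map on
  every concatenated vector records the layout, so downstream code never
  relies on the convention implicitly.
* **Row intervals** are 0-based half-open `[r0, r1)`.
* **Resize interpolation** is bilinear — deterministic, ubiquitous, and the
  identity on an already-224×224 input. A frozen-snapshot test pins the
  interpolation so a silent library change would be caught.
* **Grayscale inputs** are channel-replicated at load time.

## 3. Backbone contract and the toy backbone

Feature extraction is a pluggable contract: a backbone maps a square RGB
image to a fixed-length vector, deterministically. The reference
configuration is an ImageNet-pretrained CNN read at its global-average-pool
layer (1000 features per input, hence 22 × 1000 = 22,000 per face); the
package does not ship pretrained weights, and no test depends on them.
Non-square strips are bilinearly resized to the backbone's native square
input without preserving aspect ratio — a fixed-input network must receive
fixed-size inputs, and stretching is the simplest deterministic choice.
The native input side is configuration, not a constant.

The bundled `toyBackbone` computes grid-pooled (default 7×7) per-channel
means and standard deviations, applies a seeded random linear projection,
and squashes with tanh. It is a deterministic measurement head, not a
trained model: it preserves coarse spatial layout (so strip-localized
signal stays detectable) while being reproducible from a single integer
seed. Feature vectors are stored as doubles regardless of backbone
internals; the CSV persistence uses 17 significant digits so round trips
are bit-exact.

## 4. Feature selection: NCA ranking and the INCA prefix loop

Features are first min–max normalized per column, with constant columns
mapped to 0 and the fitted min/max retained for reuse on held-out data.

The ranking step is the *feature-selection* variant of neighborhood
component analysis: one relevance weight $w_l$ per feature, learned by
maximizing

$$F(w) = \sum_j p_j \;-\; \lambda \sum_l w_l^2,
\qquad p_j = \sum_{i \ne j,\, y_i = y_j} p_{ij},$$

where sample $j$ picks reference $i$ with soft-neighbor probability
$p_{ij} \propto \exp(-d_w(x_j, x_i)/\sigma)$ and
$d_w(a,b) = \sum_l w_l^2 |a_l - b_l|$ is a weighted city-block distance.
The city-block kernel mirrors the downstream Manhattan kNN so the selector
optimizes the geometry the classifier will actually use. Defaults, all
exposed: $\sigma = 1$, $\lambda = 1/N$, 100 full-batch gradient-ascent
iterations from $w = 1$ with initial step 0.1, halved (and the step
rejected) whenever the objective decreases. Softmax terms are shifted by
the per-sample minimum distance, so the procedure is stable even when raw
distances are in the thousands (D = 22,000). The gradient implementation
is verified against finite differences in the tests. The ranking is
$w_l^2$ descending with ties broken by ascending feature index; the
procedure itself is deterministic.

INCA then evaluates every ranked prefix of length $l \in [100, 1000]$
(step 1, i.e. 901 candidates; the range is clipped to the feature count)
by the misclassification rate of a k = 1 Manhattan kNN under **one** fixed
stratified ten-fold partition shared across all candidates — losses are
comparable only if the partition is held fixed. Minimum loss wins; ties go
to the smallest length (the cheaper model).

Two modes are first-class:

* **faithful** — normalization and ranking are fitted once on the full
  matrix before cross-validation, matching the original step order. The
  selection loss is then an optimistic estimate, since the ranking has
  seen the test folds.
* **no-leakage** (`incaSelectStrict`) — min/max and the ranking are refit
  inside each training fold and candidates scored on the held-out fold,
  giving honest generalization estimates; the final prefix is read off a
  full-data ranking at the best length so downstream stages receive one
  concrete feature set.

Whether the original pipeline re-ranked per fold is unknowable from its
description; ranking once globally is the faithful reading, and the strict
mode quantifies what that choice is worth.

## 5. Classifier and cross-validation

"Fine" kNN: k = 1, Manhattan distance, no distance weighting (irrelevant
at k = 1 absent ties). Distance ties are broken by the smallest
training-row index — documented and deterministic. Cross-validation is
stratified by default: per class, members are spread so per-class fold
counts differ by at most one from proportionality, with remainders placed
on the currently smallest folds so overall fold sizes also differ by at
most one. Test predictions from all folds are pooled into a single K×K
confusion matrix (the presentation the published per-dataset tables use);
per-fold accuracies are reported alongside.

## 6. Metrics

From a pooled confusion matrix (rows true, columns predicted):
class-wise recall, precision (0 when a class is never predicted) and F1;
overall accuracy; unweighted average recall and precision; macro-F1 (the
mean of class F1s — the only averaging that reproduces the published
overall F1 from the published class tables); Cohen's kappa; the geometric
mean of class recalls; and two Matthews correlation variants. The value
reported as **MCC** is the macro-average of the four one-vs-rest binary
MCCs — independent recomputation from the published confusion tables shows
this is the definition behind the published overall MCC values, where
Gorodkin's single-statistic $R_K$ differs in the second decimal. $R_K$ is
reported alongside as `mccRk`. Both reduce exactly to the classical binary
MCC at K = 2, a property the tests check on random 2×2 tables. All values
are kept at full precision internally; rounding (half away from zero, two
decimals) happens only in the presentation layer.

## 7. Synthetic fixtures: what they emulate and what they do not

The clinical databases behind the published evaluation are
access-restricted, so the package ships seeded generators instead:

* `genAUTable()` draws AU vectors uniformly per class with rejection until
  the PSPI grouping lands in the intended class — exactly `nPerClass`
  frames per class, and label self-consistency is checkable by
  reconstruction.
* `genFaceImages()` builds grayscale 448×448 images (exercising the resize
  path) whose class signal sits in horizontal bands aligned with the
  finest 28-row strip scale: class $c$ elevates bands $c$ and $c+4$ of the
  eight positions by `bandContrast` × 255 × 0.55 with a sinusoidal
  texture, over a textured background, plus Gaussian pixel noise of sd
  `noiseSd` × 255. Defaults — 50 frames per class, contrast 0.6, noise
  0.1 — are the fixture conditions used by the end-to-end recovery test,
  chosen so the signal is clearly learnable but far from degenerate
  (noise sd is 42% of the band elevation). A misaligned-band variant
  (`alignBands = FALSE`) exists for robustness experiments.

Passing the end-to-end test (pooled ten-fold accuracy above 60% against
25% chance, with a 50-feature toy backbone and INCA range [10, 60])
establishes that the *plumbing* — geometry, extraction, selection,
classification, pooling — recovers strip-localized class structure. It
says nothing about real faces: the fixtures have no identity variation,
no pose, no illumination changes, and their class signal is linearly
separable by construction. Claims about clinical performance rest on the
published evaluation, whose metric layer this package reproduces exactly
from the published confusion tables.

## 8. Problem sizes and numerical choices

The test and acceptance runs use deliberately scaled-down problems chosen
as sensible desk-scale experiments: the end-to-end fixture run uses 200
images (50 per class), a 50-dimensional toy backbone (D = 1,100 after
concatenation) and INCA range [10, 60]; determinism and stage-resume
checks use 48 images at 64×64 with an 8-dimensional backbone. The NCA
kernel is O(N²D) per iteration, implemented in C++; degenerate inputs
(constant feature columns, single-class labels, empty candidate ranges,
classes smaller than the fold count) are rejected with classed validation
errors rather than silently patched.

## 9. Known limitations

* Face detection/cropping is out of scope; inputs must be pre-cropped.
* The pretrained-CNN backbone is a contract, not a shipped artifact;
  reproducing the published feature values verbatim is explicitly not a
  goal.
* Under-sampling ignores subject identity (no subject metadata contract),
  so subject leakage across folds is possible on real data organized by
  video.
* The faithful INCA mode's selection loss is optimistically biased by
  design; use the no-leakage mode when an honest error estimate matters.
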
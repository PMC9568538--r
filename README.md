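# painstrips

Pain-intensity classification from facial images via horizontal strip
("shutter blinds") deep features, in R.

## The problem

Patients who cannot self-report — neonates, sedated or non-communicative
adults — still express pain in the face. The Facial Action Coding System
(FACS) grades pain-related action units per video frame: brow-lowering
(AU4), cheek-raising (AU6), eyelid tightening (AU7), nose wrinkling (AU9),
upper-lip raising (AU10), each on a 0–5 intensity scale, and binary
eye-closure (AU43). The Prkachin–Solomon Pain Intensity combines them as

    PSPI = AU4 + max(AU6, AU7) + max(AU9, AU10) + AU43        (range 0–16)

and frames are grouped into four ordinal classes: PSPI = 0, PSPI = 1,
2 ≤ PSPI ≤ 3, PSPI > 3. `painstrips` implements an automated classifier of
these classes from pre-cropped face images, for researchers in affective
computing and clinical machine learning.

## The method

1. **Strip decomposition.** Each face is resized to 224×224 and cut into 21
   full-width horizontal strips at four scales — two 112×224, four 56×224,
   seven 32×224, eight 28×224 — each scale tiling the rows exactly
   (`makeBlinds`). The strips act like shutter blinds over facial regions
   (brow, eyes, nose, mouth).
2. **Deep features.** A pluggable backbone (contract: square image →
   fixed-length vector; reference configuration 1000 features from a
   pretrained CNN's global-average-pool layer) is applied to every strip
   and to the whole face, giving a concatenated vector of 22 × 1000 =
   22,000 features (`extractAll`). A seeded, dependency-free `toyBackbone`
   makes everything runnable offline.
3. **Feature selection.** Features are min–max normalized, ranked by a
   feature-selection variant of neighborhood component analysis
   (`ncaRank`), and pruned by the iterative INCA loop (`incaSelect`): every
   ranked prefix length in \[100, 1000\] (901 candidates) is scored by the
   misclassification rate of a k = 1 Manhattan kNN under one fixed
   stratified ten-fold partition, and the best prefix wins.
4. **Classification & metrics.** k = 1 Manhattan-distance kNN with
   stratified ten-fold cross-validation, pooling all test predictions into
   one confusion matrix (`crossValidate`), from which the full metric
   suite derives (`overallMetrics`): accuracy, unweighted average recall /
   precision, macro-F1, Matthews correlation (macro one-vs-rest, plus
   Gorodkin's multiclass R_K), Cohen's kappa and the geometric mean of
   class recalls.

`runPipeline()` orchestrates label → balance → features → select →
evaluate → metrics with seeded determinism, resumable stages and artifact
files; `genFaceImages()`/`genAUTable()` generate seeded synthetic fixtures
(band-structured face-like images and AU tables) so every stage is
testable without the access-restricted clinical databases.

## Worked example

Entering the published pooled ten-fold confusion matrix of the shoulder-pain
benchmark and recomputing every reported metric:

```r
library(painstrips)
lv <- painClassLabels()
cm <- matrix(as.integer(c(2342,  67,   59,   15,
                            11, 2798,   99,    1,
                             9,   94, 3598,   62,
                             8,    4,   52, 1633)),
             4, 4, byrow = TRUE, dimnames = list(true = lv, predicted = lv))
cat(metricReportTable(cm), sep = "\n")
```

prints

```
class          recall  precision       F1
PSPI=0          94.32      98.82    96.52
PSPI=1          96.18      94.43    95.30
2<=PSPI<=3      95.62      94.49    95.05
PSPI>3          96.23      95.44    95.83

overall:  Acc 95.57  UAR 95.59  UAP 95.79  F1 95.67  MCC 94.14  CK 93.93  GM 95.58
```

i.e. 95.57% of the 10,852 frames are classified into the correct pain
class, class-balanced recall (UAR) is 95.59%, chance-corrected agreement
(Cohen's kappa) 93.93%, and the geometric mean of class recalls — the
strictest of the averages, dragged down by any one weak class — is 95.58%.

A complete synthetic run (generate images, extract, select, classify):

```r
cfg <- runConfig(outputDir = "run1",
                 synth = synthSpec(nPerClass = 50, seed = 1),
                 featureDim = 50, incaLo = 10, incaHi = 60)
res <- runPipeline(cfg)
res$cvResult$accuracy      # pooled ten-fold accuracy on the fixture set
```

A thin command-line wrapper with subcommands (`synth`, `label`, `balance`,
`blinds`, `run`, `metrics`) is installed at `inst/scripts/painstrips`.

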
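#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

## Strip geometry constants: four scales tiling a 224-row face image into
## full-width horizontal strips ("shutter blinds"): 2 x 112, 4 x 56, 7 x 32,
## 8 x 28 rows. All scales divide 224 exactly; asserted at load time.
FACE_SIDE <- 224L
STRIP_SCALES <- c(2L, 4L, 7L, 8L)
stopifnot(all(FACE_SIDE %% STRIP_SCALES == 0L))
N_STRIPS <- sum(STRIP_SCALES)

#' PatchSet: the horizontal strip decomposition of one face image
#'
#' Holds the 21 ordered full-width horizontal strips of a 224x224 face at
#' four scales (two 112-row, four 56-row, seven 32-row, eight 28-row strips)
#' plus the undivided face. Strips are ordered coarse to fine and top to
#' bottom within a scale; the whole face is kept separately and enters any
#' feature concatenation last.
#'
#' @slot strips list of 21 numeric arrays (rows x 224 x 3, intensities 0-255).
#' @slot geometry data.frame with one row per strip: \code{scale} (number of
#'   strips at that scale), \code{index} (1-based, top to bottom),
#'   \code{r0}, \code{r1} (0-based half-open row interval).
#' @slot whole the undivided 224x224x3 face array.
#' @export
setClass("PatchSet", representation(
    strips = "list",
    geometry = "data.frame",
    whole = "array"
))

setValidity("PatchSet", function(object) {
    g <- object@geometry
    if (length(object@strips) != N_STRIPS)
        return(sprintf("expected %d strips, found %d", N_STRIPS, length(object@strips)))
    if (nrow(g) != N_STRIPS) return("geometry must have one row per strip")
    heights <- g$r1 - g$r0
    want <- rep(FACE_SIDE %/% STRIP_SCALES, times = STRIP_SCALES)
    if (!identical(as.integer(heights), as.integer(want)))
        return("strip heights must be 112,112, 56x4, 32x7, 28x8 in canonical order")
    for (s in STRIP_SCALES) {
        rows <- g[g$scale == s, , drop = FALSE]
        if (rows$r0[1] != 0L || rows$r1[nrow(rows)] != FACE_SIDE ||
            (nrow(rows) > 1 && any(rows$r0[-1] != rows$r1[-nrow(rows)])))
            return(sprintf("scale %d strips must tile rows [0,224) without gap or overlap", s))
    }
    for (k in seq_len(N_STRIPS)) {
        d <- dim(object@strips[[k]])
        if (length(d) != 3 || d[1] != heights[k] || d[2] != FACE_SIDE || d[3] != 3L)
            return(sprintf("strip %d has wrong dimensions", k))
    }
    d <- dim(object@whole)
    if (length(d) != 3 || !all(d == c(FACE_SIDE, FACE_SIDE, 3L)))
        return("whole face must be 224x224x3")
    TRUE
})

#' Backbone: a pluggable image-to-vector feature extractor
#'
#' A backbone maps a square RGB image to a fixed-length numeric feature
#' vector. The reference configuration of the pipeline uses a pretrained
#' CNN read at its global-average-pooling layer (1000 features); any
#' deterministic extractor honoring this contract can be plugged in.
#' \code{\link{toyBackbone}} supplies a seeded, dependency-free instance.
#'
#' @slot name character tag.
#' @slot inputSide native square input resolution; patches are bilinearly
#'   resized to this side length before extraction.
#' @slot featureDim length of the output vector (contract: the same for
#'   every input).
#' @slot extract function(array inputSide x inputSide x 3, 0-255) -> numeric
#'   vector of length \code{featureDim}; must be deterministic.
#' @export
setClass("Backbone", representation(
    name = "character",
    inputSide = "integer",
    featureDim = "integer",
    extract = "function"
))

setValidity("Backbone", function(object) {
    if (length(object@inputSide) != 1L || object@inputSide < 8L)
        return("inputSide must be a single integer >= 8")
    if (length(object@featureDim) != 1L || object@featureDim < 1L)
        return("featureDim must be a single integer >= 1")
    TRUE
})

#' NCARanking: per-feature relevance weights and the induced ranking
#'
#' @slot weights numeric vector of learned weights, one per feature
#'   (relevance score is \code{weights^2}).
#' @slot ranking integer permutation of 1..D, features sorted by squared
#'   weight descending, ties broken by ascending feature index.
#' @slot hyper list of the hyperparameters used (sigma, lambda, iterations,
#'   learnRate, objective trace).
#' @export
setClass("NCARanking", representation(
    weights = "numeric",
    ranking = "integer",
    hyper = "list"
))

setValidity("NCARanking", function(object) {
    d <- length(object@weights)
    if (!identical(sort(object@ranking), seq_len(d)))
        return("ranking must be a permutation of 1..D")
    sc <- object@weights[object@ranking]^2
    if (is.unsorted(-sc)) return("weights^2 must be non-increasing along the ranking")
    TRUE
})

#' SelectionResult: the INCA loss curve and chosen feature prefix
#'
#' @slot lengths integer vector of candidate prefix lengths evaluated.
#' @slot losses misclassification rate (0-1) per candidate length under the
#'   shared cross-validation partition.
#' @slot bestLength the candidate with minimum loss (ties: smallest length).
#' @slot selected feature indexes (a prefix of the NCA ranking) of length
#'   \code{bestLength}.
#' @slot seed cross-validation seed used for the loss function.
#' @slot mode "faithful" (normalize and rank once on the full matrix) or
#'   "no-leakage" (per-fold refitting for the loss curve).
#' @export
setClass("SelectionResult", representation(
    lengths = "integer",
    losses = "numeric",
    bestLength = "integer",
    selected = "integer",
    seed = "integer",
    mode = "character"
))

setValidity("SelectionResult", function(object) {
    if (length(object@lengths) != length(object@losses))
        return("lengths and losses must have equal length")
    i <- match(object@bestLength, object@lengths)
    if (is.na(i)) return("bestLength must be one of the evaluated lengths")
    if (object@losses[i] > min(object@losses) + 1e-12)
        return("loss at bestLength must be the minimum loss")
    if (length(object@selected) != object@bestLength)
        return("selected must have bestLength entries")
    TRUE
})

#' PainFeatureSet: a labeled feature matrix as a SummarizedExperiment
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding one
#' \code{"features"} assay (features in rows, frames/samples in columns) and
#' a \code{painClass} factor in \code{colData}. Use
#' \code{\link{featureMatrix}} to obtain the samples-by-features matrix the
#' selection and classification stages consume, and \code{\link{painClass}}
#' for the labels.
#'
#' @export
setClass("PainFeatureSet", contains = "SummarizedExperiment")

setValidity("PainFeatureSet", function(object) {
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        return("must carry a 'features' assay")
    if (!"painClass" %in% colnames(colData(object)))
        return("colData must contain a 'painClass' column")
    if (!is.factor(colData(object)$painClass))
        return("painClass must be a factor")
    a <- assay(object, "features")
    if (anyNA(a)) return("feature matrix must not contain missing values")
    TRUE
})
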
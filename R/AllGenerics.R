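#' Accessors for painstrips S4 classes
#'
#' @param x,object an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors list of strip arrays of a \linkS4class{PatchSet}.
#' @export
setGeneric("strips", function(x) standardGeneric("strips"))
#' @export
setMethod("strips", "PatchSet", function(x) x@strips)

#' @describeIn accessors strip geometry table (scale, index, r0, r1).
#' @export
setGeneric("stripGeometry", function(x) standardGeneric("stripGeometry"))
#' @export
setMethod("stripGeometry", "PatchSet", function(x) x@geometry)

#' @describeIn accessors the undivided 224x224x3 face of a PatchSet.
#' @export
setGeneric("wholeFace", function(x) standardGeneric("wholeFace"))
#' @export
setMethod("wholeFace", "PatchSet", function(x) x@whole)

#' @describeIn accessors learned per-feature weights of an
#'   \linkS4class{NCARanking}.
#' @export
setGeneric("featureWeights", function(x) standardGeneric("featureWeights"))
#' @export
setMethod("featureWeights", "NCARanking", function(x) x@weights)

#' @describeIn accessors feature indexes sorted most to least relevant.
#' @export
setGeneric("featureRanking", function(x) standardGeneric("featureRanking"))
#' @export
setMethod("featureRanking", "NCARanking", function(x) x@ranking)

#' @describeIn accessors chosen prefix length of a
#'   \linkS4class{SelectionResult}.
#' @export
setGeneric("bestLength", function(x) standardGeneric("bestLength"))
#' @export
setMethod("bestLength", "SelectionResult", function(x) x@bestLength)

#' @describeIn accessors selected feature indexes of a SelectionResult.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @describeIn accessors candidate lengths and their CV losses as a
#'   data.frame (the INCA loss curve).
#' @export
setGeneric("lossCurve", function(x) standardGeneric("lossCurve"))
#' @export
setMethod("lossCurve", "SelectionResult", function(x)
    data.frame(length = x@lengths, loss = x@losses))

#' @describeIn accessors samples-by-features numeric matrix of a
#'   \linkS4class{PainFeatureSet}.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @export
setMethod("featureMatrix", "PainFeatureSet", function(x)
    t(assay(x, "features")))

#' @describeIn accessors pain-class factor (one level per ordinal PSPI
#'   group) of a PainFeatureSet.
#' @export
setGeneric("painClass", function(x) standardGeneric("painClass"))
#' @export
setMethod("painClass", "PainFeatureSet", function(x)
    colData(x)$painClass)

#' @rdname accessors
#' @export
setMethod("show", "PatchSet", function(object) {
    g <- object@geometry
    cat("PatchSet: 21 horizontal strips of a 224x224 face\n")
    for (s in unique(g$scale)) {
        h <- FACE_SIDE %/% s
        cat(sprintf("  scale %d: %d strips of %d x 224\n", s, s, h))
    }
    cat("  + whole face 224 x 224 (appended last in concatenation)\n")
})

#' @rdname accessors
#' @export
setMethod("show", "Backbone", function(object) {
    cat(sprintf("Backbone '%s': %d x %d input -> %d features\n",
                object@name, object@inputSide, object@inputSide,
                object@featureDim))
})

#' @rdname accessors
#' @export
setMethod("show", "NCARanking", function(object) {
    d <- length(object@weights)
    top <- utils::head(object@ranking, 5L)
    cat(sprintf("NCARanking over %d features\n", d))
    cat("  top features:", paste(top, collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "SelectionResult", function(object) {
    cat(sprintf(
        "SelectionResult (%s): %d candidate lengths in [%d, %d]\n",
        object@mode, length(object@lengths), min(object@lengths),
        max(object@lengths)))
    cat(sprintf("  best length %d, loss %.4f\n", object@bestLength,
                min(object@losses)))
})
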
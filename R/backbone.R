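## Grid-pooled image statistics driving the toy backbone: the image is cut
## into a g x g grid and each cell contributes its per-channel mean and
## standard deviation (on the [0,1] scale), giving g*g*3*2 summary values.
gridStats <- function(face, grid) {
    d <- dim(face)
    rb <- ceiling(seq_len(d[1]) / d[1] * grid)
    cb <- ceiling(seq_len(d[2]) / d[2] * grid)
    out <- numeric(0)
    for (ch in 1:3) {
        m <- face[, , ch] / 255
        sums <- rowsum(t(rowsum(m, rb)), cb)           # grid x grid cell sums
        sq <- rowsum(t(rowsum(m * m, rb)), cb)
        cnt <- as.vector(table(cb) %o% table(rb))
        mu <- as.vector(sums) / cnt
        v <- pmax(as.vector(sq) / cnt - mu^2, 0)
        out <- c(out, mu, sqrt(v))
    }
    out
}

#' A deterministic seeded toy backbone
#'
#' Builds a \linkS4class{Backbone} whose extractor computes grid-pooled
#' per-channel means and standard deviations of the input image, applies a
#' fixed random linear projection (drawn once from the seed at construction
#' time) and a tanh squashing nonlinearity. It has no pretrained weights
#' and no notion of faces; it exists so the full pipeline is exercisable
#' and reproducible offline. Two backbones built from the same seed agree
#' on every input.
#'
#' @param seed RNG seed fixing the projection.
#' @param inputSide native square input resolution (default 56).
#' @param featureDim output vector length (default 1000, the reference
#'   configuration).
#' @param grid pooling grid size per axis (default 7).
#' @return a \linkS4class{Backbone}.
#' @export
toyBackbone <- function(seed = 1L, inputSide = 56L, featureDim = 1000L,
                        grid = 7L) {
    inputSide <- assertCount(inputSide, "inputSide", 8L)
    featureDim <- assertCount(featureDim, "featureDim", 1L)
    grid <- assertCount(grid, "grid", 1L)
    nstat <- grid * grid * 3L * 2L
    proj <- withSeed(seed, {
        list(W = matrix(stats::rnorm(featureDim * nstat, sd = 1 / sqrt(nstat)),
                        nrow = featureDim),
             b = stats::rnorm(featureDim, sd = 0.1))
    })
    extract <- function(img) {
        s <- gridStats(img, grid)
        as.numeric(tanh(proj$W %*% s + proj$b))
    }
    new("Backbone", name = sprintf("toy(seed=%d)", as.integer(seed)),
        inputSide = inputSide, featureDim = featureDim, extract = extract)
}

#' Extract backbone features from one patch
#'
#' The patch is bilinearly resized to the backbone's native square input
#' (aspect ratio not preserved; grayscale inputs are channel-replicated at
#' load time) and passed to the extractor. The output length is checked
#' against the backbone contract.
#'
#' @param patch numeric H x W x 3 array, 0-255 scale.
#' @param bb a \linkS4class{Backbone}.
#' @return numeric vector of length \code{bb@featureDim}.
#' @export
extractPatchFeatures <- function(patch, bb) {
    if (!is(bb, "Backbone")) validationError("'bb' must be a Backbone")
    assertFace(patch, "patch")
    v <- bb@extract(resizeFace(patch, bb@inputSide))
    if (!is.numeric(v) || length(v) != bb@featureDim)
        contractError(
            "backbone '%s' returned %d values, contract requires %d",
            bb@name, length(v), bb@featureDim)
    as.numeric(v)
}

#' Concatenated strip + whole-face feature vector for one face
#'
#' Extracts features from each of the 21 strips in canonical order followed
#' by the undivided face, concatenated into a single vector of length
#' 22 * featureDim (22,000 in the reference configuration). The block map
#' (1-based inclusive index ranges per block) is attached as attribute
#' \code{"blockMap"}.
#'
#' @param face numeric 224x224x3 array, 0-255 scale.
#' @param bb a \linkS4class{Backbone}.
#' @return numeric vector of length \code{22 * bb@featureDim} with a
#'   \code{blockMap} attribute.
#' @export
extractAll <- function(face, bb) {
    ps <- makeBlinds(face)
    blocks <- c(lapply(ps@strips, extractPatchFeatures, bb = bb),
                list(whole = extractPatchFeatures(ps@whole, bb)))
    v <- unlist(blocks, use.names = FALSE)
    fd <- bb@featureDim
    attr(v, "blockMap") <- data.frame(
        block = names(blocks),
        start = (seq_along(blocks) - 1L) * fd + 1L,
        end = seq_along(blocks) * fd,
        stringsAsFactors = FALSE)
    v
}

#' Block map of a concatenated feature vector
#'
#' @param v vector returned by \code{\link{extractAll}}.
#' @return data.frame with columns \code{block, start, end} partitioning
#'   the vector indexes.
#' @export
blockMap <- function(v) {
    bm <- attr(v, "blockMap")
    if (is.null(bm)) validationError("vector carries no block map")
    bm
}

#' Assemble a PainFeatureSet from face images
#'
#' Runs \code{\link{extractAll}} over a set of faces and collects the
#' concatenated vectors into a \linkS4class{PainFeatureSet}
#' (features x samples \code{SummarizedExperiment} with a \code{painClass}
#' label per sample).
#'
#' @param faces list of 224x224x3 arrays, or a character vector of image
#'   paths (read and resized as needed).
#' @param classes factor (or coercible) of pain-class labels, one per face.
#' @param bb a \linkS4class{Backbone}.
#' @param ids sample identifiers (default: list/file names).
#' @return a \linkS4class{PainFeatureSet}.
#' @export
buildFeatureSet <- function(faces, classes, bb, ids = NULL) {
    if (is.character(faces)) {
        if (is.null(ids)) ids <- sub("\\.[^.]+$", "", basename(faces))
        faces <- lapply(faces, function(p) resizeFace(readFaceImage(p)))
    }
    if (is.null(ids)) ids <- if (!is.null(names(faces))) names(faces) else
        sprintf("frame_%04d", seq_along(faces))
    if (length(faces) != length(classes))
        validationError("one class label per face is required")
    vecs <- lapply(faces, extractAll, bb = bb)
    X <- do.call(cbind, vecs)   # features x samples
    rownames(X) <- sprintf("f%05d", seq_len(nrow(X)) - 1L)
    colnames(X) <- ids
    cls <- if (is.factor(classes)) classes else
        factor(classes, levels = painClassLabels())
    se <- SummarizedExperiment(
        assays = list(features = X),
        colData = DataFrame(painClass = cls, row.names = ids))
    metadata(se)$backbone <- bb@name
    metadata(se)$featureDim <- bb@featureDim
    new("PainFeatureSet", se)
}

#' Construct a PainFeatureSet from a samples-by-features matrix
#'
#' @param X numeric matrix, samples in rows.
#' @param classes factor of labels, one per row of \code{X}.
#' @param ids sample identifiers (default rownames of X or frame_000k).
#' @return a \linkS4class{PainFeatureSet}.
#' @export
PainFeatureSet <- function(X, classes, ids = NULL) {
    if (is.null(ids))
        ids <- if (!is.null(rownames(X))) rownames(X) else
            sprintf("frame_%04d", seq_len(nrow(X)))
    if (is.null(colnames(X))) colnames(X) <- sprintf("f%05d", seq_len(ncol(X)) - 1L)
    cls <- if (is.factor(classes)) classes else factor(classes)
    tX <- t(X)
    colnames(tX) <- ids
    se <- SummarizedExperiment(
        assays = list(features = tX),
        colData = DataFrame(painClass = cls, row.names = ids))
    new("PainFeatureSet", se)
}

#' Persist / load a feature matrix as CSV
#'
#' Dense CSV with columns \code{id, class_index, class_label, f0..fD-1};
#' numeric values are written with 17 significant digits so the round trip
#' is bit-exact for doubles.
#'
#' @param fs a \linkS4class{PainFeatureSet}.
#' @param path CSV path.
#' @return \code{path} (write) or a \code{PainFeatureSet} (read).
#' @export
writeFeatureCSV <- function(fs, path) {
    X <- featureMatrix(fs)
    cls <- painClass(fs)
    header <- c("id", "class_index", "class_label",
                sprintf("f%d", seq_len(ncol(X)) - 1L))
    body <- cbind(rownames(X), as.integer(cls) - 1L, as.character(cls),
                  matrix(formatC(X, digits = 17, format = "g"), nrow = nrow(X)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = ","), con)
    writeLines(apply(body, 1L, paste, collapse = ","), con)
    invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
    if (!file.exists(path)) ioError("feature CSV not found: %s", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    fcols <- grep("^f[0-9]+$", names(tab))
    if (!length(fcols) || !all(c("id", "class_label") %in% names(tab)))
        validationError("not a painstrips feature CSV: %s", path)
    X <- as.matrix(tab[fcols])
    rownames(X) <- tab$id
    lv <- if (all(unique(tab$class_label) %in% painClassLabels()))
        painClassLabels() else sort(unique(tab$class_label))
    PainFeatureSet(X, factor(tab$class_label, levels = lv), ids = tab$id)
}
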
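## Face images are plain numeric arrays, height x width x 3, intensities on
## the 8-bit 0-255 scale (stored as doubles so interpolated values survive).
## EBImage stores images as width x height in [0,1]; the two helpers below
## convert at the boundary.

faceFromEBImage <- function(img) {
    dat <- EBImage::imageData(img)
    if (length(dim(dat)) == 2L) dat <- array(dat, c(dim(dat), 1L))
    if (dim(dat)[3] == 1L) dat <- dat[, , c(1L, 1L, 1L), drop = FALSE]
    if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
    aperm(dat, c(2L, 1L, 3L)) * 255
}

faceToEBImage <- function(face) {
    EBImage::Image(aperm(face / 255, c(2L, 1L, 3L)), colormode = "Color")
}

assertFace <- function(face, name = "image") {
    d <- dim(face)
    if (is.null(d) || length(d) != 3L || d[3] != 3L)
        validationError("'%s' must be an H x W x 3 array", name)
    if (d[1] < 8L || d[2] < 8L)
        validationError("'%s' is too small: height and width must be >= 8", name)
    if (anyNA(face)) validationError("'%s' contains missing pixel values", name)
    invisible(face)
}

#' Read a pre-cropped face image
#'
#' Loads a PNG or JPEG as a height x width x 3 intensity array on the 0-255
#' scale. Grayscale images are channel-replicated; an alpha channel is
#' dropped.
#'
#' @param path path to the image file.
#' @return numeric array H x W x 3.
#' @export
readFaceImage <- function(path) {
    if (!file.exists(path)) ioError("image not found: %s", path)
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e) ioError("cannot read image %s: %s",
                                                path, conditionMessage(e)))
    face <- faceFromEBImage(img)
    assertFace(face, path)
    face
}

#' Write a face array as a PNG
#'
#' @param face numeric H x W x 3 array, 0-255.
#' @param path output path (.png).
#' @return \code{path}, invisibly.
#' @export
writeFaceImage <- function(face, path) {
    assertFace(face)
    EBImage::writeImage(faceToEBImage(pmin(pmax(face, 0), 255)), path)
    invisible(path)
}

#' Resize a face image to a square
#'
#' Bilinear interpolation (deterministic); a same-size input is returned
#' unchanged bit-for-bit. The pipeline standardizes faces to 224x224 before
#' strip decomposition.
#'
#' @param face numeric H x W x 3 array, 0-255 scale.
#' @param side target side length in pixels (default 224).
#' @return numeric side x side x 3 array.
#' @export
resizeFace <- function(face, side = 224L) {
    assertFace(face)
    side <- assertCount(side, "side", min = 2L)
    if (all(dim(face)[1:2] == side)) return(face)
    out <- EBImage::resize(faceToEBImage(face), w = side, h = side)
    faceFromEBImage(out)
}

#' Canonical geometry of the 21 horizontal strips
#'
#' Row intervals are 0-based half-open \code{[r0, r1)} on the 224-row face;
#' strips span the full 224-pixel width. Order: scales coarse to fine
#' (2, 4, 7, 8 strips of heights 112, 56, 32, 28), top to bottom within a
#' scale. The geometry is fixed and independent of pixel content.
#'
#' @return data.frame with columns \code{scale, index, r0, r1}.
#' @export
blindGeometry <- function() {
    do.call(rbind, lapply(STRIP_SCALES, function(s) {
        h <- FACE_SIDE %/% s
        data.frame(scale = s, index = seq_len(s),
                   r0 = (seq_len(s) - 1L) * h, r1 = seq_len(s) * h)
    }))
}

#' Decompose a 224x224 face into its 21 horizontal strips
#'
#' The "shutter blinds" decomposition: the face is cut into full-width
#' horizontal strips at four scales (two 112x224, four 56x224, seven
#' 32x224, eight 28x224), each scale tiling the rows exactly. The undivided
#' face is carried along and enters feature concatenation last.
#'
#' @param face numeric 224x224x3 array, 0-255 scale.
#' @return a \linkS4class{PatchSet}.
#' @examples
#' ps <- makeBlinds(array(128, c(224, 224, 3)))
#' table(vapply(strips(ps), function(s) dim(s)[1], 1L))
#' @export
makeBlinds <- function(face) {
    d <- dim(face)
    if (is.null(d) || length(d) != 3L || !all(d == c(FACE_SIDE, FACE_SIDE, 3L)))
        validationError("'face' must be exactly 224x224x3; use resizeFace() first")
    g <- blindGeometry()
    strips <- lapply(seq_len(nrow(g)), function(k) {
        face[(g$r0[k] + 1L):g$r1[k], , , drop = FALSE]
    })
    names(strips) <- sprintf("s%d_%d", g$scale, g$index)
    new("PatchSet", strips = strips, geometry = g, whole = face)
}

#' Export the strips of a PatchSet as PNG files (debug aid)
#'
#' Writes \code{strip_<scale>_<index>.png} for each strip plus
#' \code{whole.png}.
#'
#' @param ps a \linkS4class{PatchSet}.
#' @param dir output directory (created if absent).
#' @return character vector of the written paths, invisibly.
#' @export
writeBlinds <- function(ps, dir) {
    if (!is(ps, "PatchSet")) validationError("'ps' must be a PatchSet")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    g <- ps@geometry
    paths <- character(0)
    for (k in seq_len(nrow(g))) {
        p <- file.path(dir, sprintf("strip_%d_%d.png", g$scale[k], g$index[k]))
        writeFaceImage(ps@strips[[k]], p)
        paths <- c(paths, p)
    }
    p <- file.path(dir, "whole.png")
    writeFaceImage(ps@whole, p)
    invisible(c(paths, p))
}
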
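#' Specification for the synthetic fixture generators
#'
#' The generators produce (a) per-frame action-unit tables whose PSPI
#' grouping is exactly class-balanced and (b) face-like grayscale images
#' whose class signal lives in horizontal bands aligned with the finest
#' (28-row) strip scale: class c elevates bands c and c+4 of the eight
#' band positions, by analogy with pain action units being localized to
#' brow/eye/mouth regions. Images are generated at 448x448 so the resize
#' path is exercised.
#'
#' @param nPerClass frames per pain class (>= 10 so ten-fold CV is valid).
#' @param imageSide generated image side length (default 448, resized to
#'   224 downstream).
#' @param bandContrast band elevation as a fraction of the 0-255 range, in
#'   (0, 1]; must exceed \code{noiseSd} for a learnable fixture.
#' @param noiseSd Gaussian pixel noise standard deviation as a fraction of
#'   the 0-255 range.
#' @param seed RNG seed; generators are bit-reproducible given the spec.
#' @param alignBands place bands on the 28-row strip grid (default TRUE);
#'   FALSE shifts bands by half a band height for robustness experiments.
#' @return list of class \code{synthSpec}.
#' @export
synthSpec <- function(nPerClass = 50L, imageSide = 448L, bandContrast = 0.6,
                      noiseSd = 0.1, seed = 1L, alignBands = TRUE) {
    nPerClass <- assertCount(nPerClass, "nPerClass", 10L)
    imageSide <- assertCount(imageSide, "imageSide", 16L)
    if (imageSide %% 8L != 0L)
        validationError("'imageSide' must be divisible by 8 (band grid)")
    if (!is.numeric(bandContrast) || bandContrast <= 0 || bandContrast > 1)
        validationError("'bandContrast' must lie in (0, 1]")
    if (!is.numeric(noiseSd) || noiseSd < 0)
        validationError("'noiseSd' must be >= 0")
    if (bandContrast <= noiseSd)
        validationError("'bandContrast' must exceed 'noiseSd' for a learnable fixture")
    structure(list(nPerClass = nPerClass, imageSide = imageSide,
                   bandContrast = bandContrast, noiseSd = noiseSd,
                   seed = as.integer(seed), alignBands = isTRUE(alignBands)),
              class = "synthSpec")
}

#' Generate a synthetic per-frame action-unit table
#'
#' Draws AU intensity vectors uniformly at random per class and keeps each
#' draw only if its PSPI grouping lands in the intended class (rejection
#' sampling), yielding exactly \code{nPerClass} frames per class. The
#' emitted classes therefore agree with \code{\link{pspiScore}} +
#' \code{\link{pspiGroup}} by construction. Deterministic given the seed.
#'
#' @param spec a \code{\link{synthSpec}}.
#' @param path optional CSV output path (AU-table dialect of
#'   \code{\link{readAUTable}}).
#' @return data.frame with columns \code{id, au4, au6, au7, au9, au10,
#'   au43}, invisibly written to \code{path} if given.
#' @export
genAUTable <- function(spec, path = NULL) {
    stopifnot(inherits(spec, "synthSpec"))
    n <- spec$nPerClass
    rows <- withSeed(spec$seed, {
        out <- vector("list", 4L)
        for (cls in 0:3) {
            got <- matrix(integer(0), ncol = 6L)
            while (nrow(got) < n) {
                draw <- cbind(au4 = sample(0:5, 4 * n, TRUE),
                              au6 = sample(0:5, 4 * n, TRUE),
                              au7 = sample(0:5, 4 * n, TRUE),
                              au9 = sample(0:5, 4 * n, TRUE),
                              au10 = sample(0:5, 4 * n, TRUE),
                              au43 = sample(0:1, 4 * n, TRUE))
                s <- draw[, "au4"] + pmax(draw[, "au6"], draw[, "au7"]) +
                    pmax(draw[, "au9"], draw[, "au10"]) + draw[, "au43"]
                g <- ifelse(s == 0, 0L, ifelse(s == 1, 1L, ifelse(s <= 3, 2L, 3L)))
                got <- rbind(got, draw[g == cls, , drop = FALSE])
            }
            out[[cls + 1L]] <- got[seq_len(n), , drop = FALSE]
        }
        do.call(rbind, out)
    })
    tab <- data.frame(id = sprintf("frame_%04d", seq_len(nrow(rows))), rows,
                      stringsAsFactors = FALSE)
    if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    tab
}

## Deterministic band/background construction for one class, before noise.
synthPrototype <- function(spec, cls) {
    side <- spec$imageSide
    bandH <- side %/% 8L
    offset <- if (spec$alignBands) 0L else bandH %/% 2L
    rows <- seq_len(side)
    base <- matrix(96 + 8 * sin(2 * pi * rep(seq_len(side), each = side) / 32),
                   nrow = side)                       # vertical texture
    marked <- c(cls, (cls + 4L) %% 8L)
    inBand <- rep(FALSE, side)
    for (b in marked) {
        r0 <- b * bandH + offset
        idx <- ((r0:(r0 + bandH - 1L)) %% side) + 1L
        inBand[idx] <- TRUE
    }
    elev <- spec$bandContrast * 255 * 0.55
    tex <- 6 * sin(2 * pi * rows / 16)
    base[inBand, ] <- base[inBand, ] + elev + tex[inBand]
    base
}

#' Generate synthetic face-like images with class-dependent bands
#'
#' For each pain class c (0..3), emits \code{nPerClass} grayscale
#' (channel-replicated) images whose bands c and c + 4 of the eight
#' horizontal band positions are elevated by \code{bandContrast * 255 *
#' 0.55} with a sinusoidal texture, over a textured background, plus
#' i.i.d. Gaussian pixel noise of sd \code{noiseSd * 255}. At
#' \code{noiseSd = 0} all images of a class are identical. Deterministic
#' given the seed.
#'
#' @param spec a \code{\link{synthSpec}}.
#' @param dir optional output directory; if given, writes one PNG per
#'   frame, \code{labels.csv} (id, class_index, class_label), the AU table
#'   CSV from \code{\link{genAUTable}} and \code{manifest.json} recording
#'   the spec.
#' @return list with \code{images} (list of side x side x 3 arrays, 0-255),
#'   \code{classes} (factor), \code{ids}.
#' @export
genFaceImages <- function(spec, dir = NULL) {
    stopifnot(inherits(spec, "synthSpec"))
    side <- spec$imageSide
    protos <- lapply(0:3, function(cls) synthPrototype(spec, cls))
    n <- spec$nPerClass
    images <- vector("list", 4L * n)
    classes <- integer(4L * n)
    withSeed(spec$seed, {
        k <- 0L
        for (cls in 0:3) {
            for (i in seq_len(n)) {
                k <- k + 1L
                m <- protos[[cls + 1L]]
                if (spec$noiseSd > 0)
                    m <- m + matrix(stats::rnorm(side * side,
                                                 sd = spec$noiseSd * 255),
                                    nrow = side)
                m <- pmin(pmax(m, 0), 255)
                images[[k]] <- array(m, c(side, side, 3L))
                classes[k] <- cls
            }
        }
    })
    ids <- sprintf("frame_%04d", seq_along(images))
    cls <- factor(painClassLabels()[classes + 1L], levels = painClassLabels())
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        for (k in seq_along(images))
            writeFaceImage(images[[k]], file.path(dir, paste0(ids[k], ".png")))
        utils::write.csv(
            data.frame(id = ids, class_index = classes,
                       class_label = as.character(cls)),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
        genAUTable(spec, file.path(dir, "au_table.csv"))
        jsonlite::write_json(unclass(spec), file.path(dir, "manifest.json"),
                             auto_unbox = TRUE)
    }
    list(images = images, classes = cls, ids = ids)
}
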
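#' Pain class labels for the four ordinal PSPI groups
#'
#' The 17 possible PSPI scores (0-16) are partitioned into four classes of
#' increasing pain intensity: PSPI = 0, PSPI = 1, 2 <= PSPI <= 3 and
#' PSPI > 3.
#'
#' @return character vector of the four class labels, ordinal order.
#' @export
painClassLabels <- function() {
    c("PSPI=0", "PSPI=1", "2<=PSPI<=3", "PSPI>3")
}

#' Prkachin-Solomon Pain Intensity (PSPI) score from FACS action units
#'
#' Computes \code{AU4 + max(AU6, AU7) + max(AU9, AU10) + AU43} per frame.
#' The pain-related action units are brow-lowering (AU4), cheek-raising
#' (AU6), eyelid tightening (AU7), nose wrinkling (AU9), upper-lip raising
#' (AU10), each coded 0-5, and binary eye-closure (AU43). The score ranges
#' from 0 (no pain) to 16 (strongest pain). All arguments are vectorized.
#'
#' @param au4,au6,au7,au9,au10 integer intensities in 0..5.
#' @param au43 binary eye-closure code, 0 or 1.
#' @return integer PSPI score(s) in 0..16.
#' @examples
#' pspiScore(2, 1, 3, 2, 4, 0)  # 2 + 3 + 4 + 0 = 9
#' @export
pspiScore <- function(au4, au6, au7, au9, au10, au43) {
    au4 <- assertIntensity(au4, "au4", 5L)
    au6 <- assertIntensity(au6, "au6", 5L)
    au7 <- assertIntensity(au7, "au7", 5L)
    au9 <- assertIntensity(au9, "au9", 5L)
    au10 <- assertIntensity(au10, "au10", 5L)
    au43 <- assertIntensity(au43, "au43", 1L)
    n <- length(au4)
    if (any(lengths(list(au6, au7, au9, au10, au43)) != n))
        validationError("all AU vectors must have equal length")
    au4 + pmax(au6, au7) + pmax(au9, au10) + au43
}

#' Map PSPI scores to the four ordinal pain classes
#'
#' @param score integer PSPI score(s) in 0..16.
#' @return factor with the levels of \code{\link{painClassLabels}}.
#' @seealso \code{\link{classIndex}} for the 0-based ordinal codes.
#' @export
pspiGroup <- function(score) {
    if (!is.numeric(score) || anyNA(score) || any(score != round(score)))
        validationError("'score' must be integer-valued with no missing entries")
    if (any(score < 0 | score > 16))
        validationError("'score' out of range: PSPI lies in 0..16")
    idx <- ifelse(score == 0, 0L, ifelse(score == 1, 1L, ifelse(score <= 3, 2L, 3L)))
    factor(painClassLabels()[idx + 1L], levels = painClassLabels())
}

#' 0-based ordinal index of pain classes
#'
#' @param cls factor as returned by \code{\link{pspiGroup}}.
#' @return integer vector in 0..3.
#' @export
classIndex <- function(cls) {
    cls <- as.factor(cls)
    if (!all(levels(cls) %in% painClassLabels()))
        validationError("unknown pain-class labels")
    match(as.character(cls), painClassLabels()) - 1L
}

#' Read a per-frame action-unit intensity table
#'
#' The expected dialect is a CSV with header columns \code{id, au4, au6,
#' au7, au9, au10, au43}. Missing AU columns are an error (never imputed).
#'
#' @param path path to the CSV file.
#' @return data.frame with the seven columns, AU columns integer.
#' @export
readAUTable <- function(path) {
    if (!file.exists(path)) ioError("AU table not found: %s", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "au4", "au6", "au7", "au9", "au10", "au43")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        validationError("AU table %s is missing column(s): %s", path,
                        paste(miss, collapse = ", "))
    tab[need]
}

#' Label frames: PSPI score and pain class per row of an AU table
#'
#' @param au data.frame as returned by \code{\link{readAUTable}}.
#' @return data.frame with columns \code{id, pspi, class_index,
#'   class_label}.
#' @export
labelAUTable <- function(au) {
    pspi <- pspiScore(au$au4, au$au6, au$au7, au$au9, au$au10, au$au43)
    cls <- pspiGroup(pspi)
    data.frame(id = au$id, pspi = pspi, class_index = classIndex(cls),
               class_label = as.character(cls), stringsAsFactors = FALSE)
}

#' Per-class frame frequencies
#'
#' @param labels data.frame from \code{\link{labelAUTable}}, or a factor of
#'   class labels.
#' @return data.frame with columns \code{class_label, count}, one row per
#'   pain class in ordinal order, plus a total row.
#' @export
classFrequency <- function(labels) {
    cls <- if (is.data.frame(labels)) labels$class_label else as.character(labels)
    f <- factor(cls, levels = painClassLabels())
    counts <- as.integer(table(f))
    data.frame(class_label = c(painClassLabels(), "Total"),
               count = c(counts, sum(counts)), stringsAsFactors = FALSE)
}

#' Balance a labeled dataset by seeded per-class under-sampling
#'
#' Classes above their target count are down-sampled uniformly at random
#' without replacement; classes at or below target are kept whole. The
#' result is deterministic given \code{seed}, and retained rows keep their
#' original order.
#'
#' @param labels data.frame with at least \code{id} and \code{class_label}
#'   columns (as from \code{\link{labelAUTable}}).
#' @param targets integer target count per class: either named by class
#'   label or an unnamed vector of length 4 in ordinal class order.
#' @param seed RNG seed for the subsampling.
#' @return the subset data.frame with the same columns as \code{labels}.
#' @export
balanceUndersample <- function(labels, targets, seed) {
    if (!is.data.frame(labels) || !all(c("id", "class_label") %in% names(labels)))
        validationError("'labels' must have columns id and class_label")
    lv <- painClassLabels()
    if (is.null(names(targets))) {
        if (length(targets) != length(lv))
            validationError("unnamed 'targets' must have length %d", length(lv))
        names(targets) <- lv
    }
    if (!all(names(targets) %in% lv))
        validationError("unknown class label(s) in targets: %s",
                        paste(setdiff(names(targets), lv), collapse = ", "))
    cls <- factor(labels$class_label, levels = lv)
    counts <- table(cls)
    keep <- rep(TRUE, nrow(labels))
    withSeed(seed, {
        for (lab in lv) {
            tgt <- if (lab %in% names(targets)) targets[[lab]] else counts[[lab]]
            if (tgt > counts[[lab]])
                validationError(
                    "target %d exceeds available count %d for class '%s'",
                    tgt, counts[[lab]], lab)
            if (tgt < counts[[lab]]) {
                rows <- which(cls == lab)
                keep[rows] <- FALSE
                keep[sample(rows, tgt)] <- TRUE
            }
        }
    })
    labels[keep, , drop = FALSE]
}

#' Write a frame-label table
#'
#' Emits the \code{id, pspi, class_index, class_label} CSV produced by
#' \code{\link{labelAUTable}}.
#'
#' @param labels data.frame of labels.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(labels, path) {
    utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
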
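#' Cross-validation specification
#'
#' @param nFolds number of folds (default 10).
#' @param seed RNG seed for the fold partition.
#' @param stratified stratify folds by class (default TRUE). Stratification
#'   keeps every class present in every training split, which stabilizes
#'   k = 1 behavior; a plain random partition is available for comparison.
#' @return list of class \code{cvSpec}.
#' @export
cvSpec <- function(nFolds = 10L, seed = 1L, stratified = TRUE) {
    nFolds <- assertCount(nFolds, "nFolds", 2L)
    structure(list(nFolds = nFolds, seed = as.integer(seed),
                   stratified = isTRUE(stratified)),
              class = "cvSpec")
}

#' Seeded (stratified) fold assignment
#'
#' Produces a fold id (1..nFolds) per sample. In stratified mode each
#' class's members are spread across folds so per-class fold counts differ
#' by at most one from proportionality, and remainders are placed on the
#' currently smallest folds so overall fold sizes also differ by at most
#' one. Deterministic given the seed.
#'
#' @param y factor of class labels (any vector in non-stratified mode).
#' @param cv a \code{\link{cvSpec}}.
#' @return integer vector of fold ids, same length as \code{y}.
#' @export
makeFolds <- function(y, cv = cvSpec()) {
    n <- length(y)
    k <- cv$nFolds
    if (n < k) validationError("need at least nFolds = %d samples, got %d", k, n)
    fold <- integer(n)
    withSeed(cv$seed, {
        if (cv$stratified) {
            y <- as.factor(y)
            small <- names(which(table(y) < k))
            if (length(small))
                validationError(paste0(
                    "class(es) %s have fewer than nFolds = %d members; ",
                    "use fewer folds or stratified = FALSE"),
                    paste(small, collapse = ", "), k)
            totals <- integer(k)
            for (lab in levels(y)) {
                rows <- sample(which(y == lab))
                nc <- length(rows)
                base <- nc %/% k
                sizes <- rep(base, k)
                r <- nc - base * k
                if (r > 0) {
                    topup <- order(totals, seq_len(k))[seq_len(r)]
                    sizes[topup] <- sizes[topup] + 1L
                }
                fold[rows] <- rep(seq_len(k), times = sizes)
                totals <- totals + sizes
            }
        } else {
            rows <- sample(n)
            sizes <- rep(n %/% k, k)
            r <- n - sum(sizes)
            if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
            fold[rows] <- rep(seq_len(k), times = sizes)
        }
    })
    fold
}

#' k-nearest-neighbor prediction with Manhattan distance
#'
#' The reference classifier of the pipeline: "fine" kNN with k = 1 under
#' the city-block distance \eqn{d(a,b) = \sum_l |a_l - b_l|}. Distance ties
#' at k = 1 are broken by the smallest training-row index (deterministic).
#' For k > 1, unweighted majority vote; vote ties go to the tied class
#' whose member is nearest.
#'
#' @param trainX,trainY training matrix (samples x features) and labels.
#' @param testX test matrix with the same number of columns.
#' @param k neighborhood size (default 1).
#' @return factor of predicted labels with the levels of \code{trainY}.
#' @export
knnPredict <- function(trainX, trainY, testX, k = 1L) {
    trainX <- as.matrix(trainX); testX <- as.matrix(testX)
    if (ncol(trainX) != ncol(testX))
        validationError("train and test feature dimensions differ (%d vs %d)",
                        ncol(trainX), ncol(testX))
    if (nrow(trainX) == 0L) validationError("empty training set")
    k <- assertCount(k, "k", 1L)
    if (k > nrow(trainX))
        validationError("k = %d exceeds the %d training samples", k, nrow(trainX))
    trainY <- as.factor(trainY)
    if (length(trainY) != nrow(trainX))
        validationError("length(trainY) != nrow(trainX)")
    D <- cpp_manhattan_dist(testX, trainX)   # ntest x ntrain
    if (k == 1L) {
        idx <- max.col(-D, ties.method = "first")
        return(trainY[idx])
    }
    pred <- character(nrow(D))
    for (i in seq_len(nrow(D))) {
        ord <- order(D[i, ])                 # stable: ties by train index
        top <- trainY[ord[seq_len(k)]]
        votes <- table(top)
        winners <- names(votes)[votes == max(votes)]
        pred[i] <- as.character(top[match(TRUE, as.character(top) %in% winners)])
    }
    factor(pred, levels = levels(trainY))
}

confusionCounts <- function(true, pred, levels) {
    cm <- table(factor(true, levels = levels), factor(pred, levels = levels))
    m <- matrix(as.integer(cm), nrow = length(levels),
                dimnames = list(true = levels, predicted = levels))
    m
}

#' Cross-validated kNN with a pooled confusion matrix
#'
#' Partitions the data with \code{\link{makeFolds}}, predicts each fold
#' from a model trained on the rest, and pools every test prediction into
#' a single K x K confusion matrix (rows = true class, columns = predicted
#' class), alongside per-fold accuracies. Deterministic given the CV seed.
#'
#' @param X samples-by-features numeric matrix, or a
#'   \linkS4class{PainFeatureSet}.
#' @param y factor of class labels (ignored for a PainFeatureSet).
#' @param cv a \code{\link{cvSpec}}.
#' @param k kNN neighborhood size (default 1).
#' @return list with \code{confusion} (integer matrix), \code{accuracy}
#'   (pooled, 0-1), \code{foldAccuracy}, \code{folds}.
#' @export
crossValidate <- function(X, y = NULL, cv = cvSpec(), k = 1L) {
    if (is(X, "PainFeatureSet")) {
        y <- painClass(X)
        X <- featureMatrix(X)
    }
    X <- as.matrix(X)
    y <- droplevels(as.factor(y))
    if (length(y) != nrow(X)) validationError("length(y) != nrow(X)")
    folds <- makeFolds(y, cv)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    foldAcc <- numeric(cv$nFolds)
    for (f in seq_len(cv$nFolds)) {
        te <- folds == f
        pf <- knnPredict(X[!te, , drop = FALSE], y[!te],
                         X[te, , drop = FALSE], k = k)
        pred[te] <- pf
        foldAcc[f] <- mean(pf == y[te])
    }
    cm <- confusionCounts(y, pred, levels(y))
    list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm),
         foldAccuracy = foldAcc, folds = folds)
}

## Misclassification rate of k=1 Manhattan kNN under a fixed fold partition
## (shared loss function of the INCA candidate loop).
cvLoss <- function(X, y, folds, k = 1L) {
    wrong <- 0L
    for (f in sort(unique(folds))) {
        te <- folds == f
        pf <- knnPredict(X[!te, , drop = FALSE], y[!te],
                         X[te, , drop = FALSE], k = k)
        wrong <- wrong + sum(pf != y[te])
    }
    wrong / length(y)
}

#' Write / read a labeled confusion matrix CSV
#'
#' Layout mirrors the standard presentation: first column the true-class
#' label, remaining columns the predicted-class counts.
#'
#' @param cm K x K integer matrix with dimnames.
#' @param path CSV path.
#' @return \code{path} (write) or the matrix (read).
#' @export
writeConfusion <- function(cm, path) {
    df <- data.frame(true = rownames(cm), cm, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeConfusion
#' @export
readConfusion <- function(path) {
    if (!file.exists(path)) ioError("confusion CSV not found: %s", path)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    dimnames(m) <- list(true = df[[1]], predicted = colnames(df)[-1])
    m
}
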
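# Published pooled ten-fold confusion matrices of the strip-based pain
# classifier on the two benchmark datasets (UNBC-McMaster shoulder pain;
# DISFA), rows = true class, columns = predicted class. All metric-layer
# expectations derive from these counts.
benchmarkConfusion <- function(which = c("shoulder", "disfa")) {
    which <- match.arg(which)
    lv <- painClassLabels()
    counts <- switch(which,
        shoulder = c(2342, 67, 59, 15,
                     11, 2798, 99, 1,
                     9, 94, 3598, 62,
                     8, 4, 52, 1633),
        disfa = c(8528, 405, 80, 12,
                  132, 9606, 227, 8,
                  19, 338, 9765, 187,
                  4, 11, 121, 9739))
    matrix(as.integer(counts), 4, 4, byrow = TRUE,
           dimnames = list(true = lv, predicted = lv))
}

# Round half away from zero to 2 decimals, the presentation convention.
r2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

# Independent 1-NN oracle: exhaustive pairwise Manhattan distances in plain
# R, ties broken by smallest training index.
bruteNN1 <- function(trainX, trainY, testX) {
    pred <- trainY[rep(1L, nrow(testX))]
    for (i in seq_len(nrow(testX))) {
        d <- apply(trainX, 1L, function(r) sum(abs(r - testX[i, ])))
        pred[i] <- trainY[which.min(d)]
    }
    pred
}

# Classical binary Matthews correlation from a 2x2 confusion matrix.
binaryMCC <- function(cm) {
    storage.mode(cm) <- "double"
    tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    (tp * tn - fp * fn) / sqrt(den)
}

randomFace <- function(seed, side = 224L) {
    withr::with_seed(seed, array(runif(side * side * 3, 0, 255),
                                 c(side, side, 3L)))
}
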
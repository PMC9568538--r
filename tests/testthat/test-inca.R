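test_that("min-max normalization has the stated closed form and conventions", {
    X <- cbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 1, 0.5))
    fit <- minmaxNormalize(X)
    expect_equal(unname(fit$X[, "a"]), c(0, 0.5, 1))
    expect_equal(unname(fit$X[, "b"]), c(0, 0, 0))     # constant column
    expect_equal(unname(fit$X[, "c"]), c(0, 1, 0.5))
    # idempotence when every column already spans [0, 1]
    again <- minmaxNormalize(fit$X[, c("a", "c")])
    expect_equal(again$X, fit$X[, c("a", "c")])
    # fitted transform re-applies to new data
    expect_equal(unname(applyMinmax(fit, X)[, "a"]), c(0, 0.5, 1))
    expect_error(minmaxNormalize(matrix(numeric(0), 0, 0)),
                 class = "painstrips_validation_error")
    expect_error(minmaxNormalize(matrix(c(1, NA), 1)),
                 class = "painstrips_validation_error")
})

test_that("NCA objective gradient matches finite differences", {
    withr::with_seed(42, {
        X <- matrix(runif(20 * 6), 20)
        y <- rep(1:2, 10)
        w <- runif(6, 0.5, 1.5)
    })
    og <- painstrips:::cpp_nca_objgrad(X, as.integer(y), w, 1, 0.05)
    num <- vapply(1:6, function(l) {
        e <- rep(0, 6); e[l] <- 1e-6
        (painstrips:::cpp_nca_objgrad(X, as.integer(y), w + e, 1, 0.05)$objective -
         painstrips:::cpp_nca_objgrad(X, as.integer(y), w - e, 1, 0.05)$objective) / 2e-6
    }, numeric(1))
    expect_equal(og$gradient, num, tolerance = 1e-6)
})

test_that("duplicate feature columns earn equal NCA weights", {
    withr::with_seed(1, {
        X <- matrix(rnorm(60 * 4), 60)
        y <- rep(c("a", "b"), 30)
        X[, 1] <- X[, 1] + ifelse(y == "a", 1, -1)
    })
    X <- cbind(X, X[, 1])                      # clone the informative column
    Xn <- minmaxNormalize(X)$X
    rk <- ncaRank(Xn, y, iterations = 50)
    w <- featureWeights(rk)
    expect_lt(abs(w[1] - w[5]), 1e-6)
})

test_that("permuting feature columns permutes NCA weights identically", {
    withr::with_seed(2, {
        X <- matrix(rnorm(40 * 6), 40)
        y <- rep(0:1, each = 20)
        X[, 3] <- X[, 3] + y
    })
    Xn <- minmaxNormalize(X)$X
    perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
    w1 <- featureWeights(ncaRank(Xn, y, iterations = 40))
    w2 <- featureWeights(ncaRank(Xn[, perm], y, iterations = 40))
    expect_equal(w2, w1[perm], tolerance = 1e-8)
})

test_that("NCA ranks a planted informative pair on top", {
    withr::with_seed(1001, {
        n <- 200
        y <- rep(0:1, each = n / 2)
        X <- matrix(rnorm(n * 20), n)
        X[, 1] <- X[, 1] + ifelse(y == 0, -1.5, 1.5)
        X[, 2] <- X[, 2] + ifelse(y == 0, 1.5, -1.5)
    })
    rk <- ncaRank(minmaxNormalize(X)$X, y, iterations = 100)
    expect_setequal(featureRanking(rk)[1:2], c(1L, 2L))
    expect_error(ncaRank(minmaxNormalize(X)$X, rep(1, 200)),
                 class = "painstrips_validation_error")  # single class
})

test_that("ranking is a permutation ordered by squared weight, ties by index", {
    withr::with_seed(3, {
        X <- matrix(rnorm(30 * 8), 30)
        y <- rep(1:3, each = 10)
    })
    rk <- ncaRank(minmaxNormalize(X)$X, y, iterations = 20)
    ord <- featureRanking(rk)
    expect_identical(sort(ord), 1:8)
    sc <- featureWeights(rk)[ord]^2
    expect_true(all(diff(sc) <= 1e-15))
})

test_that("incaSelect agrees with a brute-force evaluation of every candidate", {
    withr::with_seed(17, {
        n <- 60
        y <- factor(rep(c("a", "b"), each = n / 2))
        X <- matrix(rnorm(n * 20), n)
        X[, 5] <- X[, 5] + ifelse(y == "a", 2, -2)
        X[, 9] <- X[, 9] + ifelse(y == "a", -2, 2)
    })
    Xn <- minmaxNormalize(X)$X
    rk <- ncaRank(Xn, y, iterations = 50)
    cv <- cvSpec(5L, seed = 31L)
    sel <- incaSelect(Xn, y, rk, lo = 2L, hi = 10L, cv = cv)

    # independent oracle: same frozen folds, brute-force 1-NN per candidate
    folds <- makeFolds(y, cv)
    ord <- featureRanking(rk)
    oracleLoss <- vapply(2:10, function(l) {
        wrong <- 0L
        for (f in 1:5) {
            te <- folds == f
            pred <- bruteNN1(Xn[!te, ord[1:l], drop = FALSE], y[!te],
                             Xn[te, ord[1:l], drop = FALSE])
            wrong <- wrong + sum(pred != y[te])
        }
        wrong / length(y)
    }, numeric(1))
    expect_equal(lossCurve(sel)$loss, oracleLoss)
    expect_identical(bestLength(sel), (2:10)[which.min(oracleLoss)])
    # selected subset is the ranking prefix and self-consistent
    expect_identical(selectedFeatures(sel), ord[seq_len(bestLength(sel))])
    expect_equal(min(lossCurve(sel)$loss),
                 painstrips:::cvLoss(Xn[, selectedFeatures(sel), drop = FALSE],
                                     y, folds))
})

test_that("ties in the loss curve resolve to the smallest length", {
    withr::with_seed(4, {
        X0 <- matrix(rnorm(40), 40, 1)
        y <- rep(c("a", "b"), 20)
    })
    X <- X0[, rep(1, 6)]                       # identical columns: equal losses
    Xn <- minmaxNormalize(X)$X
    rk <- ncaRank(Xn, y, iterations = 10)
    sel <- incaSelect(Xn, y, rk, lo = 2L, hi = 6L, cv = cvSpec(5L, 1L))
    expect_identical(length(unique(lossCurve(sel)$loss)), 1L)
    expect_identical(bestLength(sel), 2L)
})

test_that("the default range over a wide matrix evaluates 901 candidate lengths", {
    withr::with_seed(5, {
        n <- 40
        y <- factor(rep(painClassLabels(), each = 10))
        X <- matrix(rnorm(n * 1100), n)
        X[, 1] <- X[, 1] + as.integer(y)
    })
    Xn <- minmaxNormalize(X)$X
    rk <- ncaRank(Xn, y, iterations = 3)
    sel <- incaSelect(Xn, y, rk, lo = 100L, hi = 1000L, cv = cvSpec(10L, 2L))
    expect_identical(length(lossCurve(sel)$length), 901L)
    expect_identical(range(lossCurve(sel)$length), c(100L, 1000L))
    # range clipped to D when the matrix is narrower
    sel5 <- incaSelect(Xn[, 1:5], y,
                       ncaRank(Xn[, 1:5], y, iterations = 2),
                       lo = 10L, hi = 20L, cv = cvSpec(10L, 2L))
    expect_identical(lossCurve(sel5)$length, 5L)
    expect_error(incaSelect(Xn, y, rk, lo = 300L, hi = 200L,
                            cv = cvSpec(10L, 2L)),
                 class = "painstrips_validation_error")
})

test_that("no-leakage selection runs per-fold refits and reports honest losses", {
    withr::with_seed(6, {
        n <- 60
        y <- factor(rep(c("a", "b"), each = n / 2))
        X <- matrix(rnorm(n * 10), n)
        X[, 2] <- X[, 2] + ifelse(y == "a", 2.5, -2.5)
    })
    sel <- incaSelectStrict(X, y, lo = 1L, hi = 5L, cv = cvSpec(5L, 9L),
                            iterations = 20)
    expect_s4_class(sel, "SelectionResult")
    expect_identical(sel@mode, "no-leakage")
    expect_length(selectedFeatures(sel), bestLength(sel))
    expect_true(all(lossCurve(sel)$loss >= 0 & lossCurve(sel)$loss <= 1))
})

test_that("selection results persist through JSON", {
    withr::with_seed(7, {
        X <- matrix(rnorm(40 * 8), 40)
        y <- rep(c("a", "b"), 20)
    })
    Xn <- minmaxNormalize(X)$X
    sel <- incaSelect(Xn, y, ncaRank(Xn, y, iterations = 10),
                      lo = 2L, hi = 6L, cv = cvSpec(5L, 3L))
    tmp <- withr::local_tempfile(fileext = ".json")
    writeSelection(sel, tmp)
    back <- readSelection(tmp)
    expect_identical(back@lengths, sel@lengths)
    expect_equal(back@losses, sel@losses)
    expect_identical(back@bestLength, sel@bestLength)
    expect_identical(back@selected, sel@selected)
})
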
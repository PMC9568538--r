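#' Min-max normalization per feature
#'
#' Maps each column to \code{(x - min) / (max - min)}; constant columns map
#' to 0. The fitted per-feature minima and maxima are returned so the same
#' transform can be re-applied to held-out data (see
#' \code{\link{applyMinmax}}).
#'
#' @param X numeric matrix (samples x features), no missing values.
#' @return list with \code{X} (normalized matrix), \code{min}, \code{max}.
#' @export
minmaxNormalize <- function(X) {
    X <- as.matrix(X)
    if (nrow(X) == 0L || ncol(X) == 0L) validationError("empty feature matrix")
    if (anyNA(X) || !all(is.finite(X)))
        validationError("feature matrix contains missing or non-finite values")
    mins <- apply(X, 2L, min)
    maxs <- apply(X, 2L, max)
    list(X = applyMinmax(list(min = mins, max = maxs), X),
         min = mins, max = maxs)
}

#' @rdname minmaxNormalize
#' @param fit list with \code{min} and \code{max} from a previous
#'   \code{minmaxNormalize} call.
#' @export
applyMinmax <- function(fit, X) {
    X <- as.matrix(X)
    rng <- fit$max - fit$min
    out <- sweep(X, 2L, fit$min, "-")
    out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/")
    out[, rng == 0] <- 0
    out
}

#' Rank features by neighborhood component analysis
#'
#' Feature-selection NCA: learns one nonnegative relevance weight per
#' feature by maximizing the regularized expected leave-one-out
#' correct-classification probability. Sample j picks reference i with
#' probability proportional to \eqn{\exp(-d_w(x_j, x_i)/\sigma)} where
#' \eqn{d_w(a,b) = \sum_l w_l^2 |a_l - b_l|} is the weighted city-block
#' distance (matching the downstream Manhattan kNN), and the objective is
#' the summed probability of picking a same-class reference minus
#' \eqn{\lambda \sum_l w_l^2}. Optimization is full-batch gradient ascent
#' from w = 1 for a fixed iteration budget, with the step halved and
#' rejected whenever the objective decreases. The ranking orders features
#' by squared weight descending, ties broken by ascending feature index.
#' The procedure is deterministic; \code{seed} is recorded for provenance.
#'
#' @param X normalized samples-by-features matrix.
#' @param y factor of class labels (>= 2 classes).
#' @param sigma kernel width of the soft-neighbor distance (default 1).
#' @param lambda ridge penalty on squared weights (default \code{1/N}).
#' @param iterations gradient steps (default 100).
#' @param learnRate initial step size (default 0.1).
#' @param seed recorded in the hyperparameter list.
#' @return an \linkS4class{NCARanking}.
#' @export
ncaRank <- function(X, y, sigma = 1, lambda = NULL, iterations = 100L,
                    learnRate = 0.1, seed = 1L) {
    X <- as.matrix(X)
    if (anyNA(X) || !all(is.finite(X)))
        validationError("feature matrix contains missing or non-finite values")
    y <- droplevels(as.factor(y))
    if (nlevels(y) < 2L) validationError("need at least 2 classes for NCA")
    if (length(y) != nrow(X)) validationError("length(y) != nrow(X)")
    iterations <- assertCount(iterations, "iterations", 1L)
    n <- nrow(X); d <- ncol(X)
    if (is.null(lambda)) lambda <- 1 / n
    yInt <- as.integer(y)

    w <- rep(1, d)
    lr <- learnRate
    og <- cpp_nca_objgrad(X, yInt, w, sigma, lambda)
    trace <- numeric(iterations)
    for (it in seq_len(iterations)) {
        wNew <- w + lr * og$gradient
        ogNew <- cpp_nca_objgrad(X, yInt, wNew, sigma, lambda)
        if (ogNew$objective >= og$objective) {
            w <- wNew
            og <- ogNew
        } else {
            lr <- lr / 2
        }
        trace[it] <- og$objective
    }
    score <- w^2
    ord <- order(-score, seq_len(d))
    new("NCARanking", weights = w, ranking = as.integer(ord),
        hyper = list(sigma = sigma, lambda = lambda,
                     iterations = iterations, learnRate = learnRate,
                     seed = as.integer(seed), objective = trace))
}

#' Iterative NCA (INCA): choose the best-performing ranked-feature prefix
#'
#' Evaluates every candidate prefix length l in \code{[lo, hi]} (step
#' \code{step}; the range is clipped to the number of features): the first
#' l features of the NCA ranking are scored by the misclassification rate
#' of k = 1 Manhattan kNN under one fixed stratified cross-validation
#' partition, shared across all candidates so losses are comparable. The
#' prefix with minimum loss wins; ties go to the smallest length. With the
#' default range [100, 1000] and step 1, 901 candidate lengths are
#' evaluated.
#'
#' @param X normalized samples-by-features matrix.
#' @param y factor of class labels.
#' @param ranking an \linkS4class{NCARanking} for the columns of \code{X}.
#' @param lo,hi candidate prefix-length range (defaults 100 and 1000).
#' @param cv a \code{\link{cvSpec}} defining the shared loss partition.
#' @param step length increment between candidates (default 1).
#' @param k kNN neighborhood size of the loss function (default 1).
#' @return a \linkS4class{SelectionResult} with mode \code{"faithful"}.
#' @export
incaSelect <- function(X, y, ranking, lo = 100L, hi = 1000L, cv = cvSpec(),
                       step = 1L, k = 1L) {
    X <- as.matrix(X)
    y <- droplevels(as.factor(y))
    if (!is(ranking, "NCARanking")) validationError("'ranking' must be an NCARanking")
    if (length(ranking@ranking) != ncol(X))
        validationError("ranking covers %d features but X has %d columns",
                        length(ranking@ranking), ncol(X))
    lo <- assertCount(lo, "lo", 1L)
    hi <- assertCount(hi, "hi", 1L)
    step <- assertCount(step, "step", 1L)
    d <- ncol(X)
    lo2 <- min(lo, d); hi2 <- min(hi, d)
    if (lo2 > hi2) validationError("empty candidate range [%d, %d]", lo2, hi2)
    lengths <- seq.int(lo2, hi2, by = step)
    folds <- makeFolds(y, cv)
    losses <- vapply(lengths, function(l) {
        cols <- ranking@ranking[seq_len(l)]
        cvLoss(X[, cols, drop = FALSE], y, folds, k = k)
    }, numeric(1))
    best <- lengths[which.min(losses)]
    new("SelectionResult",
        lengths = as.integer(lengths), losses = losses,
        bestLength = as.integer(best),
        selected = ranking@ranking[seq_len(best)],
        seed = as.integer(cv$seed), mode = "faithful")
}

#' INCA with per-fold refitting (no-leakage mode)
#'
#' The faithful pipeline normalizes and ranks once on the full matrix
#' before cross-validation, so the selection loss is optimistically biased.
#' This strict variant refits the min-max transform and the NCA ranking
#' inside each training fold and scores each candidate length on the held
#' out fold, giving an honest generalization estimate of the loss curve.
#' The final selected prefix is taken from a full-data ranking at the best
#' length so downstream stages receive one concrete feature set.
#'
#' @param Xraw unnormalized samples-by-features matrix.
#' @param y factor of class labels.
#' @param lo,hi,cv,step,k as in \code{\link{incaSelect}}.
#' @param ... further arguments passed to \code{\link{ncaRank}}.
#' @return a \linkS4class{SelectionResult} with mode \code{"no-leakage"}.
#' @export
incaSelectStrict <- function(Xraw, y, lo = 100L, hi = 1000L, cv = cvSpec(),
                             step = 1L, k = 1L, ...) {
    Xraw <- as.matrix(Xraw)
    y <- droplevels(as.factor(y))
    d <- ncol(Xraw)
    lo2 <- min(lo, d); hi2 <- min(hi, d)
    if (lo2 > hi2) validationError("empty candidate range [%d, %d]", lo2, hi2)
    lengths <- seq.int(lo2, hi2, by = step)
    folds <- makeFolds(y, cv)
    wrong <- numeric(length(lengths))
    for (f in sort(unique(folds))) {
        te <- folds == f
        fit <- minmaxNormalize(Xraw[!te, , drop = FALSE])
        Xtr <- fit$X
        Xte <- applyMinmax(fit, Xraw[te, , drop = FALSE])
        rk <- ncaRank(Xtr, y[!te], ...)
        for (j in seq_along(lengths)) {
            cols <- rk@ranking[seq_len(lengths[j])]
            pf <- knnPredict(Xtr[, cols, drop = FALSE], y[!te],
                             Xte[, cols, drop = FALSE], k = k)
            wrong[j] <- wrong[j] + sum(pf != y[te])
        }
    }
    losses <- wrong / length(y)
    best <- lengths[which.min(losses)]
    full <- ncaRank(minmaxNormalize(Xraw)$X, y, ...)
    new("SelectionResult",
        lengths = as.integer(lengths), losses = losses,
        bestLength = as.integer(best),
        selected = full@ranking[seq_len(best)],
        seed = as.integer(cv$seed), mode = "no-leakage")
}

#' Persist / load a SelectionResult as JSON
#'
#' @param sel a \linkS4class{SelectionResult}.
#' @param path JSON path.
#' @return \code{path} (write) or a \code{SelectionResult} (read).
#' @export
writeSelection <- function(sel, path) {
    obj <- list(lengths = sel@lengths, losses = sel@losses,
                best_length = sel@bestLength, selected_indexes = sel@selected,
                seed = sel@seed, mode = sel@mode)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeSelection
#' @export
readSelection <- function(path) {
    if (!file.exists(path)) ioError("selection JSON not found: %s", path)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("SelectionResult",
        lengths = as.integer(obj$lengths), losses = as.numeric(obj$losses),
        bestLength = as.integer(obj$best_length),
        selected = as.integer(obj$selected_indexes),
        seed = as.integer(obj$seed), mode = obj$mode)
}
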
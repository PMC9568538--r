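assertConfusion <- function(cm) {
    cm <- as.matrix(cm)
    if (nrow(cm) != ncol(cm)) validationError("confusion matrix must be square")
    if (anyNA(cm) || any(cm < 0) || any(cm != round(cm)))
        validationError("confusion counts must be nonnegative integers")
    if (any(rowSums(cm) == 0))
        validationError("every true class must have at least one sample (empty row)")
    storage.mode(cm) <- "double"   # count products can exceed integer range
    cm
}

#' Class-wise recall, precision and F1 from a confusion matrix
#'
#' Rows are true classes, columns predicted classes. \code{recall_k =
#' cm[k,k]/rowsum_k}, \code{precision_k = cm[k,k]/colsum_k} (0 when the
#' column sum is 0), \code{F1_k = 2PR/(P+R)} (0 when P + R = 0). Values
#' are percentages at full precision; round only for presentation.
#'
#' @param cm K x K count matrix.
#' @return data.frame with columns \code{class, recall, precision, f1}.
#' @export
classwiseMetrics <- function(cm) {
    cm <- assertConfusion(cm)
    diagc <- diag(cm)
    recall <- diagc / rowSums(cm)
    colsum <- colSums(cm)
    precision <- ifelse(colsum > 0, diagc / colsum, 0)
    pr <- precision + recall
    f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
    data.frame(
        class = if (!is.null(rownames(cm))) rownames(cm) else
            sprintf("C%d", seq_len(nrow(cm)) - 1L),
        recall = 100 * recall, precision = 100 * precision, f1 = 100 * f1,
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall multiclass metrics from a confusion matrix
#'
#' Computes, as percentages at full precision:
#' \itemize{
#'   \item accuracy = trace/N;
#'   \item UAR / UAP: unweighted (macro) averages of class recalls /
#'     precisions;
#'   \item macro-F1: mean of class-wise F1;
#'   \item Cohen's kappa \eqn{(p_o - p_e)/(1 - p_e)} with
#'     \eqn{p_e = \sum_k rowsum_k \cdot colsum_k / N^2};
#'   \item MCC: the macro-averaged one-vs-rest binary Matthews correlation
#'     (mean over classes of the 2x2 MCC of class k against the rest);
#'   \item mccRk: Gorodkin's multiclass \eqn{R_K},
#'     \eqn{(cN - \sum_k p_k t_k)/\sqrt{(N^2-\sum p_k^2)(N^2-\sum t_k^2)}}
#'     with c = trace, t = row sums, p = column sums, reported alongside
#'     as the single-statistic generalization;
#'   \item GM: geometric mean of class-wise recalls.
#' }
#' Both MCC variants coincide with the classical binary MCC at K = 2.
#'
#' @param cm K x K count matrix (K >= 2).
#' @return named list: \code{accuracy, uar, uap, macroF1, mcc, kappa, gm,
#'   mccRk}.
#' @export
overallMetrics <- function(cm) {
    cm <- assertConfusion(cm)
    if (nrow(cm) < 2L)
        validationError("overall metrics are undefined for a single class")
    n <- sum(cm)
    cw <- classwiseMetrics(cm)
    tk <- rowSums(cm); pk <- colSums(cm)
    tr <- sum(diag(cm))
    po <- tr / n
    pe <- sum(tk * pk) / n^2
    if (pe >= 1)
        validationError("kappa undefined: degenerate marginal distribution")
    kappa <- (po - pe) / (1 - pe)
    den <- (n^2 - sum(pk^2)) * (n^2 - sum(tk^2))
    if (den <= 0)
        validationError("MCC undefined: degenerate marginal distribution")
    mccRk <- (tr * n - sum(pk * tk)) / sqrt(den)
    mccOvr <- mean(vapply(seq_len(nrow(cm)), function(k) {
        tp <- cm[k, k]; fp <- pk[k] - tp; fn <- tk[k] - tp
        tn <- n - tp - fp - fn
        d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
        if (d <= 0) validationError(
            "MCC undefined for class %d: degenerate 2x2 margin", k)
        (tp * tn - fp * fn) / sqrt(d)
    }, numeric(1)))
    recalls <- cw$recall / 100
    list(accuracy = 100 * po,
         uar = mean(cw$recall),
         uap = mean(cw$precision),
         macroF1 = mean(cw$f1),
         mcc = 100 * mccOvr,
         kappa = 100 * kappa,
         gm = 100 * prod(recalls)^(1 / length(recalls)),
         mccRk = 100 * mccRk)
}

#' Human-readable metric report
#'
#' Formats the class-wise table plus the overall metric row with
#' percentages rounded half-up to 2 decimals (presentation only; computed
#' values keep full precision).
#'
#' @param cm K x K confusion matrix.
#' @return character vector of report lines (also printed invisibly by
#'   \code{cat} when assigned).
#' @export
metricReportTable <- function(cm) {
    cw <- classwiseMetrics(cm)
    ov <- overallMetrics(cm)
    fmt <- function(x) sprintf("%.2f", roundHalfUp(x))
    lines <- c(
        sprintf("%-12s %8s %10s %8s", "class", "recall", "precision", "F1"),
        sprintf("%-12s %8s %10s %8s", cw$class, fmt(cw$recall),
                fmt(cw$precision), fmt(cw$f1)),
        "",
        paste("overall: ",
              sprintf("Acc %s  UAR %s  UAP %s  F1 %s  MCC %s  CK %s  GM %s",
                      fmt(ov$accuracy), fmt(ov$uar), fmt(ov$uap),
                      fmt(ov$macroF1), fmt(ov$mcc), fmt(ov$kappa),
                      fmt(ov$gm))))
    lines
}

#' Write a metric report (overall + class-wise) as JSON
#'
#' @param cm K x K confusion matrix.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
writeMetricReport <- function(cm, path) {
    obj <- list(overall = overallMetrics(cm),
                classwise = classwiseMetrics(cm))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                         dataframe = "columns")
    invisible(path)
}
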
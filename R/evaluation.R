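## Dataset splitting, confusion-matrix metrics and ROC analysis.
## Viable is the positive class throughout.

.asCode <- function(labels) {
    if (is.numeric(labels)) {
        stopifnot(all(labels %in% c(0, 1)))
        as.integer(labels)
    } else {
        code <- classCode(labels)
        if (anyNA(code)) stop("labels contain 'unknown'/unlabelled samples")
        as.integer(code)
    }
}

#' Stratified calibration/validation split
#'
#' Randomly partitions the samples per class at a fixed seed, either by a
#' validation fraction or by explicit per-class validation counts.
#' Calibration and validation are disjoint by construction.
#'
#' @param set a [SpectraSet-class] with viable/nonviable labels.
#' @param validationFraction fraction of each class assigned to validation
#'   (rounded per class); ignored when `validationCounts` is given.
#' @param validationCounts per-class validation size: a single number used
#'   for both classes, or a named vector `c(viable = , nonviable = )`.
#' @param seed integer seed for the random partition.
#' @return list with elements `calibration` and `validation`
#'   ([SpectraSet-class]s) and `seed`.
#' @export
stratifiedSplit <- function(set, validationFraction = NULL,
                            validationCounts = NULL, seed = 1) {
    lab <- viabilityLabel(set)
    if (any(lab == "unknown"))
        stop("cannot split unlabelled ('unknown') samples")
    if (is.null(validationFraction) && is.null(validationCounts))
        stop("give validationFraction or validationCounts")
    classes <- c("viable", "nonviable")
    valIdx <- integer(0)
    idxByClass <- split(seq_along(lab), factor(lab, levels = classes))
    counts <- vapply(classes, function(cl) {
        n <- length(idxByClass[[cl]])
        k <- if (!is.null(validationCounts)) {
            vc <- validationCounts
            if (!is.null(names(vc))) vc <- vc[[cl]]
            as.integer(vc)
        } else as.integer(round(validationFraction * n))
        if (k > n)
            stop(sprintf("requested %d validation samples for class '%s' but only %d exist",
                         k, cl, n))
        k
    }, integer(1))
    valIdx <- .withSeed(seed, unlist(lapply(classes, function(cl)
        sample(idxByClass[[cl]], counts[[cl]]))))
    list(calibration = set[, setdiff(seq_along(lab), valIdx)],
         validation = set[, sort(valIdx)],
         seed = as.integer(seed))
}

.metricsFromCounts <- function(tp, fn, fp, tn) {
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    ner <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
    c(sensitivity = sens, specificity = spec, ner = ner, er = 1 - ner,
      prec = ratio(tp, tp + fp), fpr = ratio(fp, fp + tn),
      accuracy = ratio(tp + tn, tp + fn + fp + tn))
}

#' Confusion-matrix classification metrics
#'
#' With viable as the positive class: sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, non-error rate `NER = (sensitivity + specificity)/2`,
#' error rate `ER = 1 - NER`, precision `PREC = tp/(tp+fp)`, false positive
#' rate `FPR = fp/(fp+tn)`, and overall accuracy `(tp+tn)/n`. A metric with
#' zero denominator is `NA`.
#'
#' @param tp,fn,fp,tn confusion counts.
#' @return named numeric vector of the metrics.
#' @examples
#' classificationMetrics(tp = 43, fn = 6, fp = 9, tn = 42)
#' @export
classificationMetrics <- function(tp, fn, fp, tn) {
    stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
    .metricsFromCounts(tp, fn, fp, tn)
}

#' Confusion matrix and evaluation report
#'
#' Builds the viable-positive confusion matrix from true and predicted
#' labels (0/1 codes or label strings) and, when the continuous responses
#' `yhat` are supplied, adds the ROC sweep, its trapezoidal AUC and the
#' sensitivity/specificity crossing threshold.
#'
#' @param truth true labels (0/1 or `"viable"`/`"nonviable"`).
#' @param predicted predicted labels; defaults to thresholding `yhat` at
#'   `threshold` when omitted.
#' @param yhat optional continuous responses for ROC analysis.
#' @param threshold decision threshold for `yhat` (default 0.5).
#' @return an [EvalReport-class].
#' @export
evaluateClassification <- function(truth, predicted = NULL, yhat = NULL,
                                   threshold = 0.5) {
    truth <- .asCode(truth)
    if (is.null(predicted)) {
        if (is.null(yhat)) stop("give predicted labels or yhat")
        predicted <- as.integer(yhat >= threshold)
    } else predicted <- .asCode(predicted)
    stopifnot(length(truth) == length(predicted))
    if (length(truth) == 0) stop("empty evaluation set")
    tp <- sum(truth == 1 & predicted == 1)
    fn <- sum(truth == 1 & predicted == 0)
    fp <- sum(truth == 0 & predicted == 1)
    tn <- sum(truth == 0 & predicted == 0)
    roc <- if (!is.null(yhat)) rocCurve(yhat, truth) else
        list(points = data.frame(threshold = numeric(),
                                 sensitivity = numeric(),
                                 specificity = numeric(), fpr = numeric()),
             auc = NA_real_, crossingThreshold = NA_real_)
    new("EvalReport", tp = tp, fn = fn, fp = fp, tn = tn,
        metrics = .metricsFromCounts(tp, fn, fp, tn),
        rocPoints = roc$points, auc = roc$auc,
        crossingThreshold = roc$crossingThreshold, threshold = threshold)
}

#' ROC curve, AUC and sensitivity/specificity crossing
#'
#' Sweeps the decision threshold over the sorted unique responses (plus
#' sentinels); at each threshold, `yhat >= threshold` is classified viable.
#' AUC is the trapezoidal area over (FPR, sensitivity). The crossing
#' threshold is where sensitivity equals specificity, linearly interpolated
#' between adjacent sweep points.
#'
#' @param yhat continuous responses.
#' @param truth true labels (0/1 or label strings); both classes required.
#' @return list with `points` (data.frame: threshold, sensitivity,
#'   specificity, fpr), `auc`, and `crossingThreshold`.
#' @export
rocCurve <- function(yhat, truth) {
    truth <- .asCode(truth)
    stopifnot(length(yhat) == length(truth))
    nPos <- sum(truth == 1); nNeg <- sum(truth == 0)
    if (nPos == 0 || nNeg == 0)
        stop("ROC requires both classes present")
    thr <- c(-Inf, sort(unique(yhat)), Inf)
    sens <- spec <- numeric(length(thr))
    for (i in seq_along(thr)) {
        pred <- yhat >= thr[i]
        sens[i] <- sum(pred & truth == 1) / nPos
        spec[i] <- sum(!pred & truth == 0) / nNeg
    }
    pts <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec, fpr = 1 - spec)
    ord <- order(pts$fpr, pts$sensitivity)
    x <- pts$fpr[ord]; yv <- pts$sensitivity[ord]
    auc <- sum(diff(x) * (head(yv, -1) + tail(yv, -1)) / 2)
    d <- sens - spec   # decreasing in threshold
    k <- which(head(d, -1) >= 0 & tail(d, -1) <= 0)
    crossing <- if (length(k)) {
        k <- k[1]
        t1 <- thr[k]; t2 <- thr[k + 1]
        if (!is.finite(t1)) t1 <- t2
        if (!is.finite(t2)) t2 <- t1
        if (d[k] == d[k + 1]) (t1 + t2) / 2
        else t1 + (t2 - t1) * d[k] / (d[k] - d[k + 1])
    } else thr[which.min(abs(d))]
    list(points = pts, auc = auc, crossingThreshold = crossing)
}

#' @describeIn evaluateClassification metrics accessor.
#' @param report an `EvalReport`.
#' @export
reportMetrics <- function(report) report@metrics

#' @describeIn evaluateClassification confusion counts accessor
#'   (`tp`, `fn`, `fp`, `tn`).
#' @export
confusionCounts <- function(report)
    c(tp = report@tp, fn = report@fn, fp = report@fp, tn = report@tn)

setMethod("show", "EvalReport", function(object) {
    cat("EvalReport (viable = positive class)\n")
    m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
                byrow = TRUE,
                dimnames = list(truth = c("viable", "nonviable"),
                                predicted = c("viable", "nonviable")))
    print(m)
    mt <- object@metrics
    fmt <- function(v, digits) ifelse(is.na(v), "NA", formatC(v, digits = digits,
                                                              format = "f"))
    cat(sprintf("  sensitivity %s  specificity %s  NER %s  ER %s  PREC %s  FPR %s\n",
                fmt(mt["sensitivity"], 3), fmt(mt["specificity"], 2),
                fmt(mt["ner"], 2), fmt(mt["er"], 2),
                fmt(mt["prec"], 2), fmt(mt["fpr"], 2)))
    if (!is.na(object@auc))
        cat(sprintf("  AUC %.3f, sensitivity/specificity crossing at %.3f\n",
                    object@auc, object@crossingThreshold))
    invisible(object)
})
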
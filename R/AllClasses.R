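#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef cor lm mad median pf pnorm qchisq qf qnorm quantile
#'   rbinom rnorm runif sd var predict
#' @importFrom utils read.csv write.csv head tail
NULL

.VALID_LABELS <- c("nonviable", "viable", "unknown")

#' SpectraSet: labelled FT-NIR spectra
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' set of absorbance spectra on a common, strictly increasing, uniformly
#' spaced wavenumber grid, together with per-seed metadata: a unique sample
#' id, the seed variety, and the viability label established by a germination
#' test (`"viable"`, `"nonviable"`, or `"unknown"` for prediction-only data).
#'
#' Internally the assay named `"absorbance"` stores wavenumbers in rows and
#' samples in columns, following the SummarizedExperiment convention that
#' rows are features. User-facing accessors present the chemometric
#' orientation: [absorbance()] returns a samples x wavenumbers matrix.
#'
#' @slot wavenumbers numeric vector of wavenumbers in cm^-1 (also available
#'   via the accessor; kept in `rowData` as the column `wavenumber`).
#'
#' @seealso [SpectraSet()] for construction, [simulateSpectra()],
#'   [readSpectra()].
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
    msg <- character()
    if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'absorbance' is missing")
    wn <- SummarizedExperiment::rowData(object)$wavenumber
    if (is.null(wn)) {
        msg <- c(msg, "rowData column 'wavenumber' is missing")
    } else if (length(wn) > 1L) {
        d <- diff(wn)
        if (any(d <= 0))
            msg <- c(msg, "wavenumbers must be strictly increasing")
        else if (max(d) - min(d) > 1e-9 * abs(mean(d)))
            msg <- c(msg, "wavenumber spacing must be uniform")
    }
    if ("absorbance" %in% SummarizedExperiment::assayNames(object) &&
        !all(is.finite(SummarizedExperiment::assay(object, "absorbance"))))
        msg <- c(msg, "absorbance values must all be finite")
    ids <- colnames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "sample ids must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("variety", "label") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'variety' and 'label'")
    } else if (!all(cd$label %in% .VALID_LABELS)) {
        msg <- c(msg, sprintf("labels must be one of: %s",
                              paste(.VALID_LABELS, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
}

setValidity("SpectraSet", .validSpectraSet)

#' PLS-DA model fitted by NIPALS
#'
#' Holds every quantity needed to reproduce predictions of a two-class
#' partial least squares discriminant analysis fit: the NIPALS factors
#' (x-weights W, x-loadings P, y-loadings q, x-scores T, y-scores U), the
#' training means used for centering, the collapsed regression coefficient
#' vector b with `yhat = (x - xMean) %*% b + yMean`, and the preprocessing
#' chain under which the model was trained. The class code is fixed:
#' nonviable = 0, viable = 1.
#'
#' @slot nLV integer, number of latent variables A.
#' @slot weights p x A matrix W of x-weights (unit norm columns).
#' @slot loadings p x A matrix P of x-loadings.
#' @slot yLoadings length-A numeric q of y-loadings.
#' @slot scores n x A matrix T of x-scores.
#' @slot yScores n x A matrix U of y-scores.
#' @slot xMean length-p training column means.
#' @slot yMean scalar training mean of the class code.
#' @slot coefficients length-p regression coefficient vector b.
#' @slot preprocessing list describing the preprocessing chain and its
#'   fitted state (e.g. the MSC reference spectrum), for replay on new data.
#' @slot trainedWavenumbers wavenumber axis (cm^-1) the model expects after
#'   preprocessing; `numeric(0)` when fitted on a bare matrix.
#' @export
setClass("PLSDAModel",
    representation(
        nLV = "integer",
        weights = "matrix",
        loadings = "matrix",
        yLoadings = "numeric",
        scores = "matrix",
        yScores = "matrix",
        xMean = "numeric",
        yMean = "numeric",
        coefficients = "numeric",
        preprocessing = "list",
        trainedWavenumbers = "numeric"
    )
)

setValidity("PLSDAModel", function(object) {
    msg <- character()
    A <- object@nLV
    p <- length(object@xMean)
    if (ncol(object@weights) != A || ncol(object@loadings) != A ||
        length(object@yLoadings) != A || ncol(object@scores) != A)
        msg <- c(msg, "factor dimensions inconsistent with nLV")
    if (nrow(object@weights) != p || nrow(object@loadings) != p ||
        length(object@coefficients) != p)
        msg <- c(msg, "variable dimensions inconsistent")
    if (length(object@trainedWavenumbers) &&
        length(object@trainedWavenumbers) != p)
        msg <- c(msg, "trainedWavenumbers length must equal p")
    if (length(msg)) msg else TRUE
})

#' VIP scores and threshold-based variable selection
#'
#' @slot scores per-variable VIP scores (all >= 0; sum of squares equals the
#'   number of variables).
#' @slot threshold the selection threshold applied to `scores`.
#' @slot selectedMask logical mask, `scores >= threshold`.
#' @slot scanTable data.frame with one row per scanned threshold:
#'   `threshold`, `nSelected`, `cvAccuracy` (NA when no variable survives),
#'   and `nLV` of the refitted reduced model.
#' @export
setClass("VIPResult",
    representation(
        scores = "numeric",
        threshold = "numeric",
        selectedMask = "logical",
        scanTable = "data.frame"
    )
)

setValidity("VIPResult", function(object) {
    msg <- character()
    if (any(object@scores < 0)) msg <- c(msg, "VIP scores must be >= 0")
    if (length(object@selectedMask) != length(object@scores))
        msg <- c(msg, "mask length must equal score length")
    if (!isTRUE(all(object@selectedMask ==
                    (object@scores >= object@threshold))))
        msg <- c(msg, "selectedMask must equal scores >= threshold")
    if (length(msg)) msg else TRUE
})

#' Hotelling's T2 / Q-residual diagnostics
#'
#' Per-sample leverage (T2, distance within the latent-variable space) and
#' lack-of-fit (Q, squared spectral residual off the model plane), with
#' their confidence limits. A sample is flagged as an outlier only when it
#' exceeds BOTH limits; single-statistic exceedances are kept separately
#' for inspection.
#'
#' @slot t2,q per-sample statistics (>= 0).
#' @slot t2Limit,qLimit confidence limits at `confidence`.
#' @slot confidence the confidence level used (default 0.989).
#' @slot outlier logical, `t2 > t2Limit & q > qLimit`.
#' @slot highT2,highQ the single-statistic flags.
#' @export
setClass("DiagnosticReport",
    representation(
        t2 = "numeric",
        q = "numeric",
        t2Limit = "numeric",
        qLimit = "numeric",
        confidence = "numeric",
        outlier = "logical",
        highT2 = "logical",
        highQ = "logical"
    )
)

setValidity("DiagnosticReport", function(object) {
    msg <- character()
    if (any(object@t2 < -1e-12) || any(object@q < -1e-12))
        msg <- c(msg, "T2 and Q must be non-negative")
    if (!isTRUE(all(object@outlier == (object@highT2 & object@highQ))))
        msg <- c(msg, "outlier flag must be highT2 & highQ")
    if (length(msg)) msg else TRUE
})

#' Classification evaluation report
#'
#' Confusion-matrix counts (viable is the positive class) with the standard
#' chemometric summary metrics, the ROC sweep, its trapezoidal AUC and the
#' sensitivity/specificity crossing threshold.
#'
#' Metrics: sensitivity tp/(tp+fn), specificity tn/(tn+fp), non-error rate
#' NER = (sensitivity+specificity)/2, error rate ER = 1 - NER, precision
#' PREC = tp/(tp+fp), false positive rate FPR = fp/(fp+tn), and overall
#' accuracy (tp+tn)/n. Undefined ratios (zero denominator) are NA.
#'
#' @slot tp,fn,fp,tn confusion counts.
#' @slot metrics named numeric vector (sensitivity, specificity, ner, er,
#'   prec, fpr, accuracy).
#' @slot rocPoints data.frame of the ROC sweep: `threshold`, `sensitivity`,
#'   `specificity`, `fpr`; empty when no continuous scores were supplied.
#' @slot auc trapezoidal area under the ROC curve (NA without scores).
#' @slot crossingThreshold threshold where sensitivity and specificity
#'   cross (NA without scores).
#' @slot threshold the decision threshold used for the confusion counts.
#' @export
setClass("EvalReport",
    representation(
        tp = "integer", fn = "integer", fp = "integer", tn = "integer",
        metrics = "numeric",
        rocPoints = "data.frame",
        auc = "numeric",
        crossingThreshold = "numeric",
        threshold = "numeric"
    )
)

setValidity("EvalReport", function(object) {
    counts <- c(object@tp, object@fn, object@fp, object@tn)
    msg <- character()
    if (any(counts < 0)) msg <- c(msg, "confusion counts must be >= 0")
    if (sum(counts) <= 0) msg <- c(msg, "confusion matrix must be non-empty")
    if (length(msg)) msg else TRUE
})
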
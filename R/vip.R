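## Variable importance in projection. For variable j,
##   VIP_j = sqrt( p * sum_a (w_ja / ||w_a||)^2 SSY_a / sum_a SSY_a )
## with SSY_a = q_a^2 (t_a' t_a) the Y sum of squares explained by
## component a. With normalized weights the scores satisfy the identity
## sum_j VIP_j^2 = p, which is asserted by the class validity checks in the
## test suite.

#' VIP scores of a fitted PLS-DA model
#'
#' @param model a fitted [PLSDAModel-class].
#' @param threshold selection threshold applied to the scores
#'   (default 1, the conventional "greater than average influence" cut).
#' @return a [VIPResult-class] (with an empty scan table; see
#'   [vipThresholdScan()] for threshold calibration).
#' @export
computeVIP <- function(model, threshold = 1) {
    W <- model@weights
    Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    ssy <- model@yLoadings^2 * colSums(model@scores^2)
    if (sum(ssy) < 1e-300)
        stop("degenerate model: explained Y sum of squares is zero")
    p <- nrow(W)
    scores <- sqrt(p * drop(Wn^2 %*% ssy) / sum(ssy))
    new("VIPResult", scores = scores, threshold = threshold,
        selectedMask = scores >= threshold,
        scanTable = data.frame(threshold = numeric(), nSelected = integer(),
                               cvAccuracy = numeric(), nLV = integer()))
}

#' VIP threshold scan with refitting
#'
#' Fits a full-variable PLS-DA model (number of LVs chosen by
#' cross-validation), computes VIP scores, and then for each candidate
#' threshold selects the variables with VIP >= threshold, refits on the
#' reduced variable set (re-running LV selection), and records the reduced
#' model's cross-validated accuracy. The returned threshold maximizes CV
#' accuracy, with ties broken toward fewer variables, then toward the
#' smaller threshold. A threshold that selects no variable is recorded with
#' `NA` accuracy.
#'
#' @param x spectra ([SpectraSet-class] or matrix).
#' @param y 0/1 class code (taken from labels when `x` is a `SpectraSet`).
#' @param thresholds candidate thresholds (default `seq(0.8, 1.5, 0.1)`).
#' @param maxLV,folds,seed cross-validation protocol, as in [selectNumLV()].
#' @return a [VIPResult-class] with the scan table filled in.
#' @export
vipThresholdScan <- function(x, y = NULL, thresholds = seq(0.8, 1.5, by = 0.1),
                             maxLV = 15, folds = 10, seed = 1) {
    if (is(x, "SpectraSet")) { y <- classCode(x); x <- absorbance(x) }
    X <- as.matrix(x); y <- as.numeric(y)
    stopifnot(length(thresholds) >= 1)
    sel <- selectNumLV(X, y, maxLV = maxLV, folds = folds, seed = seed)
    full <- fitPLSDA(X, y, nLV = sel$nLV)
    vip <- computeVIP(full)
    rows <- lapply(thresholds, function(th) {
        mask <- vip@scores >= th
        if (!any(mask))
            return(data.frame(threshold = th, nSelected = 0L,
                              cvAccuracy = NA_real_, nLV = NA_integer_))
        selR <- selectNumLV(X[, mask, drop = FALSE], y, maxLV = maxLV,
                            folds = folds, seed = seed)
        data.frame(threshold = th, nSelected = sum(mask),
                   cvAccuracy = 1 - min(selR$cvError), nLV = selR$nLV)
    })
    scan <- do.call(rbind, rows)
    ok <- which(!is.na(scan$cvAccuracy))
    if (!length(ok)) stop("every threshold selected zero variables")
    best <- ok[order(-scan$cvAccuracy[ok], scan$nSelected[ok],
                     scan$threshold[ok])][1]
    th <- scan$threshold[best]
    new("VIPResult", scores = vip@scores, threshold = th,
        selectedMask = vip@scores >= th, scanTable = scan)
}

#' Selected wavenumbers of a VIP result
#' @param vip a [VIPResult-class].
#' @param wavenumbers the wavenumber axis the scores refer to.
#' @return the selected wavenumbers in cm^-1.
#' @export
selectedWavenumbers <- function(vip, wavenumbers)
    wavenumbers[vip@selectedMask]

setMethod("show", "VIPResult", function(object) {
    cat(sprintf("VIPResult: %d variables, threshold %.3g, %d selected\n",
                length(object@scores), object@threshold,
                sum(object@selectedMask)))
    if (nrow(object@scanTable)) {
        cat("  threshold scan:\n")
        print(object@scanTable, row.names = FALSE)
    }
    invisible(object)
})
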
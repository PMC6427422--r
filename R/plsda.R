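## NIPALS PLS-DA. The class membership is regressed as a 0/1 code
## (nonviable = 0, viable = 1) on the (preprocessed) spectra:
##     Y = X b + E,    X = T P' + E_X,    Y = U Q' + E_Y
## Components are extracted one at a time by NIPALS with deflation; the
## collapsed coefficient vector is b = W (P'W)^{-1} q, so prediction is
## yhat = (x - xMean) b + yMean. Classification applies the +/-0.5 band
## around each class code: yhat >= 0.5 -> viable, else nonviable, with
## values outside [-0.5, 1.5] assigned to the nearest class and flagged.

.NIPALS_TOL <- 1e-10
.NIPALS_MAXIT <- 500L

## Core NIPALS on a centered X and centered y. Returns the factor matrices.
.nipals <- function(Xc, yc, nLV) {
    n <- nrow(Xc); p <- ncol(Xc)
    W <- matrix(0, p, nLV); P <- matrix(0, p, nLV)
    Tm <- matrix(0, n, nLV); U <- matrix(0, n, nLV)
    q <- numeric(nLV)
    for (a in seq_len(nLV)) {
        u <- yc
        wOld <- rep(Inf, p)
        it <- 0L
        repeat {
            it <- it + 1L
            w <- crossprod(Xc, u)
            nw <- sqrt(sum(w^2))
            if (nw < 1e-300)
                stop(sprintf("NIPALS degenerate at component %d: X'u ~ 0", a))
            w <- w / nw
            tv <- Xc %*% w
            tt <- sum(tv^2)
            if (tt < 1e-300)
                stop(sprintf("NIPALS degenerate at component %d: t ~ 0", a))
            qa <- sum(yc * tv) / tt
            u <- yc * qa / max(qa^2, 1e-300)
            if (sqrt(sum((w - wOld)^2)) < .NIPALS_TOL) break
            if (it >= .NIPALS_MAXIT)
                stop(sprintf("NIPALS failed to converge at component %d", a))
            wOld <- w
        }
        pv <- crossprod(Xc, tv) / tt
        W[, a] <- w; P[, a] <- pv; Tm[, a] <- tv; U[, a] <- u; q[a] <- qa
        Xc <- Xc - tv %*% t(pv)
        yc <- yc - tv * qa
    }
    list(W = W, P = P, T = Tm, U = U, q = q)
}

## Collapsed coefficients for the first A components of a factorization.
.coefForA <- function(fac, A) {
    W <- fac$W[, seq_len(A), drop = FALSE]
    P <- fac$P[, seq_len(A), drop = FALSE]
    drop(W %*% solve(crossprod(P, W), fac$q[seq_len(A)]))
}

#' Fit a PLS-DA model with NIPALS
#'
#' Mean-centers `x` and `y` on the training means (no per-column scaling)
#' and extracts `nLV` latent variables by NIPALS with deflation.
#'
#' @param x a [SpectraSet-class] (the 0/1 class code is then taken from its
#'   labels) or a samples x variables numeric matrix.
#' @param y numeric response; for classification the 0/1 class code
#'   (nonviable = 0, viable = 1). Ignored (derived from labels) when `x` is
#'   a `SpectraSet`.
#' @param nLV number of latent variables, `<= min(n - 1, p)`.
#' @param preprocessing optional fitted preprocessing chain to store with
#'   the model for replay on new data (see [fitPreprocess()]).
#' @return a [PLSDAModel-class].
#' @examples
#' set <- simulateSpectra(simulationConfig(), 10)
#' m <- fitPLSDA(set, nLV = 3)
#' @export
fitPLSDA <- function(x, y = NULL, nLV, preprocessing = list()) {
    wn <- numeric(0)
    if (is(x, "SpectraSet")) {
        y <- classCode(x)
        if (anyNA(y))
            stop("cannot fit on 'unknown' labels; drop unlabelled samples")
        wn <- as.numeric(wavenumbers(x))
        X <- absorbance(x)
    } else {
        X <- as.matrix(x)
        if (is.null(y)) stop("y is required when x is a matrix")
    }
    y <- as.numeric(y)
    n <- nrow(X); p <- ncol(X)
    stopifnot(length(y) == n)
    nLV <- as.integer(nLV)
    if (nLV < 1 || nLV > min(n - 1, p))
        stop("nLV must be in 1..min(n - 1, p)")
    if (length(unique(y)) < 2)
        stop("y is single-valued: both classes must be present")
    xMean <- colMeans(X)
    yMean <- mean(y)
    fac <- .nipals(sweep(X, 2, xMean), y - yMean, nLV)
    new("PLSDAModel",
        nLV = nLV, weights = fac$W, loadings = fac$P, yLoadings = fac$q,
        scores = fac$T, yScores = fac$U, xMean = xMean, yMean = yMean,
        coefficients = .coefForA(fac, nLV),
        preprocessing = preprocessing, trainedWavenumbers = wn)
}

#' Continuous PLS-DA response for new spectra
#'
#' `yhat = (x - xMean) b + yMean`. When both the model and `set` carry a
#' wavenumber axis they must match exactly; `set` must already be on the
#' model's preprocessing scale (the pipeline-level predictors replay the
#' stored chain first, see [runExternalTest()]).
#'
#' @param model a [PLSDAModel-class].
#' @param set a [SpectraSet-class] or samples x variables matrix aligned
#'   with the model's variables.
#' @return numeric vector of continuous responses, one per sample.
#' @export
predictResponse <- function(model, set) {
    X <- .asMatrix(set)
    if (is(set, "SpectraSet") && length(model@trainedWavenumbers)) {
        wn <- as.numeric(wavenumbers(set))
        if (length(wn) != length(model@trainedWavenumbers) ||
            any(wn != model@trainedWavenumbers)) {
            bad <- if (length(wn) != length(model@trainedWavenumbers))
                NA_real_
            else wn[which(wn != model@trainedWavenumbers)[1]]
            stop("wavenumber axis mismatch with the trained model",
                 if (!is.na(bad)) sprintf(" (first differing: %g cm^-1)", bad))
        }
    }
    if (ncol(X) != length(model@xMean))
        stop("variable count mismatch with the trained model")
    drop(sweep(X, 2, model@xMean) %*% model@coefficients) + model@yMean
}

#' @describeIn predictResponse `predict` method for `PLSDAModel`.
#' @param object a `PLSDAModel`.
#' @param newdata spectra to predict.
#' @param ... unused.
#' @export
setMethod("predict", "PLSDAModel", function(object, newdata, ...)
    predictResponse(object, newdata))

#' Classify continuous responses by the +/-0.5 baseline rule
#'
#' A response within 0.5 of a class code is assigned to that class:
#' `yhat` in \[0.5, 1.5\] is viable, in \[-0.5, 0.5) nonviable (a tie at
#' exactly 0.5 goes to viable, the closed lower bound of the viable band).
#' Responses outside \[-0.5, 1.5\] belong to no band; they are assigned to
#' the nearest class code and flagged `outsideBaseline` so every sample is
#' accounted for.
#'
#' @param yhat numeric continuous responses.
#' @param baseline half-width of the class band, in (0, 1); default 0.5.
#' @return data.frame with `code` (0/1), `label`, and `outsideBaseline`.
#' @export
classifyBaseline <- function(yhat, baseline = 0.5) {
    stopifnot(baseline > 0, baseline < 1)
    code <- as.integer(yhat >= baseline)
    data.frame(code = code, label = codeToLabel(code),
               outsideBaseline = yhat < -baseline | yhat > 1 + baseline)
}

## Mean CV misclassification error for each number of LVs 1..maxLV.
## Stratified k-fold at a fixed seed. Returns a length-maxLV error vector.
.cvErrorByLV <- function(X, y, maxLV, folds, seed, baseline = 0.5) {
    n <- nrow(X)
    foldId <- .withSeed(seed, {
        id <- integer(n)
        for (cls in unique(y)) {
            idx <- sample(which(y == cls))
            id[idx] <- rep_len(seq_len(folds), length(idx))
        }
        id
    })
    errs <- matrix(NA_real_, folds, maxLV)
    for (k in seq_len(folds)) {
        trIdx <- which(foldId != k); teIdx <- which(foldId == k)
        if (length(unique(y[trIdx])) < 2 || length(teIdx) == 0)
            stop("stratification failed: a fold lacks both classes")
        Xtr <- X[trIdx, , drop = FALSE]
        A <- min(maxLV, length(trIdx) - 1, ncol(X))
        xm <- colMeans(Xtr); ym <- mean(y[trIdx])
        fac <- .nipals(sweep(Xtr, 2, xm), y[trIdx] - ym, A)
        Xte <- sweep(X[teIdx, , drop = FALSE], 2, xm)
        for (a in seq_len(maxLV)) {
            b <- .coefForA(fac, min(a, A))
            pred <- as.integer(drop(Xte %*% b) + ym >= baseline)
            errs[k, a] <- mean(pred != y[teIdx])
        }
    }
    colMeans(errs)
}

#' Select the number of latent variables by cross-validation
#'
#' Stratified k-fold cross-validation on the calibration set; the chosen A
#' minimizes the mean misclassification rate under the +/-0.5 rule, with
#' ties broken toward the smallest A.
#'
#' @param x spectra ([SpectraSet-class] or matrix).
#' @param y 0/1 class code (taken from labels when `x` is a `SpectraSet`).
#' @param maxLV largest number of LVs to consider.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with `nLV` (the selection) and `cvError` (per-A mean error).
#' @export
selectNumLV <- function(x, y = NULL, maxLV = 15, folds = 10, seed = 1) {
    if (is(x, "SpectraSet")) { y <- classCode(x); x <- absorbance(x) }
    X <- as.matrix(x); y <- as.numeric(y)
    stopifnot(maxLV >= 1, folds >= 2)
    maxLV <- min(maxLV, ncol(X), nrow(X) - ceiling(nrow(X) / folds) - 1)
    err <- .cvErrorByLV(X, y, maxLV, folds, seed)
    list(nLV = which.min(err), cvError = err)
}

setMethod("show", "PLSDAModel", function(object) {
    cat(sprintf("PLSDAModel: %d latent variable(s), %d variables\n",
                object@nLV, length(object@xMean)))
    cat(sprintf("  training samples: %d; class code: nonviable=0, viable=1\n",
                nrow(object@scores)))
    if (length(object@preprocessing))
        cat("  preprocessing:", paste(vapply(object@preprocessing,
            function(s) s$op, ""), collapse = " -> "), "\n")
    invisible(object)
})
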
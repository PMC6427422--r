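## Hotelling's T2 / Q-residual outlier diagnostics for a fitted PLS-DA
## model. T2 measures a sample's distance within the latent-variable space
## (normalized by the sample variance, n-1, of the training scores); Q is
## the squared spectral residual off the model plane. The T2 limit uses the
## F-distribution formula A(n-1)/(n-A) F(alpha; A, n-A); the Q limit uses
## the Jackson-Mudholkar approximation from the residual eigenvalues of the
## calibration data. A sample is an outlier only when BOTH are exceeded.

.jacksonMudholkarLimit <- function(residEig, confidence) {
    residEig <- residEig[residEig > 1e-12 * max(residEig, 0)]
    if (!length(residEig)) return(0)
    th1 <- sum(residEig); th2 <- sum(residEig^2); th3 <- sum(residEig^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (is.finite(h0) && h0 > 0) {
        z <- qnorm(confidence)
        inner <- z * sqrt(2 * th2 * h0^2) / th1 +
            1 + th2 * h0 * (h0 - 1) / th1^2
        if (inner > 0) return(th1 * inner^(1 / h0))
    }
    ## The power transform is only valid for h0 > 0; with a few dominant
    ## residual eigenvalues h0 can go negative, so fall back to the
    ## moment-matched chi-square approximation g * chisq_h(alpha) with
    ## g = th2/th1, h = th1^2/th2.
    th2 / th1 * qchisq(confidence, th1^2 / th2)
}

#' T2/Q outlier diagnostics
#'
#' Computes per-sample Hotelling's T2 and Q residuals of `set` under
#' `model`, with confidence limits derived from the calibration data (the
#' training scores stored in the model and the residuals of `set` itself
#' when `set` is the calibration set — pass the calibration spectra to
#' obtain the limits used for outlier screening).
#'
#' @param model a fitted [PLSDAModel-class].
#' @param set spectra on the model's preprocessing scale
#'   ([SpectraSet-class] or matrix).
#' @param confidence confidence level of the limits (default 0.989).
#' @return a [DiagnosticReport-class].
#' @export
plsdaDiagnostics <- function(model, set, confidence = 0.989) {
    X <- .asMatrix(set)
    n <- nrow(model@scores); A <- model@nLV
    if (n <= A) stop("T2 limit undefined: need n > A training samples")
    stopifnot(confidence > 0, confidence < 1)
    Xc <- sweep(X, 2, model@xMean)
    ## NIPALS score projection for (new) samples: T = Xc W (P'W)^{-1}
    R <- model@weights %*%
        solve(crossprod(model@loadings, model@weights))
    Tnew <- Xc %*% R
    scoreVar <- apply(model@scores, 2, var)
    t2 <- rowSums(sweep(Tnew^2, 2, scoreVar, "/"))
    E <- Xc - Tnew %*% t(model@loadings)
    q <- rowSums(E^2)
    t2Limit <- A * (n - 1) / (n - A) * qf(confidence, A, n - A)
    residEig <- svd(E, nu = 0, nv = 0)$d^2 / (nrow(X) - 1)
    qLimit <- .jacksonMudholkarLimit(residEig, confidence)
    highT2 <- t2 > t2Limit
    highQ <- q > qLimit
    new("DiagnosticReport", t2 = t2, q = q,
        t2Limit = t2Limit, qLimit = qLimit, confidence = confidence,
        outlier = highT2 & highQ, highT2 = highT2, highQ = highQ)
}

setMethod("show", "DiagnosticReport", function(object) {
    cat(sprintf("DiagnosticReport: %d samples at %.1f%% confidence\n",
                length(object@t2), 100 * object@confidence))
    cat(sprintf("  T2 limit %.4g (%d above), Q limit %.4g (%d above)\n",
                object@t2Limit, sum(object@highT2),
                object@qLimit, sum(object@highQ)))
    cat(sprintf("  outliers (both above): %d\n", sum(object@outlier)))
    invisible(object)
})
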
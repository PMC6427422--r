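## Spectral preprocessing menu: per-spectrum normalization (maximum, mean,
## range), standard normal variate (SNV), multiplicative scatter correction
## (MSC), Savitzky-Golay derivatives, and wavenumber-region trimming.
## All transforms are pure and row-independent; only trimming changes shape.

.asMatrix <- function(x) if (is(x, "SpectraSet")) absorbance(x) else as.matrix(x)

.rebuild <- function(x, M) {
    if (is(x, "SpectraSet")) setAbsorbance(x, M) else M
}

.rowLabel <- function(x, i) {
    if (is(x, "SpectraSet")) sampleIds(x)[i] else as.character(i)
}

#' Per-spectrum normalization
#'
#' `"max"` divides each spectrum by its maximum, `"mean"` by its mean,
#' `"range"` maps it linearly onto \[0, 1\].
#'
#' @param x a [SpectraSet-class] or a samples x wavenumbers matrix.
#' @param mode one of `"max"`, `"mean"`, `"range"`.
#' @return object of the same type as `x`.
#' @export
normalizeSpectra <- function(x, mode = c("max", "mean", "range")) {
    mode <- match.arg(mode)
    M <- .asMatrix(x)
    lo <- apply(M, 1, min); hi <- apply(M, 1, max)
    div <- switch(mode, max = hi, mean = rowMeans(M), range = hi - lo)
    bad <- which(abs(div) < 1e-300)
    if (length(bad))
        stop(sprintf("degenerate spectrum (zero %s divisor) for sample %s",
                     mode, .rowLabel(x, bad[1])))
    out <- if (mode == "range") (M - lo) / div else M / div
    .rebuild(x, out)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to mean 0 and sample standard deviation
#' (n-1 denominator) 1, removing per-spectrum additive and multiplicative
#' scatter effects.
#'
#' @inheritParams normalizeSpectra
#' @return object of the same type as `x`.
#' @export
snv <- function(x) {
    M <- .asMatrix(x)
    mu <- rowMeans(M)
    sdv <- apply(M, 1, sd)
    bad <- which(sdv < 1e-300)
    if (length(bad))
        stop(sprintf("degenerate (constant) spectrum for sample %s",
                     .rowLabel(x, bad[1])))
    .rebuild(x, (M - mu) / sdv)
}

## OLS fit of one spectrum on the reference: x ~ a + b * ref.
.mscCoef <- function(xRow, ref) {
    refC <- ref - mean(ref)
    b <- sum(refC * (xRow - mean(xRow))) / sum(refC^2)
    c(a = mean(xRow) - b * mean(ref), b = b)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum by ordinary least
#' squares, `x ~ a + b * ref`, and returns `(x - a) / b`. With the default
#' `reference = NULL` the column-mean spectrum of `x` itself is used; in a
#' calibrated pipeline the stored calibration-set mean is passed so new data
#' are corrected against the training reference.
#'
#' @inheritParams normalizeSpectra
#' @param reference numeric reference spectrum of matching length, or
#'   `NULL` for the column-mean spectrum of `x`.
#' @return object of the same type as `x`.
#' @export
msc <- function(x, reference = NULL) {
    M <- .asMatrix(x)
    if (is.null(reference)) reference <- colMeans(M)
    if (length(reference) != ncol(M))
        stop("MSC reference length must match the wavenumber axis")
    out <- M
    for (i in seq_len(nrow(M))) {
        ab <- .mscCoef(M[i, ], reference)
        if (abs(ab["b"]) < 1e-12)
            stop(sprintf("degenerate MSC slope for sample %s",
                         .rowLabel(x, i)))
        out[i, ] <- (M[i, ] - ab["a"]) / ab["b"]
    }
    .rebuild(x, out)
}

#' Savitzky-Golay derivative
#'
#' Applies a Savitzky-Golay local-polynomial derivative filter to each
#' spectrum along the wavenumber axis. The derivative is taken with respect
#' to the grid index (per grid step); set `perWavenumber = TRUE` to rescale
#' by `1/step^order` into per-cm^-1 units. Edges are handled by the
#' polynomial fits of the terminal windows.
#'
#' The window is a full odd point count. Chemometrics toolboxes often
#' parameterize the filter by points per side, so a "4-point window" maps
#' to `windowPoints = 2 * 4 + 1 = 9`, the default here.
#'
#' @inheritParams normalizeSpectra
#' @param derivativeOrder 1 or 2.
#' @param windowPoints odd full window length, `>= polyorder + 1`.
#' @param polyorder polynomial degree (default 2).
#' @param perWavenumber rescale the derivative into per-cm^-1 units
#'   (requires `x` to be a `SpectraSet`).
#' @return object of the same type as `x`.
#' @export
savgolDerivative <- function(x, derivativeOrder = 1, windowPoints = 9,
                             polyorder = 2, perWavenumber = FALSE) {
    if (windowPoints %% 2 == 0)
        stop("windowPoints must be odd: a toolbox-style '4-point' setting ",
             "means 4 points per side, i.e. windowPoints = 9")
    if (!derivativeOrder %in% c(1, 2))
        stop("derivativeOrder must be 1 or 2")
    if (derivativeOrder > polyorder)
        stop("derivativeOrder must be <= polyorder")
    if (windowPoints < polyorder + 1)
        stop("windowPoints must be >= polyorder + 1")
    M <- .asMatrix(x)
    if (windowPoints > ncol(M))
        stop("windowPoints exceeds the spectrum length")
    out <- t(apply(M, 1, signal::sgolayfilt, p = polyorder,
                   n = windowPoints, m = derivativeOrder, ts = 1))
    if (perWavenumber) {
        if (!is(x, "SpectraSet"))
            stop("perWavenumber rescaling needs a SpectraSet")
        step <- diff(wavenumbers(x))[1]
        out <- out / step^derivativeOrder
    }
    .rebuild(x, out)
}

#' Trim spectra to a wavenumber interval
#'
#' Keeps the columns with `lo <= wavenumber <= hi` (closed interval);
#' sample metadata are unchanged. Typically used to drop the
#' information-free noisy region above 9000 cm^-1.
#'
#' @param set a [SpectraSet-class].
#' @param lo,hi interval bounds in cm^-1.
#' @return a [SpectraSet-class] with the reduced axis.
#' @export
trimRegion <- function(set, lo, hi) {
    stopifnot(is(set, "SpectraSet"), lo < hi)
    keep <- wavenumbers(set) >= lo & wavenumbers(set) <= hi
    if (!any(keep))
        stop("trim interval does not overlap the wavenumber range")
    set[keep, ]
}

## ---- preprocessing chains -------------------------------------------------

#' Describe one preprocessing step
#'
#' @param op one of `"max_norm"`, `"mean_norm"`, `"range_norm"`, `"snv"`,
#'   `"msc"`, `"savgol"`.
#' @param ... step parameters: for `"savgol"`, `derivativeOrder`,
#'   `windowPoints`, `polyorder`; for `"msc"`, optionally `reference`.
#' @return a list describing the step, for use in a chain.
#' @seealso [fitPreprocess()], [applyPreprocess()]
#' @export
preprocessStep <- function(op = c("max_norm", "mean_norm", "range_norm",
                                  "snv", "msc", "savgol"), ...) {
    op <- match.arg(op)
    c(list(op = op), list(...))
}

.applyStep <- function(M, step) {
    switch(step$op,
        max_norm = normalizeSpectra(M, "max"),
        mean_norm = normalizeSpectra(M, "mean"),
        range_norm = normalizeSpectra(M, "range"),
        snv = snv(M),
        msc = msc(M, reference = step$reference),
        savgol = savgolDerivative(
            M,
            derivativeOrder = step$derivativeOrder %||% 1,
            windowPoints = step$windowPoints %||% 9,
            polyorder = step$polyorder %||% 2),
        stop("unknown preprocessing op: ", step$op))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a preprocessing chain on calibration spectra
#'
#' Resolves the data-dependent state of a chain — currently the MSC
#' reference spectrum, taken as the calibration mean at that point of the
#' chain — so the identical transform can be replayed on validation or test
#' spectra without information leakage.
#'
#' @param set calibration spectra ([SpectraSet-class] or matrix).
#' @param steps list of [preprocessStep()] entries (possibly empty = raw).
#' @return the fitted chain: the step list with embedded references.
#' @export
fitPreprocess <- function(set, steps) {
    M <- .asMatrix(set)
    fitted <- list()
    for (step in steps) {
        if (step$op == "msc" && is.null(step$reference))
            step$reference <- colMeans(M)
        M <- .applyStep(M, step)
        fitted <- c(fitted, list(step))
    }
    fitted
}

#' Apply a (fitted) preprocessing chain
#'
#' @param x spectra ([SpectraSet-class] or matrix).
#' @param steps a chain from [fitPreprocess()] (or a stateless chain).
#' @return object of the same type as `x`.
#' @export
applyPreprocess <- function(x, steps) {
    M <- .asMatrix(x)
    for (step in steps) M <- .applyStep(M, step)
    .rebuild(x, M)
}
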
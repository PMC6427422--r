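#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, samples in rows, wavenumbers in columns
#'   (the orientation of a spectra table). Stored transposed internally.
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, one per column
#'   of `absorbance`. Columns are reordered so the axis is ascending.
#' @param sampleIds unique character ids, one per row.
#' @param variety character/factor of seed varieties, one per row.
#' @param label viability labels, each one of `"viable"`, `"nonviable"`,
#'   `"unknown"`. Defaults to `"unknown"` (prediction-only data).
#'
#' @return A [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(matrix(rnorm(6), 2, 3), wavenumbers = c(4000, 4004, 4008),
#'                 sampleIds = c("a", "b"), variety = c("V1", "V2"),
#'                 label = c("viable", "nonviable"))
#' absorbance(s)
#' @export
SpectraSet <- function(absorbance, wavenumbers, sampleIds,
                       variety = rep("V1", nrow(absorbance)),
                       label = rep("unknown", nrow(absorbance))) {
    absorbance <- as.matrix(absorbance)
    if (length(wavenumbers) != ncol(absorbance))
        stop("length(wavenumbers) must equal ncol(absorbance)")
    if (length(sampleIds) != nrow(absorbance))
        stop("length(sampleIds) must equal nrow(absorbance)")
    ord <- order(wavenumbers)
    wavenumbers <- as.numeric(wavenumbers[ord])
    absorbance <- absorbance[, ord, drop = FALSE]
    label <- as.character(label)
    variety <- as.character(variety)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(absorbance = t(absorbance)),
        rowData = S4Vectors::DataFrame(wavenumber = wavenumbers),
        colData = S4Vectors::DataFrame(variety = variety, label = label,
                                       row.names = as.character(sampleIds))
    )
    new("SpectraSet", se)
}

#' @rdname SpectraSet
#' @param x,object a `SpectraSet`.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectraSet
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
    SummarizedExperiment::rowData(x)$wavenumber)

#' @rdname SpectraSet
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraSet
#' @export
setMethod("absorbance", "SpectraSet", function(x)
    t(SummarizedExperiment::assay(x, "absorbance")))

#' @rdname SpectraSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SpectraSet
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colnames(x))

#' @rdname SpectraSet
#' @export
setGeneric("variety", function(x) standardGeneric("variety"))

#' @rdname SpectraSet
#' @export
setMethod("variety", "SpectraSet", function(x)
    SummarizedExperiment::colData(x)$variety)

#' @rdname SpectraSet
#' @export
setGeneric("viabilityLabel", function(x) standardGeneric("viabilityLabel"))

#' @rdname SpectraSet
#' @export
setMethod("viabilityLabel", "SpectraSet", function(x)
    SummarizedExperiment::colData(x)$label)

#' Replace the absorbance matrix (samples x wavenumbers)
#'
#' @param x a `SpectraSet`.
#' @param value samples x wavenumbers matrix conforming to `x`.
#' @keywords internal
setAbsorbance <- function(x, value) {
    stopifnot(nrow(value) == ncol(x), ncol(value) == nrow(x))
    SummarizedExperiment::assay(x, "absorbance") <- t(value)
    x
}

#' Numeric class code of the viability labels
#'
#' viable = 1, nonviable = 0, unknown = NA — the Y coding of the PLS-DA
#' regression.
#'
#' @param x a `SpectraSet` or a character vector of labels.
#' @return numeric vector of 0/1/NA.
#' @export
classCode <- function(x) {
    lab <- if (is(x, "SpectraSet")) viabilityLabel(x) else as.character(x)
    code <- rep(NA_real_, length(lab))
    code[lab == "viable"] <- 1
    code[lab == "nonviable"] <- 0
    code
}

#' Labels from a 0/1 class code
#' @param code numeric vector of 0/1 (NA allowed).
#' @return character vector of `"nonviable"`/`"viable"`/`"unknown"`.
#' @export
codeToLabel <- function(code) {
    lab <- rep("unknown", length(code))
    lab[!is.na(code) & code == 1] <- "viable"
    lab[!is.na(code) & code == 0] <- "nonviable"
    lab
}

setMethod("show", "SpectraSet", function(object) {
    wn <- wavenumbers(object)
    cat(sprintf("SpectraSet: %d spectra x %d wavenumbers (%g-%g cm^-1, step %g)\n",
                ncol(object), nrow(object),
                min(wn), max(wn), if (length(wn) > 1) wn[2] - wn[1] else NA))
    tab <- table(factor(viabilityLabel(object), levels = .VALID_LABELS))
    cat("  labels:  ", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = " "), "\n")
    cat("  variety: ", paste(sprintf("%s=%d", names(table(variety(object))),
                                     table(variety(object))),
                             collapse = " "), "\n")
    invisible(object)
})
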
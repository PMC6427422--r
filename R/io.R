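## Spectra table dialect: UTF-8 CSV, columns
##   sample_id, variety, label, <wn1>, <wn2>, ...
## with wavenumber column headers in cm^-1 and labels serialized as
## viable|nonviable|unknown. Values are written with 17 significant digits
## so a write/read round trip reproduces doubles exactly.

#' Write a SpectraSet to a CSV spectra table
#'
#' @param set a [SpectraSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readSpectra()]
#' @export
writeSpectra <- function(set, path) {
    stopifnot(is(set, "SpectraSet"))
    A <- absorbance(set)
    wn <- wavenumbers(set)
    num <- apply(A, 2, function(col) sprintf("%.17g", col))
    if (is.null(dim(num))) num <- matrix(num, nrow = nrow(A))
    df <- data.frame(sample_id = sampleIds(set), variety = variety(set),
                     label = viabilityLabel(set), num,
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("sample_id", "variety", "label", sprintf("%.17g", wn))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a CSV spectra table into a SpectraSet
#'
#' The first three columns must be `sample_id`, `variety`, `label`; the
#' remaining column headers are wavenumbers in cm^-1. Wavenumber columns may
#' appear in any order in the file; they are sorted ascending on read.
#' A label of `"unknown"` marks prediction-only samples.
#'
#' @param path path to a spectra CSV.
#' @return a [SpectraSet-class].
#' @export
readSpectra <- function(path) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("sample_id", "variety", "label")
    if (!identical(colnames(df)[seq_len(3)], need))
        stop("spectra table must start with columns: ",
             paste(need, collapse = ", "))
    wnChar <- colnames(df)[-seq_len(3)]
    wn <- suppressWarnings(as.numeric(wnChar))
    if (anyNA(wn))
        stop("non-numeric wavenumber header(s): ",
             paste(head(wnChar[is.na(wn)], 3), collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample ids in spectra table: ",
             paste(head(unique(df$sample_id[duplicated(df$sample_id)]), 3),
                   collapse = ", "))
    bad <- setdiff(unique(df$label), .VALID_LABELS)
    if (length(bad))
        stop("invalid label value(s): ", paste(bad, collapse = ", "))
    A <- as.matrix(df[, -seq_len(3), drop = FALSE])
    if (!is.numeric(A)) stop("absorbance values must be numeric")
    dimnames(A) <- NULL
    SpectraSet(A, wavenumbers = wn, sampleIds = as.character(df$sample_id),
               variety = df$variety, label = df$label)
}
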
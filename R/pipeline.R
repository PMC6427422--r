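## Config-driven orchestration of the full workflow: simulate or load
## spectra -> trim -> compare preprocessing candidates (fit chain on
## calibration only, select LVs by CV, fit, validate under the +/-0.5
## rule) -> persist the winning model archive -> T2/Q diagnostics ->
## external-test evaluation on new data.
##
## All randomness flows from one master seed, split into fixed named
## streams (simulation = seed, split = seed + 1000, CV = seed + 2000) so
## each stage is independently reproducible.

.seedStreams <- function(seed) {
    seed <- as.integer(seed)
    list(simulation = seed, split = seed + 1000L, cv = seed + 2000L)
}

#' Pipeline configuration
#'
#' @param simulation a [simulationConfig()] used when `dataPath` is `NULL`.
#' @param dataPath optional path to a spectra CSV ([readSpectra()] dialect)
#'   used instead of simulation.
#' @param nPerVarietyPerClass simulated seeds per variety per class
#'   (default 124, i.e. 744 spectra over three varieties).
#' @param candidates named list of preprocessing chains to compare; each a
#'   list of [preprocessStep()]s (an empty list is the raw-spectra
#'   candidate). Default: raw vs Savitzky-Golay 1st derivative.
#' @param trim kept wavenumber interval in cm^-1 (default `c(4000, 9000)`,
#'   dropping the information-free noisy tail).
#' @param validationCounts,validationFraction split specification as in
#'   [stratifiedSplit()] (default: 112 validation samples per class).
#' @param maxLV,folds cross-validation protocol for LV selection.
#' @param confidence confidence level of the T2/Q limits (default 0.989).
#' @param baseline half-width of the class decision band (default 0.5).
#' @param seed master seed; per-stage streams are derived from it.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           dataPath = NULL,
                           nPerVarietyPerClass = 124,
                           candidates = list(
                               raw = list(),
                               sg1 = list(preprocessStep("savgol",
                                   derivativeOrder = 1, windowPoints = 9,
                                   polyorder = 2))),
                           trim = c(4000, 9000),
                           validationCounts = 112,
                           validationFraction = NULL,
                           maxLV = 15, folds = 10,
                           confidence = 0.989, baseline = 0.5,
                           seed = 1L) {
    if (length(candidates) < 1) stop("at least one preprocessing candidate")
    if (is.null(names(candidates)) || any(names(candidates) == ""))
        stop("candidates must be a named list")
    cfg <- list(simulation = simulation, dataPath = dataPath,
                nPerVarietyPerClass = nPerVarietyPerClass,
                candidates = candidates, trim = trim,
                validationCounts = validationCounts,
                validationFraction = validationFraction,
                maxLV = maxLV, folds = folds, confidence = confidence,
                baseline = baseline, seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

.loadOrSimulate <- function(config, seeds) {
    if (!is.null(config$dataPath)) readSpectra(config$dataPath)
    else simulateSpectra(config$simulation, config$nPerVarietyPerClass,
                         seed = seeds$simulation)
}

.classCorrect <- function(truth, pred) {
    c(viable = sum(truth == 1 & pred == 1), viableTotal = sum(truth == 1),
      nonviable = sum(truth == 0 & pred == 0),
      nonviableTotal = sum(truth == 0))
}

#' Train and compare preprocessing candidates; build the general model
#'
#' Pools all varieties, trims the axis, splits into calibration and
#' validation once (the same split for every candidate), and for each
#' preprocessing candidate: fits the chain's state on the calibration
#' spectra only (no information leakage), selects the number of latent
#' variables by stratified cross-validation, fits the PLS-DA model and
#' evaluates calibration and validation accuracy under the +/-0.5 rule.
#' The candidate with the highest validation accuracy (ties: fewer LVs)
#' becomes the general model; its archive carries everything needed for
#' bit-reproducible prediction on new spectra.
#'
#' @param config a [pipelineConfig()].
#' @return list of class `"GeneralModelRun"`: `comparison` (one row per
#'   candidate: nLV, per-class correct counts and accuracy for calibration
#'   and validation), `best` (winning candidate name), `archive` (model
#'   archive list, see [saveModelArchive()]), `model` (the winning
#'   [PLSDAModel-class]), `diagnostics` (calibration
#'   [DiagnosticReport-class]), `split` sizes and `seed`.
#' @export
runGeneralModel <- function(config = pipelineConfig()) {
    seeds <- .seedStreams(config$seed)
    full <- .loadOrSimulate(config, seeds)
    full <- trimRegion(full, config$trim[1], config$trim[2])
    sp <- stratifiedSplit(full, validationFraction = config$validationFraction,
                          validationCounts = config$validationCounts,
                          seed = seeds$split)
    cal <- sp$calibration; val <- sp$validation
    yCal <- classCode(cal); yVal <- classCode(val)
    rows <- list(); fits <- list()
    for (nm in names(config$candidates)) {
        chain <- fitPreprocess(cal, config$candidates[[nm]])
        Xcal <- applyPreprocess(absorbance(cal), chain)
        Xval <- applyPreprocess(absorbance(val), chain)
        sel <- selectNumLV(Xcal, yCal, maxLV = config$maxLV,
                           folds = config$folds, seed = seeds$cv)
        model <- fitPLSDA(Xcal, yCal, nLV = sel$nLV, preprocessing = chain)
        model@trainedWavenumbers <- as.numeric(wavenumbers(cal))
        predCal <- classifyBaseline(predictResponse(model, Xcal),
                                    config$baseline)$code
        predVal <- classifyBaseline(predictResponse(model, Xval),
                                    config$baseline)$code
        cc <- .classCorrect(yCal, predCal); vc <- .classCorrect(yVal, predVal)
        rows[[nm]] <- data.frame(
            candidate = nm, nLV = model@nLV,
            calViable = sprintf("%d/%d", cc["viable"], cc["viableTotal"]),
            calNonviable = sprintf("%d/%d", cc["nonviable"],
                                   cc["nonviableTotal"]),
            calAccuracy = (cc["viable"] + cc["nonviable"]) /
                (cc["viableTotal"] + cc["nonviableTotal"]),
            valViable = sprintf("%d/%d", vc["viable"], vc["viableTotal"]),
            valNonviable = sprintf("%d/%d", vc["nonviable"],
                                   vc["nonviableTotal"]),
            valAccuracy = (vc["viable"] + vc["nonviable"]) /
                (vc["viableTotal"] + vc["nonviableTotal"]),
            row.names = NULL)
        fits[[nm]] <- list(model = model, Xcal = Xcal)
    }
    comparison <- do.call(rbind, rows)
    best <- comparison$candidate[order(-comparison$valAccuracy,
                                       comparison$nLV)][1]
    bestFit <- fits[[best]]
    diag <- plsdaDiagnostics(bestFit$model, bestFit$Xcal,
                             confidence = config$confidence)
    archive <- .buildArchive(bestFit$model, config, best, seeds)
    structure(list(comparison = comparison, best = best, archive = archive,
                   model = bestFit$model, diagnostics = diag,
                   split = c(calibration = ncol(cal), validation = ncol(val)),
                   seed = config$seed),
              class = "GeneralModelRun")
}

#' @export
print.GeneralModelRun <- function(x, ...) {
    cat(sprintf("General model run (seed %d): best candidate '%s'\n",
                x$seed, x$best))
    print(x$comparison, row.names = FALSE)
    invisible(x)
}

.buildArchive <- function(model, config, candidate, seeds) {
    list(format = "seednir-model-archive", version = 1L,
         classCode = c(nonviable = 0, viable = 1),
         candidate = candidate,
         trim = config$trim, baseline = config$baseline,
         preprocessing = model@preprocessing,
         nLV = model@nLV,
         weights = model@weights, loadings = model@loadings,
         yLoadings = model@yLoadings,
         scores = model@scores, yScores = model@yScores,
         xMean = model@xMean, yMean = model@yMean,
         coefficients = model@coefficients,
         trainedWavenumbers = model@trainedWavenumbers,
         fitMetadata = list(seed = config$seed, seeds = seeds,
                            folds = config$folds, maxLV = config$maxLV))
}

#' Save / load a model archive
#'
#' The archive is one JSON document holding the full NIPALS factorization,
#' centering means, regression coefficients, the fitted preprocessing chain
#' (including the MSC reference where used), trim bounds, class coding and
#' fit metadata — sufficient for bit-reproducible prediction. Numbers are
#' serialized at full double precision.
#'
#' @param archive an archive list from [runGeneralModel()] (`$archive`).
#' @param path file path of the JSON document.
#' @return `path` (save) / the archive list (load), with matrices restored.
#' @export
saveModelArchive <- function(archive, path) {
    jsonlite::write_json(archive, path, digits = I(17), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname saveModelArchive
#' @export
readModelArchive <- function(path) {
    a <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
    if (!identical(a$format, "seednir-model-archive"))
        stop("not a seednir model archive: ", path)
    for (f in c("weights", "loadings", "scores", "yScores"))
        a[[f]] <- as.matrix(a[[f]])
    a$nLV <- as.integer(a$nLV)
    a$preprocessing <- lapply(a$preprocessing, function(s) {
        s <- as.list(s)
        if (!is.null(s$reference)) s$reference <- as.numeric(s$reference)
        s
    })
    a
}

.modelFromArchive <- function(archive) {
    new("PLSDAModel", nLV = archive$nLV,
        weights = archive$weights, loadings = archive$loadings,
        yLoadings = as.numeric(archive$yLoadings),
        scores = archive$scores, yScores = archive$yScores,
        xMean = as.numeric(archive$xMean), yMean = as.numeric(archive$yMean),
        coefficients = as.numeric(archive$coefficients),
        preprocessing = archive$preprocessing,
        trainedWavenumbers = as.numeric(archive$trainedWavenumbers))
}

## Replay the stored trim + preprocessing chain and predict.
.predictFromArchive <- function(archive, set) {
    stopifnot(is(set, "SpectraSet"))
    if (ncol(set) == 0) stop("empty test set")
    set <- trimRegion(set, archive$trim[1], archive$trim[2])
    model <- .modelFromArchive(archive)
    prepped <- applyPreprocess(set, archive$preprocessing)
    yhat <- predictResponse(model, prepped)
    cls <- classifyBaseline(yhat, archive$baseline)
    data.frame(sample_id = sampleIds(set), yhat = yhat,
               label = cls$label, code = cls$code,
               outsideBaseline = cls$outsideBaseline)
}

#' Predict viability of new seeds with a stored general model
#'
#' Applies the archive's trim and preprocessing chain (with its stored MSC
#' reference) and the +/-0.5 decision rule.
#'
#' @param archive a model archive (list, or path to its JSON document).
#' @param set a [SpectraSet-class] of new spectra on the instrument grid.
#' @return data.frame with per-sample continuous response, label and
#'   outside-baseline flag.
#' @export
predictSeeds <- function(archive, set) {
    if (is.character(archive)) archive <- readModelArchive(archive)
    .predictFromArchive(archive, set)
}

#' Evaluate a stored general model on an external test set
#'
#' @param archive a model archive (list or JSON path).
#' @param testSet a labelled [SpectraSet-class] (e.g. a mixed-variety lot
#'   from [simulateLabelledLot()]), disjoint from training by construction.
#' @return an [EvalReport-class].
#' @export
runExternalTest <- function(archive, testSet) {
    if (is.character(archive)) archive <- readModelArchive(archive)
    pred <- .predictFromArchive(archive, testSet)
    truth <- classCode(testSet)
    if (anyNA(truth)) stop("external test set must be fully labelled")
    evaluateClassification(truth, predicted = pred$code, yhat = pred$yhat,
                           threshold = archive$baseline)
}
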
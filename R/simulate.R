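## Synthetic FT-NIR seed spectra.
##
## Each simulated spectrum is built as
##   variety baseline (offset + linear slope across the axis)
## + sum of Gaussian absorption bands (class-specific amplitudes at the
##   discriminative centers)
## + a global additive class offset (nonviable seeds absorb more)
## then corrupted by a per-sample affine scatter transform
##   x' = a + b * x,  a ~ N(0, scatterOffsetSd), b ~ N(1, scatterSlopeSd)
## (the generative model that MSC and SNV are designed to invert), by a
## per-sample smooth random baseline flex (a low-frequency curve built from
## broad random Gaussians, emulating wavelength-dependent scattering and
## instrumental drift, which derivative preprocessing suppresses), and by
## heteroscedastic Gaussian noise, with the >= tailStart region much noisier
## than the informative range (emulating the information-free 9000-10000
## cm^-1 band of the instrument).

#' Simulation configuration for synthetic seed spectra
#'
#' Returns a validated configuration list whose defaults emulate the
#' structure of FT-NIR absorbance spectra of naturally aged triploid
#' watermelon seeds: absorption bands near 4536, 4744, 4987, 5174, 5376 and
#' 6929 cm^-1 shared by both classes, class-discriminative bands at 4079,
#' 5261 and 7416 cm^-1, uniformly higher absorbance for nonviable seeds,
#' three varieties with distinct baselines, multiplicative scatter
#' artifacts, and a noisy information-free region above 9000 cm^-1.
#' Germination rates default to 87%/89%/84% for varieties V1/V2/V3.
#'
#' @param wnMin,wnMax,wnStep wavenumber grid in cm^-1 (default 4000-10000,
#'   step 4, i.e. 1501 points).
#' @param bandCenters,bandWidths Gaussian band centers and sigmas (cm^-1).
#' @param bandAmplitudesViable,bandAmplitudesNonviable band amplitudes
#'   (absorbance units) per class; they differ only at the bands listed in
#'   `discriminativeCenters`.
#' @param classOffset global additive absorbance excess of nonviable seeds
#'   (must be > 0 so nonviable spectra sit above viable ones everywhere).
#' @param discriminativeCenters wavenumbers whose amplitudes differ by class.
#' @param varietyOffsets,varietySlopes per-variety baseline offset
#'   (absorbance) and total baseline rise across the axis (absorbance).
#' @param scatterSlopeSd,scatterOffsetSd dispersions of the per-sample
#'   affine scatter transform (slope around 1, offset around 0).
#' @param baselineFlexSd amplitude SD (absorbance) of the per-sample smooth
#'   random baseline flex; `baselineFlexKnots` broad Gaussian components
#'   spread across the axis model wavelength-dependent scattering drift.
#' @param noiseSdBase,noiseSdTail additive noise SD (absorbance) below and
#'   at/above `tailStart`.
#' @param tailStart wavenumber (cm^-1) where the noisy tail begins.
#' @param germinationRates per-variety probability that a seed is viable.
#' @param rngSeed integer seed for reproducible simulation.
#'
#' @return a list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(
        wnMin = 4000, wnMax = 10000, wnStep = 4,
        bandCenters = c(4079, 4536, 4744, 4987, 5174, 5261, 5376, 6929, 7416),
        bandWidths = c(30, 70, 35, 60, 45, 30, 50, 160, 40),
        bandAmplitudesViable =
            c(0.100, 0.45, 0.20, 0.40, 0.32, 0.120, 0.30, 0.25, 0.080),
        bandAmplitudesNonviable =
            c(0.106, 0.45, 0.20, 0.40, 0.32, 0.126, 0.30, 0.25, 0.085),
        classOffset = 0.02,
        discriminativeCenters = c(4079, 5261, 7416),
        varietyOffsets = c(V1 = 0.40, V2 = 0.46, V3 = 0.52),
        varietySlopes = c(V1 = 0.00, V2 = 0.05, V3 = -0.04),
        scatterSlopeSd = 0.05, scatterOffsetSd = 0.02,
        baselineFlexSd = 0.04, baselineFlexKnots = 40L,
        noiseSdBase = 0.003, noiseSdTail = 0.03, tailStart = 9000,
        germinationRates = c(V1 = 0.87, V2 = 0.89, V3 = 0.84),
        rngSeed = 1L) {
    cfg <- list(
        wnMin = wnMin, wnMax = wnMax, wnStep = wnStep,
        bandCenters = bandCenters, bandWidths = bandWidths,
        bandAmplitudesViable = bandAmplitudesViable,
        bandAmplitudesNonviable = bandAmplitudesNonviable,
        classOffset = classOffset,
        discriminativeCenters = discriminativeCenters,
        varietyOffsets = varietyOffsets, varietySlopes = varietySlopes,
        scatterSlopeSd = scatterSlopeSd, scatterOffsetSd = scatterOffsetSd,
        baselineFlexSd = baselineFlexSd,
        baselineFlexKnots = as.integer(baselineFlexKnots),
        noiseSdBase = noiseSdBase, noiseSdTail = noiseSdTail,
        tailStart = tailStart,
        germinationRates = germinationRates, rngSeed = as.integer(rngSeed))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

#' Validate a simulation configuration
#' @param cfg a `SimulationConfig` (or plain list with the same fields).
#' @return the configuration, invisibly, or an error.
#' @export
validateSimulationConfig <- function(cfg) {
    if (cfg$wnMin >= cfg$wnMax) stop("wnMin must be < wnMax")
    if (cfg$wnStep <= 0) stop("wnStep must be > 0")
    nGrid <- (cfg$wnMax - cfg$wnMin) / cfg$wnStep
    if (abs(nGrid - round(nGrid)) > 1e-9)
        stop("grid length (wnMax - wnMin)/wnStep must be an integer")
    nb <- length(cfg$bandCenters)
    if (length(cfg$bandWidths) != nb ||
        length(cfg$bandAmplitudesViable) != nb ||
        length(cfg$bandAmplitudesNonviable) != nb)
        stop("band centers, widths and amplitudes must have equal length")
    if (any(cfg$bandAmplitudesViable < 0) ||
        any(cfg$bandAmplitudesNonviable < 0))
        stop("band amplitudes must be non-negative")
    if (any(cfg$bandWidths <= 0)) stop("band widths must be > 0")
    if (cfg$classOffset <= 0) stop("classOffset must be > 0")
    if (any(cfg$germinationRates < 0) || any(cfg$germinationRates > 1))
        stop("germination rates must lie in [0, 1]")
    if (length(cfg$varietyOffsets) != length(cfg$varietySlopes) ||
        length(cfg$varietyOffsets) != length(cfg$germinationRates))
        stop("variety parameter vectors must have equal length")
    invisible(cfg)
}

.wavenumberGrid <- function(cfg)
    seq(cfg$wnMin, cfg$wnMax, by = cfg$wnStep)

## Evaluate a seed with side-effect-free RNG: the caller's .Random.seed is
## saved and restored so simulation never perturbs user RNG state.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Deterministic noise-free class/variety template spectra on the grid.
.templateSpectrum <- function(cfg, wn, varietyIdx, viable) {
    amps <- if (viable) cfg$bandAmplitudesViable else cfg$bandAmplitudesNonviable
    s <- cfg$varietyOffsets[[varietyIdx]] +
        cfg$varietySlopes[[varietyIdx]] *
            (wn - cfg$wnMin) / (cfg$wnMax - cfg$wnMin)
    for (b in seq_along(cfg$bandCenters))
        s <- s + amps[b] *
            exp(-(wn - cfg$bandCenters[b])^2 / (2 * cfg$bandWidths[b]^2))
    if (!viable) s <- s + cfg$classOffset
    s
}

## Synthesize spectra for given variety indices and viability flags.
## Draw order is fixed (scatter offsets, scatter slopes, baseline-flex
## coefficients, then the noise matrix) so identical config + seed gives
## bit-identical output.
.synthesizeSpectra <- function(cfg, varietyIdx, viable) {
    wn <- .wavenumberGrid(cfg)
    n <- length(varietyIdx)
    offsets <- rnorm(n, 0, cfg$scatterOffsetSd)
    slopes <- rnorm(n, 1, cfg$scatterSlopeSd)
    nk <- cfg$baselineFlexKnots %||% 0L
    flex <- matrix(0, n, length(wn))
    if (nk > 0 && (cfg$baselineFlexSd %||% 0) > 0) {
        centers <- seq(cfg$wnMin, cfg$wnMax, length.out = nk)
        sigma <- (cfg$wnMax - cfg$wnMin) / nk
        basis <- vapply(centers,
                        function(m) exp(-(wn - m)^2 / (2 * sigma^2)),
                        numeric(length(wn)))
        coefs <- matrix(rnorm(n * nk, 0, cfg$baselineFlexSd), n, nk,
                        byrow = TRUE)
        flex <- coefs %*% t(basis)
    }
    noiseSd <- ifelse(wn >= cfg$tailStart, cfg$noiseSdTail, cfg$noiseSdBase)
    noise <- matrix(rnorm(n * length(wn)), n, length(wn), byrow = TRUE) *
        rep(noiseSd, each = n)
    X <- matrix(0, n, length(wn))
    for (i in seq_len(n)) {
        base <- .templateSpectrum(cfg, wn, varietyIdx[i], viable[i])
        X[i, ] <- offsets[i] + slopes[i] * base + flex[i, ] + noise[i, ]
    }
    X
}

#' Simulate a balanced labelled set of seed spectra
#'
#' Generates `nPerVarietyPerClass` seeds for every (variety, class)
#' combination, so the result is balanced by construction: with the default
#' three varieties the set holds `6 * nPerVarietyPerClass` spectra.
#' Identical configuration and seed give bit-identical output.
#'
#' @param config a [simulationConfig()].
#' @param nPerVarietyPerClass number of seeds per variety per class (>= 1).
#' @param seed optional integer overriding `config$rngSeed`.
#' @return a [SpectraSet-class].
#' @examples
#' s <- simulateSpectra(simulationConfig(), nPerVarietyPerClass = 5)
#' dim(absorbance(s))   # 30 x 1501
#' @export
simulateSpectra <- function(config, nPerVarietyPerClass, seed = NULL) {
    validateSimulationConfig(config)
    stopifnot(nPerVarietyPerClass >= 1)
    nv <- length(config$varietyOffsets)
    varietyNames <- names(config$varietyOffsets)
    if (is.null(varietyNames)) varietyNames <- paste0("V", seq_len(nv))
    varietyIdx <- rep(seq_len(nv), each = 2 * nPerVarietyPerClass)
    viable <- rep(rep(c(TRUE, FALSE), each = nPerVarietyPerClass), nv)
    X <- .withSeed(if (is.null(seed)) config$rngSeed else seed,
                   .synthesizeSpectra(config, varietyIdx, viable))
    SpectraSet(X, wavenumbers = .wavenumberGrid(config),
               sampleIds = sprintf("seed%04d", seq_len(nrow(X))),
               variety = varietyNames[varietyIdx],
               label = ifelse(viable, "viable", "nonviable"))
}

#' Simulate an unbalanced field lot of seeds
#'
#' Draws each seed's viability from its variety's germination rate
#' (Bernoulli), then synthesizes the spectrum — emulating a mixed lot of
#' stored seeds as used for an external test of a trained model.
#'
#' @inheritParams simulateSpectra
#' @param nPerVariety number of seeds drawn from each variety (>= 1).
#' @return a [SpectraSet-class] with labels reflecting the Bernoulli draws.
#' @export
simulateLabelledLot <- function(config, nPerVariety, seed = NULL) {
    validateSimulationConfig(config)
    stopifnot(nPerVariety >= 1)
    nv <- length(config$varietyOffsets)
    varietyNames <- names(config$varietyOffsets)
    if (is.null(varietyNames)) varietyNames <- paste0("V", seq_len(nv))
    varietyIdx <- rep(seq_len(nv), each = nPerVariety)
    res <- .withSeed(if (is.null(seed)) config$rngSeed else seed, {
        viable <- rbinom(length(varietyIdx), 1,
                         config$germinationRates[varietyIdx]) == 1
        list(viable = viable,
             X = .synthesizeSpectra(config, varietyIdx, viable))
    })
    SpectraSet(res$X, wavenumbers = .wavenumberGrid(config),
               sampleIds = sprintf("lot%04d", seq_len(nrow(res$X))),
               variety = varietyNames[varietyIdx],
               label = ifelse(res$viable, "viable", "nonviable"))
}

#' Read a simulation configuration from a YAML file
#'
#' The file is a flat mapping whose keys mirror the arguments of
#' [simulationConfig()]; omitted keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a `SimulationConfig`.
#' @export
readSimulationConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(simulationConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown simulation config keys: ", paste(bad, collapse = ", "))
    do.call(simulationConfig, lapply(vals, unlist))
}
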
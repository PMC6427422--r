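# Small fixtures built in code.

# A coarse-grid configuration for tests where the spectral detail is
# irrelevant (label bookkeeping, splitting, I/O): 51 grid points.
coarseConfig <- function(...) {
    simulationConfig(
        wnMin = 4000, wnMax = 4400, wnStep = 8,
        bandCenters = c(4079, 4200, 4300),
        bandWidths = c(25, 40, 30),
        bandAmplitudesViable = c(0.10, 0.30, 0.20),
        bandAmplitudesNonviable = c(0.14, 0.30, 0.24),
        discriminativeCenters = c(4079, 4300),
        classOffset = 0.02,
        ...)
}

# Noise- and scatter-free configuration (deterministic spectra).
cleanConfig <- function(...) {
    coarseConfig(scatterSlopeSd = 0, scatterOffsetSd = 0,
                 baselineFlexSd = 0, noiseSdBase = 0, noiseSdTail = 0, ...)
}

# Tiny labelled SpectraSet with arbitrary values.
toySet <- function(n = 3, p = 5, seed = 42) {
    set.seed(seed)
    SpectraSet(matrix(rnorm(n * p), n, p),
               wavenumbers = seq(4000, by = 4, length.out = p),
               sampleIds = paste0("s", seq_len(n)),
               variety = rep_len(c("V1", "V2", "V3"), n),
               label = rep_len(c("viable", "nonviable", "unknown"), n))
}

# Random two-class data with a linear class signal, for PLS fits.
randomClassData <- function(n = 24, p = 8, seed = 1, sep = 2) {
    set.seed(seed)
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + sep * y
    list(X = X, y = y)
}
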
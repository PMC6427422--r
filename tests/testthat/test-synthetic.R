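test_that("grid arithmetic gives the expected spectra dimensions", {
    s <- simulateSpectra(simulationConfig(), nPerVarietyPerClass = 10)
    expect_identical(dim(absorbance(s)), c(60L, 1501L))
    expect_equal(wavenumbers(s)[1], 4000)
    expect_equal(tail(wavenumbers(s), 1), 10000)
    expect_setequal(unique(variety(s)), c("V1", "V2", "V3"))
    expect_equal(sum(viabilityLabel(s) == "viable"), 30)
})

test_that("a non-integer grid or negative amplitude is a configuration error", {
    expect_error(simulationConfig(wnMax = 10001), "integer")
    expect_error(simulationConfig(
        bandAmplitudesViable = c(-0.1, 0.45, 0.20, 0.40, 0.32, 0.12,
                                 0.30, 0.25, 0.08)),
        "non-negative")
    expect_error(simulationConfig(classOffset = 0), "classOffset")
    expect_error(simulationConfig(germinationRates = c(0.9, 1.2, 0.8)),
                 "germination")
})

test_that("noise-free class-mean difference at discriminative centers equals the configured delta plus class offset", {
    ## band centers on grid points so the construction is exact there
    cfg <- simulationConfig(
        wnMin = 4000, wnMax = 4400, wnStep = 8,
        bandCenters = c(4080, 4200, 4304),
        bandWidths = c(25, 40, 30),
        bandAmplitudesViable = c(0.10, 0.30, 0.20),
        bandAmplitudesNonviable = c(0.14, 0.30, 0.24),
        discriminativeCenters = c(4080, 4304),
        classOffset = 0.02,
        scatterSlopeSd = 0, scatterOffsetSd = 0, baselineFlexSd = 0,
        noiseSdBase = 0, noiseSdTail = 0)
    s <- simulateSpectra(cfg, nPerVarietyPerClass = 4)
    A <- absorbance(s)
    code <- classCode(s)
    diffSpec <- colMeans(A[code == 0, ]) - colMeans(A[code == 1, ])
    wn <- wavenumbers(s)
    for (ctr in cfg$discriminativeCenters) {
        j <- which.min(abs(wn - ctr))
        b <- which(cfg$bandCenters == ctr)
        delta <- cfg$bandAmplitudesNonviable[b] - cfg$bandAmplitudesViable[b]
        expect_equal(diffSpec[j], delta + cfg$classOffset, tolerance = 1e-8)
    }
    ## ordering holds at every wavenumber when noise is off
    expect_true(all(diffSpec > 0))
})

test_that("simulation is bit-identical under a fixed seed and differs across seeds", {
    cfg <- simulationConfig()
    a <- absorbance(simulateSpectra(cfg, 5))
    b <- absorbance(simulateSpectra(cfg, 5))
    c <- absorbance(simulateSpectra(cfg, 5, seed = 2))
    expect_identical(a, b)
    expect_false(identical(a, c))
    l1 <- absorbance(simulateLabelledLot(cfg, 5))
    l2 <- absorbance(simulateLabelledLot(cfg, 5))
    expect_identical(l1, l2)
})

test_that("simulation does not disturb the caller's RNG stream", {
    set.seed(123)
    r1 <- rnorm(3)
    set.seed(123)
    invisible(simulateSpectra(coarseConfig(), 3))
    r2 <- rnorm(3)
    expect_identical(r1, r2)
})

test_that("labelled lots follow the per-variety germination rates", {
    expect_true(all(viabilityLabel(
        simulateLabelledLot(coarseConfig(germinationRates = c(1, 1, 1)), 20))
        == "viable"))
    expect_true(all(viabilityLabel(
        simulateLabelledLot(coarseConfig(germinationRates = c(0, 0, 0)), 20))
        == "nonviable"))
    n <- 10000
    lot <- simulateLabelledLot(coarseConfig(), nPerVariety = n, seed = 11)
    rates <- c(V1 = 0.87, V2 = 0.89, V3 = 0.84)
    for (v in names(rates)) {
        frac <- mean(viabilityLabel(lot)[variety(lot) == v] == "viable")
        sdBin <- sqrt(rates[[v]] * (1 - rates[[v]]) / n)
        expect_lt(abs(frac - rates[[v]]), 3 * sdBin)
    }
})

test_that("the tail region is noisier than the informative region", {
    cfg <- simulationConfig(scatterSlopeSd = 0, scatterOffsetSd = 0,
                            baselineFlexSd = 0)
    s <- simulateSpectra(cfg, nPerVarietyPerClass = 20)  # 120 spectra
    A <- absorbance(s)
    wn <- wavenumbers(s)
    ## within-group residual variance per channel (class x variety groups)
    groups <- interaction(variety(s), viabilityLabel(s))
    resid <- A
    for (g in levels(groups)) {
        idx <- groups == g
        resid[idx, ] <- sweep(A[idx, , drop = FALSE], 2,
                              colMeans(A[idx, , drop = FALSE]))
    }
    vTail <- mean(apply(resid[, wn >= 9000], 2, var))
    vBase <- mean(apply(resid[, wn < 9000], 2, var))
    expect_gt(vTail, 10 * vBase)
})

test_that("spectra tables round-trip exactly through CSV", {
    s <- toySet()
    path <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(s, path)
    r <- readSpectra(path)
    expect_identical(absorbance(r), absorbance(s))
    expect_identical(wavenumbers(r), wavenumbers(s))
    expect_identical(sampleIds(r), sampleIds(s))
    expect_identical(variety(r), variety(s))
    expect_identical(viabilityLabel(r), viabilityLabel(s))
})

test_that("readers canonicalize shuffled wavenumber columns and accept unknown labels", {
    s <- toySet()
    path <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(s, path)
    df <- read.csv(path, check.names = FALSE)
    shuffle <- c(1:3, 3 + sample(ncol(df) - 3))
    write.csv(df[, shuffle], path, row.names = FALSE, quote = FALSE)
    r <- readSpectra(path)
    expect_identical(wavenumbers(r), wavenumbers(s))
    expect_equal(absorbance(r), absorbance(s), tolerance = 1e-12)
    ## 'unknown' labels are legal and give an NA class code
    expect_true("unknown" %in% viabilityLabel(r))
    expect_true(anyNA(classCode(r)))
})

test_that("malformed spectra tables are rejected", {
    s <- toySet()
    path <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(s, path)
    df <- read.csv(path, check.names = FALSE)
    colnames(df)[4] <- "notanumber"
    bad <- withr::local_tempfile(fileext = ".csv")
    write.csv(df, bad, row.names = FALSE, quote = FALSE)
    expect_error(readSpectra(bad), "non-numeric wavenumber")
    df <- read.csv(path, check.names = FALSE)
    df$sample_id <- rep("dup", nrow(df))
    write.csv(df, bad, row.names = FALSE, quote = FALSE)
    expect_error(readSpectra(bad), "duplicate sample ids")
    df <- read.csv(path, check.names = FALSE)
    df$label[1] <- "maybe"
    write.csv(df, bad, row.names = FALSE, quote = FALSE)
    expect_error(readSpectra(bad), "invalid label")
})

test_that("SpectraSet validity enforces the axis and metadata invariants", {
    expect_error(SpectraSet(matrix(1:6, 2, 3), c(4000, 4004, 4004),
                            c("a", "b")), "strictly increasing")
    expect_error(SpectraSet(matrix(1:6, 2, 3), c(4000, 4004, 4012),
                            c("a", "b")), "uniform")
    expect_error(SpectraSet(matrix(c(1, NA, 3, 4, 5, 6), 2, 3),
                            c(4000, 4004, 4008), c("a", "b")), "finite")
    expect_error(SpectraSet(matrix(1:6, 2, 3), c(4000, 4004, 4008),
                            c("a", "a")), "unique")
    expect_error(SpectraSet(matrix(1:6, 2, 3), c(4000, 4004, 4008),
                            c("a", "b"), label = c("viable", "dead")),
                 "label")
})

test_that("simulation configs round-trip through YAML", {
    cfg <- coarseConfig(noiseSdBase = 0.004)
    path <- withr::local_tempfile(fileext = ".yml")
    yaml::write_yaml(unclass(cfg), path)
    cfg2 <- readSimulationConfig(path)
    expect_equal(cfg2$bandCenters, cfg$bandCenters)
    expect_equal(cfg2$noiseSdBase, 0.004)
    expect_identical(absorbance(simulateSpectra(cfg, 3)),
                     absorbance(simulateSpectra(cfg2, 3)))
})
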
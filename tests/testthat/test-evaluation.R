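test_that("stratified splits reproduce the per-variety and pooled partition sizes", {
    cfg <- coarseConfig()
    s <- simulateSpectra(cfg, nPerVarietyPerClass = 124)  # 744 samples
    ## single-variety subset: 248 seeds, 124 per class
    v1 <- s[, variety(s) == "V1"]
    sp <- stratifiedSplit(v1, validationCounts = 37, seed = 4)
    expect_equal(table(viabilityLabel(sp$calibration))[["viable"]], 87)
    expect_equal(table(viabilityLabel(sp$calibration))[["nonviable"]], 87)
    expect_equal(table(viabilityLabel(sp$validation))[["viable"]], 37)
    expect_equal(table(viabilityLabel(sp$validation))[["nonviable"]], 37)
    ## pooled three-variety set: 744 -> 520 + 224
    sp2 <- stratifiedSplit(s, validationCounts = 112, seed = 4)
    expect_equal(ncol(sp2$calibration), 520L)
    expect_equal(ncol(sp2$validation), 224L)
    expect_equal(sum(viabilityLabel(sp2$calibration) == "viable"), 260)
    expect_equal(sum(viabilityLabel(sp2$validation) == "nonviable"), 112)
    ## calibration and validation are disjoint and exhaustive
    expect_length(intersect(sampleIds(sp2$calibration),
                            sampleIds(sp2$validation)), 0)
    expect_setequal(c(sampleIds(sp2$calibration),
                      sampleIds(sp2$validation)), sampleIds(s))
})

test_that("split edge cases behave as documented", {
    s <- simulateSpectra(coarseConfig(), 6)
    sp <- stratifiedSplit(s, validationFraction = 0, seed = 1)
    expect_equal(ncol(sp$validation), 0L)
    expect_equal(ncol(sp$calibration), ncol(s))
    expect_error(stratifiedSplit(s, validationCounts = 1000, seed = 1),
                 "only")
    expect_error(stratifiedSplit(s, seed = 1), "validationFraction")
    ## reproducible under the same seed, different under another
    a <- stratifiedSplit(s, validationFraction = 0.3, seed = 7)
    b <- stratifiedSplit(s, validationFraction = 0.3, seed = 7)
    c <- stratifiedSplit(s, validationFraction = 0.3, seed = 8)
    expect_identical(sampleIds(a$validation), sampleIds(b$validation))
    expect_false(identical(sampleIds(a$validation),
                           sampleIds(c$validation)))
})

test_that("confusion counts follow the viable-positive convention", {
    ## perfect prediction
    truth <- c(rep(1, 6), rep(0, 4))
    r <- evaluateClassification(truth, truth)
    expect_equal(unname(confusionCounts(r)), c(6L, 0L, 0L, 4L))
    ## everything called viable
    truth2 <- c(rep(1, 49), rep(0, 51))
    r2 <- evaluateClassification(truth2, rep(1, 100))
    expect_equal(unname(confusionCounts(r2)), c(49L, 0L, 51L, 0L))
    ## the external-test scenario: 43/49 viable and 42/51 nonviable correct
    pred <- c(rep(1, 43), rep(0, 6), rep(1, 9), rep(0, 42))
    r3 <- evaluateClassification(truth2, pred)
    expect_equal(unname(confusionCounts(r3)), c(43L, 6L, 9L, 42L))
})

test_that("metrics match their definitions and identities", {
    m <- classificationMetrics(tp = 43, fn = 6, fp = 9, tn = 42)
    expect_equal(unname(m["sensitivity"]), 43 / 49, tolerance = 1e-12)
    expect_equal(unname(m["specificity"]), 42 / 51, tolerance = 1e-12)
    expect_equal(unname(m["ner"]), (43 / 49 + 42 / 51) / 2,
                 tolerance = 1e-12)
    expect_equal(unname(m["er"] + m["ner"]), 1, tolerance = 1e-12)
    expect_equal(unname(m["prec"]), 43 / 52, tolerance = 1e-12)
    expect_equal(unname(m["fpr"]), 9 / 51, tolerance = 1e-12)
    ## on this near-balanced set NER and overall accuracy agree at rounding
    expect_equal(round(unname(m["ner"]), 2), round(unname(m["accuracy"]), 2))
    ## perfect and degenerate confusion matrices
    p <- classificationMetrics(10, 0, 0, 10)
    expect_equal(unname(p[c("sensitivity", "specificity", "ner", "prec")]),
                 rep(1, 4))
    expect_equal(unname(p[c("er", "fpr")]), c(0, 0))
    d <- classificationMetrics(0, 5, 0, 5)
    expect_true(is.na(d["prec"]))
    expect_false(anyNA(d[c("sensitivity", "specificity")]))
})

test_that("ROC analysis matches the brute-force concordance oracle", {
    ## perfectly separated scores
    truth <- c(rep(0, 5), rep(1, 5))
    sep <- c(rnorm(5, -3, 0.1), rnorm(5, 3, 0.1))
    r <- rocCurve(sep, truth)
    expect_equal(r$auc, 1.0)
    expect_true(any(r$points$sensitivity == 1 & r$points$specificity == 1))
    ## random scores: AUC near 1/2, and equal to pairwise concordance
    set.seed(29)
    for (i in 1:5) {
        yhat <- rnorm(60)
        truth <- rbinom(60, 1, 0.5)
        if (length(unique(truth)) < 2) truth[1] <- 1 - truth[1]
        r <- rocCurve(yhat, truth)
        expect_equal(r$auc, aucBruteForce(yhat, truth), tolerance = 1e-10)
    }
    set.seed(31)
    yhat <- rnorm(2000); truth <- rbinom(2000, 1, 0.5)
    expect_lt(abs(rocCurve(yhat, truth)$auc - 0.5), 0.05)
})

test_that("ROC sweep is monotone and AUC is invariant under monotone transforms", {
    set.seed(33)
    yhat <- rnorm(80); truth <- rbinom(80, 1, 0.6)
    r <- rocCurve(yhat, truth)
    expect_true(all(diff(r$points$sensitivity) <= 0))
    expect_true(all(diff(r$points$specificity) >= 0))
    r2 <- rocCurve(exp(2 * yhat + 1), truth)
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
    expect_error(rocCurve(yhat, rep(1, 80)), "both classes")
})

test_that("the sensitivity/specificity crossing threshold balances the two rates", {
    set.seed(35)
    yhat <- c(rnorm(100, 0, 0.3), rnorm(100, 1, 0.3))
    truth <- rep(c(0, 1), each = 100)
    r <- rocCurve(yhat, truth)
    thr <- r$crossingThreshold
    sens <- mean(yhat[truth == 1] >= thr)
    spec <- mean(yhat[truth == 0] < thr)
    expect_lt(abs(sens - spec), 0.05)
    expect_gt(thr, 0.2); expect_lt(thr, 0.8)
})

test_that("evaluation reports tie counts, metrics and ROC together", {
    set.seed(37)
    yhat <- c(rnorm(40, 0.2, 0.25), rnorm(40, 0.8, 0.25))
    truth <- rep(c(0, 1), each = 40)
    r <- evaluateClassification(truth, yhat = yhat, threshold = 0.5)
    cc <- confusionCounts(r)
    expect_equal(sum(cc), 80)
    expect_equal(unname(r@metrics["accuracy"]),
                 unname((cc["tp"] + cc["tn"]) / 80))
    expect_equal(r@auc, aucBruteForce(yhat, truth), tolerance = 1e-10)
    expect_error(evaluateClassification(integer(0), integer(0)), "empty")
})
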
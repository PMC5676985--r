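test_that("stratified split hits the target fraction and covers the range", {
    d <- CalibrationDataset(dl = runif(100, 6000, 9000),
                            tc = runif(100, 5, 31),
                            tbb = rep(seq(5, 50, 5), each = 10))
    s <- splitDataset(d, SplitSpec(fraction = 0.65, seed = 1))
    expect_equal(sum(splitLabels(s) == "calibration"), 65L)
    tab <- table(calRecords(s)$tbb, splitLabels(s))
    expect_true(all(tab > 0))   # every setpoint in both subsets

    s2 <- splitDataset(d, SplitSpec(fraction = 0.65, seed = 1))
    expect_identical(splitLabels(s), splitLabels(s2))

    ## 266 records over uneven bins
    set.seed(2)
    tbb <- sample(seq(5, 65, 5), 266, replace = TRUE)
    d2 <- CalibrationDataset(dl = runif(266, 6000, 9000),
                             tc = runif(266, 5, 31), tbb = tbb)
    s3 <- splitDataset(d2, SplitSpec(seed = 3))
    nc <- sum(splitLabels(s3) == "calibration")
    expect_true(nc %in% 172:174)
    expect_equal(range(subsetByLabel(s3, "calibration")@records$tbb),
                 range(tbb))
    expect_equal(range(subsetByLabel(s3, "validation")@records$tbb),
                 range(tbb))

    ## singleton bin goes to calibration with a warning
    d4 <- CalibrationDataset(dl = runif(7, 10, 100), tc = runif(7, 5, 31),
                             tbb = c(rep(10, 3), rep(20, 3), 30))
    expect_warning(s4 <- splitDataset(d4, SplitSpec(seed = 1)),
                   "single record")
    expect_equal(splitLabels(s4)[7], "calibration")
})

test_that("polynomial fits interpolate exact models and match the oracle", {
    ## noiseless P1 plane
    set.seed(3)
    dl <- runif(8, 500, 3000); tc <- runif(8, 5, 30)
    d <- CalibrationDataset(dl = dl, tc = tc,
                            tbb = 1 + 0.001 * dl + 0.5 * tc)
    m <- fitPolynomial(d, "P1")
    expect_equal(unname(coef(m)), c(1, 0.001, 0.5), tolerance = 1e-8)

    ## P2 on 12 random records equals a normal-equations solve
    set.seed(4)
    dl <- runif(12, 10, 100); tc <- runif(12, 5, 31)
    tbb <- runif(12, 5, 65)
    d2 <- CalibrationDataset(dl = dl, tc = tc, tbb = tbb)
    m2 <- fitPolynomial(d2, "P2")
    X <- cbind(1, dl, tc, dl^2, dl * tc, tc^2)
    expect_equal(unname(coef(m2)), unname(neSolve(X, tbb)), tolerance = 1e-6)

    ## rank deficiency raises a singular-fit error naming the terms
    d3 <- CalibrationDataset(dl = c(100, 200, 300), tc = rep(20, 3),
                             tbb = c(10, 20, 30))
    expect_error(fitPolynomial(d3, "P1"), "singular.*p01")
})

test_that("polynomial predictions evaluate the term list", {
    m <- new("PolynomialModel", form = "P1",
             coefficients = c(p00 = 1, p10 = 0.001, p01 = 0.5))
    expect_equal(predictTemperature(m, 1000, 20), 12)

    m2 <- new("PolynomialModel", form = "P2",
              coefficients = c(p00 = 7, p10 = 0, p01 = 0, p20 = 0,
                               p11 = 0, p02 = 0))
    expect_equal(predictTemperature(m2, c(0, 5e3, 6e4), c(-10, 0, 50)),
                 rep(7, 3))
    expect_error(predictTemperature(m, NaN, 20), "finite")

    ## residuals on calibration points match term-by-term recomputation
    d <- simulateBlackbodyCampaign(SensorSimConfig(seed = 5))
    fit <- fitPolynomial(d, "P2")
    rec <- calRecords(d)
    cf <- coef(fit)
    byHand <- cf["p00"] + cf["p10"] * rec$dl + cf["p01"] * rec$tc +
        cf["p20"] * rec$dl^2 + cf["p11"] * rec$dl * rec$tc +
        cf["p02"] * rec$tc^2
    expect_equal(rec$tbb - predictTemperature(fit, rec$dl, rec$tc),
                 unname(rec$tbb - byHand), tolerance = 1e-9)
})

test_that("training RMSE is non-increasing along the nested forms", {
    d <- splitDataset(simulateBlackbodyCampaign(SensorSimConfig(seed = 8)),
                      SplitSpec(seed = 8))
    cal <- subsetByLabel(d, "calibration")@records
    rmses <- vapply(c("P1", "P2", "P3", "P4"), function(f) {
        m <- fitPolynomial(d, f)
        rmse(cal$tbb, predictTemperature(m, cal$dl, cal$tc))
    }, numeric(1))
    expect_true(all(diff(rmses) <= 1e-9))
})

test_that("an exact quadratic sensor is recovered to coefficient level", {
    g <- expand.grid(dl = seq(6000, 9500, length.out = 14),
                     tc = seq(5, 31, length.out = 10))
    truth <- c(p00 = -60, p10 = 0.012, p01 = 0.2, p20 = 1e-7,
               p11 = 1e-5, p02 = 0.01)
    tbb <- truth["p00"] + truth["p10"] * g$dl + truth["p01"] * g$tc +
        truth["p20"] * g$dl^2 + truth["p11"] * g$dl * g$tc +
        truth["p02"] * g$tc^2
    d <- CalibrationDataset(dl = g$dl, tc = g$tc, tbb = tbb)
    d <- suppressWarnings(splitDataset(d, SplitSpec(seed = 2)))
    m <- fitPolynomial(d, "P2")
    expect_equal(coef(m), truth, tolerance = 1e-6)
    val <- subsetByLabel(d, "validation")@records
    expect_lt(rmse(val$tbb, predictTemperature(m, val$dl, val$tc)), 1e-6)
})

test_that("applyModel calibrates frames pixel by pixel", {
    m <- new("PolynomialModel", form = "P1",
             coefficients = c(p00 = 0, p10 = 0.001, p01 = 0.1))
    fr <- ThermalFrame(matrix(5000, 4, 4), 20, "c")
    map <- applyModel(fr, m)
    expect_equal(temps(map), matrix(7, 4, 4))
    expect_match(map@provenance, "P1:c")

    big <- ThermalFrame(matrix(7000, 640, 512), 22, "big")
    expect_equal(dim(temps(applyModel(big, m))), c(640, 512))

    set.seed(6)
    px <- matrix(runif(48, 6000, 9000), 8)
    fr2 <- ThermalFrame(px, 24, "r")
    map2 <- applyModel(fr2, m)
    byPixel <- matrix(0, 8, 6)
    for (i in 1:8) for (j in 1:6)
        byPixel[i, j] <- predictTemperature(m, px[i, j], 24)
    expect_equal(temps(map2), byPixel, tolerance = 1e-9)
})

test_that("models serialize to JSON and back without changing predictions", {
    d <- splitDataset(simulateBlackbodyCampaign(SensorSimConfig(seed = 9)),
                      SplitSpec(seed = 9))
    f <- withr::local_tempfile(fileext = ".json")

    p2 <- fitPolynomial(d, "P2")
    saveModel(p2, f)
    expect_equal(coef(loadModel(f)), coef(p2))

    ann <- trainAnn(d, AnnTrainConfig(seed = 9, maxEpochs = 300L))
    saveModel(ann, f)
    back <- loadModel(f)
    set.seed(10)
    dl <- runif(100, 6000, 9500); tc <- runif(100, 5, 31)
    expect_equal(predictTemperature(back, dl, tc),
                 predictTemperature(ann, dl, tc), tolerance = 1e-12)

    writeLines('{"form": "P9", "coefficients": {}}', f)
    expect_error(loadModel(f), "unknown model form")
    writeLines("{not json", f)
    expect_error(loadModel(f), "not a valid model JSON")
})
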
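test_that("rmse matches hand arithmetic and conserves squared error", {
    expect_equal(rmse(c(5, 6, 7), c(5, 6, 7)), 0)
    expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
    expect_error(rmse(1:3, 1:4), "equal length")

    set.seed(1)
    o <- rnorm(50, 30, 5); s <- o + rnorm(50)
    expect_equal(rmse(o, s)^2 * 50, sum((s - o)^2), tolerance = 1e-12)
})

test_that("rSquared is the squared correlation of the pairing", {
    o <- c(20, 25, 30, 35)
    expect_equal(rSquared(o, o), 1)
    expect_equal(rSquared(o, 2 * o + 3), 1)
    set.seed(2)
    a <- rnorm(40); b <- a + rnorm(40)
    expect_equal(rSquared(a, b), directR2(a, b), tolerance = 1e-12)
    expect_error(rSquared(o, rep(1, 4)), "zero variance")
})

test_that("relative error scales rmse by the observed mean", {
    expect_equal(relativeError(0, 25), 0)
    expect_equal(relativeError(2, 40), 5)
    expect_error(relativeError(1, 0), "zero")
})

test_that("similarity index behaves like an agreement measure", {
    o <- c(20, 25, 30, 35)
    expect_equal(similarityIndex(o, o), 1)
    expect_equal(similarityIndex(o, rep(mean(o), 4)), 0)
    set.seed(3)
    a <- rnorm(30, 30, 4); b <- a + rnorm(30)
    expect_equal(similarityIndex(a, b), directSI(a, b), tolerance = 1e-12)

    ## literal (signed) variant differs in general but both are <= 1
    expect_lte(similarityIndex(a, b, literal = TRUE), 1)

    ## monotonicity: inflating one residual lowers the index
    b2 <- b; b2[5] <- b2[5] + 3 * sign(b2[5] - a[5] + 1e-9)
    expect_lt(similarityIndex(a, b2), similarityIndex(a, b))
})

test_that("fitReport bundles the individual statistics consistently", {
    set.seed(4)
    o <- rnorm(25, 30, 5); s <- o + rnorm(25, 0, 1.5)
    rep <- fitReport(o, s)
    expect_equal(rep@rmse, rmse(o, s))
    expect_equal(rep@r2, rSquared(o, s))
    expect_equal(rep@relativeError, relativeError(rmse(o, s), mean(o)))
    expect_equal(rep@similarityIndex, similarityIndex(o, s))
    expect_equal(rep@residuals, s - o)

    perfect <- fitReport(o, o)
    expect_equal(perfect@r2, 1)
    expect_equal(perfect@rmse, 0)
    expect_equal(perfect@relativeError, 0)
    expect_equal(perfect@similarityIndex, 1)
})

test_that("normality test is calibrated on truly normal residuals", {
    rejections <- sum(vapply(1:50, function(s) {
        set.seed(s)
        sim <- runif(200, 10, 50)
        obs <- 2 + 0.95 * sim + rnorm(200, 0, 1.2)
        residualDiagnostics(obs, sim)@normalityP < 0.05
    }, logical(1)))
    expect_lte(rejections, 10)
})

test_that("heteroscedastic residuals are detected with high power", {
    detections <- sum(vapply(1:50, function(s) {
        set.seed(100 + s)
        sim <- runif(200, 10, 50)
        obs <- 2 + 0.95 * sim + rnorm(200, 0, 0.15 * sim)
        residualDiagnostics(obs, sim)@homoscedasticityP < 0.05
    }, logical(1)))
    expect_gte(detections, 45)
})

test_that("a gross outlier is flagged by Cook's distance", {
    sim <- seq(10, 50, length.out = 30)
    obs <- 1 + 0.9 * sim
    obs[17] <- obs[17] + 25
    diag <- residualDiagnostics(obs, sim)
    expect_true(17L %in% diag@outlierFlags)
    expect_equal(length(diag@cooksDistances), 30L)
    expect_true(all(diag@cooksDistances >= 0))
    expect_error(residualDiagnostics(obs, rep(3, 30)), "constant")
})

test_that("sensor-temperature bias shows in residuals until calibrated", {
    ## a DL-only mapping leaves residuals correlated with the sensor
    ## temperature; the bivariate quadratic model removes the pattern
    d <- splitDataset(simulateBlackbodyCampaign(SensorSimConfig(seed = 12)),
                      SplitSpec(seed = 12))
    val <- subsetByLabel(d, "validation")@records
    mfg <- fitPolynomial(d, "LINEAR_DL")
    res0 <- predictTemperature(mfg, val$dl, val$tc) - val$tbb
    expect_gt(abs(cor(res0, val$tc)), 0.5)

    p2 <- fitPolynomial(d, "P2")
    res2 <- predictTemperature(p2, val$dl, val$tc) - val$tbb
    expect_lt(abs(cor(res2, val$tc)), 0.2)
})
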
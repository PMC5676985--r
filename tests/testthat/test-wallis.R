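test_that("percentile stretch maps the distribution to the working range", {
    expect_equal(percentileStretch(matrix(500, 8, 8)),
                 matrix(127, 8, 8))

    two <- matrix(rep(c(100, 200), each = 32), 8)
    expect_setequal(unique(as.numeric(percentileStretch(two, 0, 100))),
                    c(0, 255))

    set.seed(5)
    img <- matrix(runif(64 * 64, 7000, 7400), 64)
    st <- percentileStretch(img, 2, 98)
    q <- quantile(img, c(0.02, 0.98), names = FALSE)
    expect_lte(abs(st[which.min(abs(img - q[1]))[1]] - 0), 1)
    expect_lte(abs(st[which.min(abs(img - q[2]))[1]] - 255), 1)
    expect_error(percentileStretch(img, 60, 40), "below")
})

test_that("local statistics equal hand values and the loop oracle", {
    cst <- localStats(matrix(9, 6, 6), 3)
    expect_equal(cst$mean, matrix(9, 6, 6))
    expect_equal(cst$sd, matrix(0, 6, 6))

    m5 <- matrix(1:25, 5, 5)
    ls <- localStats(m5, 3)
    v <- as.numeric(m5[2:4, 2:4])      # window around the (3, 3) pixel
    expect_equal(ls$mean[3, 3], mean(v))
    expect_equal(ls$sd[3, 3], sqrt(mean((v - mean(v))^2)))

    set.seed(6)
    img <- matrix(runif(32 * 32, 0, 255), 32)
    for (w in c(3, 7)) {
        got <- localStats(img, w)
        want <- loopLocalStats(img, w)
        expect_lt(max(abs(got$mean - want$mean)), 1e-9)
        expect_lt(max(abs(got$sd - want$sd)), 1e-9)
    }
    expect_error(localStats(img, 4), "odd")
    expect_error(localStats(img, 33), "larger")
})

test_that("the Wallis transform matches the direct formula", {
    p <- WallisParams(window = 5L)
    const <- wallis(matrix(40, 8, 8), p)
    expect_equal(const,
                 matrix(round(0.9 * 127 + 0.1 * 40), 8, 8))

    set.seed(7)
    toy <- matrix(round(runif(25, 0, 255)), 5)
    p1 <- WallisParams(window = 3L, contrast = 1, brightness = 1)
    got <- wallis(toy, p1)
    ls <- loopLocalStats(toy, 3)
    want <- loopWallis(toy, ls$mean, ls$sd, p1@targetMean, p1@targetStd,
                       1, 1, p1@epsilon)
    expect_lt(max(abs(got - want)), 0.51)

    ## full oracle equivalence on an 8x8 instance with the defaults
    img8 <- matrix(round(runif(64, 0, 255)), 8)
    p3 <- WallisParams(window = 5L)
    ls8 <- loopLocalStats(img8, 5)
    expect_lt(max(abs(wallis(img8, p3) -
                      loopWallis(img8, ls8$mean, ls8$sd, p3@targetMean,
                                 p3@targetStd, p3@contrast, p3@brightness,
                                 p3@epsilon))), 0.51)
})

test_that("filtering lifts the contrast of low-contrast scenes", {
    ## point-like hot targets compress the display dynamic to a few levels;
    ## the stretch-plus-Wallis pipeline restores local contrast
    sds <- vapply(2:4, function(s) {
        cfg <- SceneSimConfig(seed = s, smoothAmplitude = 8,
                              vignettingStrength = 8, textureAmplitude = 8,
                              hotspotSigma = 0.8)
        pr <- simulateScenePair(cfg)
        disp <- percentileStretch(pixelMatrix(pr$a), 0, 100)
        out <- wallis(percentileStretch(pixelMatrix(pr$a)))
        c(sd(disp), sd(out))
    }, numeric(2))
    expect_true(all(sds[1, ] < 10))           # the low-contrast regime
    expect_true(all(sds[2, ] >= 5 * sds[1, ]))

    ## monotone contrast: under-target scenes gain global SD
    pr <- simulateScenePair(SceneSimConfig(seed = 3))
    w0 <- percentileStretch(pixelMatrix(pr$a), 0, 100)
    expect_lt(sd(w0), WallisParams()@targetStd)
    expect_gt(sd(wallis(w0)), sd(w0))

    ## second application changes the image less than the first
    w1 <- wallis(w0); w2 <- wallis(w1)
    expect_lt(mean(abs(w2 - w1)), mean(abs(w1 - w0)))
})

test_that("batch filtering records a manifest and survives bad inputs", {
    frames <- lapply(1:3, function(s)
        simulateScenePair(SceneSimConfig(seed = s))$a)
    res <- wallisBatch(frames, WallisParams())
    expect_equal(nrow(res$manifest), 3L)
    expect_true(all(res$manifest$status == "ok"))
    for (k in 1:3) {
        w <- percentileStretch(pixelMatrix(frames[[k]]), 2, 98)
        expect_equal(res$manifest$mean_before[k], mean(w))
        expect_equal(res$manifest$sd_after[k], sd(res$images[[k]]))
    }

    res2 <- wallisBatch(list(frames[[1]], "no/such/file.tif"))
    expect_equal(res2$manifest$status, c("ok", "failed"))
    expect_null(res2$images[[2]])

    expect_error(wallisBatch(list()), "empty")
})
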
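test_that("harris response matches the brute-force structure tensor", {
    set.seed(8)
    img <- matrix(runif(20 * 20, 0, 255), 20)
    got <- harrisResponse(img)
    want <- loopHarris(img)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
})

test_that("corner detection finds square vertices and nothing on flats", {
    expect_length(detectKeypoints(matrix(80, 32, 32)), 0L)

    img <- matrix(0, 64, 64)
    img[29:36, 29:36] <- 255
    kp <- detectKeypoints(img, threshold = 0.2)
    expect_equal(length(kp), 4L)
    corners <- rbind(c(29, 29), c(29, 36), c(36, 29), c(36, 36))
    for (q in seq_len(4)) {
        dists <- sqrt(rowSums((corners -
            matrix(kp@coords[q, ], 4, 2, byrow = TRUE))^2))
        expect_lte(min(dists), sqrt(2))   # within one pixel diagonally
    }

    ## determinism and score ordering
    kp2 <- detectKeypoints(img, threshold = 0.2)
    expect_identical(kp@coords, kp2@coords)
    expect_true(all(diff(kp@scores) <= 0))
})

test_that("matching is exact on identical images and tolerant to shifts", {
    img <- percentileStretch(pixelMatrix(simulateScenePair(
        SceneSimConfig(seed = 4, hotspotAmplitude = 0,
                       textureAmplitude = 60))$a))
    kp <- detectKeypoints(img)
    m <- matchKeypoints(img, kp, img, kp)
    r <- 5
    interior <- sum(kp@coords[, 1] > r & kp@coords[, 1] <= nrow(img) - r &
                    kp@coords[, 2] > r & kp@coords[, 2] <= ncol(img) - r)
    expect_equal(nrow(m), interior)
    expect_true(all(m$ncc > 1 - 1e-12))
    expect_true(all(m$row_a == m$row_b & m$col_a == m$col_b))

    ## 3-pixel row shift: most interior keypoints recovered at the offset
    sh <- rbind(img[4:nrow(img), ], img[1:3, ])
    ms <- matchKeypoints(img, kp, sh, detectKeypoints(sh))
    atOffset <- sum(ms$row_a - ms$row_b == 3 & ms$col_a == ms$col_b)
    expect_gte(atOffset / interior, 0.9)
})

test_that("uncorrelated noise yields almost no accepted matches", {
    rates <- vapply(1:20, function(s) {
        set.seed(200 + s)
        a <- matrix(runif(64 * 64, 0, 255), 64)
        b <- matrix(runif(64 * 64, 0, 255), 64)
        ka <- detectKeypoints(a); kb <- detectKeypoints(b)
        if (min(length(ka), length(kb)) == 0) return(0)
        nrow(matchKeypoints(a, ka, b, kb)) / min(length(ka), length(kb))
    }, numeric(1))
    expect_lte(mean(rates), 0.05)
})

test_that("pipeline comparison mirrors the published gain arithmetic", {
    expect_equal(percentIncrease(58193, 110089), 89.2, tolerance = 1e-3)
    expect_equal(percentIncrease(272078, 445291), 63.7, tolerance = 1e-3)
    expect_error(percentIncrease(0, 5), "nonpositive")
})

test_that("filtering helps low-contrast pairs and saturates on rich ones", {
    amps <- seq(5, 16, length.out = 10)
    pairs <- lapply(1:10, function(s) {
        p <- simulateScenePair(SceneSimConfig(seed = s,
                                              textureAmplitude = amps[s]))
        list(a = p$a, b = p$b)
    })
    rep <- comparePipelines(pairs)
    expect_gte(sum(rep@pairs$matches_filtered > rep@pairs$matches_raw), 9)
    expect_equal(rep@totalUnfiltered, sum(rep@pairs$matches_raw))
    expect_gt(rep@percentChange, 0)

    ## deterministic re-run
    rep2 <- comparePipelines(pairs)
    expect_identical(rep@pairs, rep2@pairs)

    ## relative gain is larger where the unfiltered pipeline found less
    expect_lt(cor(rep@pairs$matches_raw, rep@pairs$pct_gain,
                  method = "spearman"), 0)

    ## already-contrasty pairs (dense texture, local SD near the target):
    ## little change either way
    rich <- lapply(11:14, function(s) {
        p <- simulateScenePair(SceneSimConfig(seed = s, nTexture = 400L,
                                              textureAmplitude = 50,
                                              hotspotAmplitude = 0,
                                              smoothAmplitude = 30))
        list(a = p$a, b = p$b)
    })
    rr <- comparePipelines(rich)
    expect_gte(rr@percentChange, -10)
    expect_lte(rr@percentChange, 30)

    expect_error(comparePipelines(list()), "empty")
})
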
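## Independent brute-force reference implementations used as oracles.
## These deliberately use plain double loops / direct formulas so they stay
## independent of the package's vectorized code paths.

## naive double-loop mean over a 0-based half-open rectangle
loopRoiMean <- function(pixels, rmin, rmax, cmin, cmax) {
    total <- 0; count <- 0
    for (i in (rmin + 1):rmax)
        for (j in (cmin + 1):cmax) {
            total <- total + pixels[i, j]
            count <- count + 1
        }
    total / count
}

## reflect an out-of-range 1-based index into 1..n (symmetric, edge kept)
reflectIdx <- function(i, n) {
    while (i < 1 || i > n) {
        if (i < 1) i <- 1 - i
        if (i > n) i <- 2 * n + 1 - i
    }
    i
}

## double-loop local mean/population-SD with symmetric reflection padding
loopLocalStats <- function(img, window) {
    r <- (window - 1) / 2
    nr <- nrow(img); nc <- ncol(img)
    m <- matrix(0, nr, nc); s <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        v <- numeric(0)
        for (di in -r:r) for (dj in -r:r)
            v <- c(v, img[reflectIdx(i + di, nr), reflectIdx(j + dj, nc)])
        m[i, j] <- mean(v)
        s[i, j] <- sqrt(mean((v - mean(v))^2))
    }
    list(mean = m, sd = s)
}

## direct per-pixel Wallis formula from precomputed local stats
loopWallis <- function(img, m, s, mt, st, cc, b, eps) {
    out <- img
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
        gain <- (cc * st) / (cc * s[i, j] + (1 - cc) * st + eps)
        out[i, j] <- (img[i, j] - m[i, j]) * gain + b * mt +
            (1 - b) * m[i, j]
    }
    round(pmin(pmax(out, 0), 255))
}

## double-loop Harris response: central-difference gradients with reflected
## borders, Gaussian-weighted structure tensor, det - k tr^2
loopHarris <- function(img, sigma = 1.5, k = 0.05) {
    nr <- nrow(img); nc <- ncol(img)
    px <- function(i, j) img[reflectIdx(i, nr), reflectIdx(j, nc)]
    gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        gx[i, j] <- (px(i, j + 1) - px(i, j - 1)) / 2
        gy[i, j] <- (px(i + 1, j) - px(i - 1, j)) / 2
    }
    r <- ceiling(3 * sigma)
    w1 <- exp(-(-r:r)^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
    R <- matrix(0, nr, nc)
    gref <- function(g, i, j) g[reflectIdx(i, nr), reflectIdx(j, nc)]
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        sxx <- 0; syy <- 0; sxy <- 0
        for (di in -r:r) for (dj in -r:r) {
            w <- w1[di + r + 1] * w1[dj + r + 1]
            a <- gref(gx, i + di, j + dj)
            b <- gref(gy, i + di, j + dj)
            sxx <- sxx + w * a * a
            syy <- syy + w * b * b
            sxy <- sxy + w * a * b
        }
        R[i, j] <- sxx * syy - sxy^2 - k * (sxx + syy)^2
    }
    R
}

## normal-equations least squares on an explicitly built design
neSolve <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

## independent single-hidden-layer tanh forward pass, scalar loop
loopAnnPredict <- function(model, dl, tc) {
    h <- nrow(model@W1)
    out <- numeric(length(dl))
    for (q in seq_along(dl)) {
        x1 <- (dl[q] - model@inputCenter[1]) / model@inputScale[1]
        x2 <- (tc[q] - model@inputCenter[2]) / model@inputScale[2]
        y <- model@b2
        for (u in seq_len(h)) {
            s <- model@b1[u] + model@W1[u, 1] * x1 + model@W1[u, 2] * x2
            y <- y + model@w2[u] * tanh(s)
        }
        out[q] <- y * model@outputScale + model@outputCenter
    }
    out
}

## direct-formula agreement statistics
directR2 <- function(o, s) {
    mo <- mean(o); ms <- mean(s)
    (sum((o - mo) * (s - ms)) /
     sqrt(sum((o - mo)^2) * sum((s - ms)^2)))^2
}
directSI <- function(o, s) {
    mo <- mean(o)
    1 - sum((s - o)^2) / sum((abs(s - mo) + abs(o - mo))^2)
}

## the twenty field-vs-product validation rows of the vineyard case study
## (reference handheld means/SDs, uncalibrated product, calibrated product)
canopyValidationTable <- function() {
    f <- system.file("extdata", "canopy_validation.csv",
                     package = "thermocal")
    utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}

gcpFixture <- function(which = c("unfiltered", "filtered")) {
    which <- match.arg(which)
    readGcpCsv(system.file("extdata",
                           paste0("gcp_errors_", which, ".csv"),
                           package = "thermocal"))
}

## random calibration dataset helper
randomDataset <- function(n, seed = 1) {
    withr_seed <- function(code) { set.seed(seed); code }
    withr_seed({
        CalibrationDataset(dl = runif(n, 10, 100), tc = runif(n, 5, 31),
                           tbb = runif(n, 5, 65))
    })
}
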
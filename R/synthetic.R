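## Synthetic-data generators emulating the toolkit's inputs: a TEC-less
## sensor forward model producing blackbody calibration campaigns, low
## contrast overlapping scene pairs, and GCP error tables. All generators
## are bit-reproducible given (config, seed).

#' Default sensor-temperature sampling for a campaign
#'
#' Twenty sensor temperatures between 5 and 31 degC, denser above 20 degC
#' (cooling-room sessions yield fewer low-temperature acquisitions than
#' ambient sessions).
#'
#' @return Numeric vector of sensor temperatures (degC).
#' @export
defaultTcSampling <- function() {
    c(seq(5, 19, length.out = 5), seq(20, 31, length.out = 15))
}

#' Simulate a blackbody calibration campaign
#'
#' One record per (blackbody setpoint, sensor temperature) combination. The
#' forward model is
#' \code{dl = offset + k1 * (tbb + 273.15)^4 * 1e-8 + k2 * (tc - t0) +
#' k3 * (tc - t0)^2 + noise}: a quartic radiance proxy for the scene term
#' plus linear and quadratic sensor-temperature drift. Counts are clipped to
#' the 16-bit container; a configuration whose noiseless counts overflow the
#' container raises an error.
#'
#' @param config a [SensorSimConfig-class].
#' @param tbbSetpoints blackbody setpoints (degC); default 5 to 65 in steps
#'   of 5.
#' @param tcValues sensor temperatures (degC); default
#'   [defaultTcSampling()].
#' @return A [CalibrationDataset-class].
#' @examples
#' d <- simulateBlackbodyCampaign(SensorSimConfig(seed = 7))
#' nRecords(d)
#' @export
simulateBlackbodyCampaign <- function(config = SensorSimConfig(),
                                      tbbSetpoints = seq(5, 65, by = 5),
                                      tcValues = defaultTcSampling()) {
    stopifnot(is(config, "SensorSimConfig"))
    if (length(tbbSetpoints) == 0 || length(tcValues) == 0)
        stop("setpoint and sensor-temperature lists must be nonempty",
             call. = FALSE)
    g <- expand.grid(tc = tcValues, tbb = tbbSetpoints)
    mu <- config@offset + config@k1 * (g$tbb + 273.15)^4 * 1e-8 +
        config@k2 * (g$tc - config@t0) + config@k3 * (g$tc - config@t0)^2
    if (any(mu < 0) || any(mu > 65535))
        stop("configuration error: noiseless counts overflow the 16-bit ",
             "container", call. = FALSE)
    dl <- withSeed(config@seed,
                   mu + stats::rnorm(length(mu), 0, config@noiseSd))
    CalibrationDataset(frame_id = sprintf("bb_%04d", seq_len(nrow(g))),
                       dl = clip(dl, 0, 65535), tc = g$tc, tbb = g$tbb)
}

## smooth random field of a given size: white noise blurred with a wide
## Gaussian, rescaled to zero mean and unit SD
smoothField <- function(n, sigma) {
    f <- convSep(matrix(stats::rnorm(n * n), n, n), gaussKernel1d(sigma))
    (f - mean(f)) / stats::sd(f)
}

#' Simulate a low-contrast overlapping scene pair
#'
#' Builds a base scene from a smooth random field, many weak fine-texture
#' blobs, a few strong hotspot objects and a radial vignetting term, then
#' cuts two overlapping frames: the second frame shows the scene translated
#' by the configured integer offset. Vignetting is camera-fixed (it does not
#' translate), and each frame gets fresh sensor noise. The hotspots dominate
#' the dynamic range, so a min-max display stretch leaves the matchable
#' texture at only a few gray levels -- the low-contrast regime that defeats
#' interest-point detection on raw thermal frames.
#'
#' @param config a [SceneSimConfig-class].
#' @return List with [ThermalFrame-class] components \code{a} and \code{b}
#'   and the true \code{offset} (row, col) in pixels.
#' @export
simulateScenePair <- function(config = SceneSimConfig()) {
    stopifnot(is(config, "SceneSimConfig"))
    n <- config@size
    tr <- config@translation
    pad <- max(abs(tr), 1L)
    big <- n + 2L * pad
    withSeed(config@seed, {
        field <- config@smoothAmplitude * smoothField(big, big / 8)
        rows <- matrix(seq_len(big), big, big)
        cols <- t(rows)
        addBlobs <- function(field, nb, amp, sigma) {
            ctr <- cbind(sample.int(big, nb, replace = TRUE),
                         sample.int(big, nb, replace = TRUE))
            a <- amp * sample(c(-1, 1), nb, replace = TRUE) *
                stats::runif(nb, 0.6, 1)
            for (q in seq_len(nb)) {
                d2 <- (rows - ctr[q, 1])^2 + (cols - ctr[q, 2])^2
                field <- field + a[q] * exp(-d2 / (2 * sigma^2))
            }
            field
        }
        if (config@nTexture > 0 && config@textureAmplitude > 0)
            field <- addBlobs(field, config@nTexture,
                              config@textureAmplitude, 1.2)
        if (config@nHotspots > 0 && config@hotspotAmplitude > 0)
            field <- addBlobs(field, config@nHotspots,
                              config@hotspotAmplitude, config@hotspotSigma)
        noiseA <- stats::rnorm(n * n, 0, config@noiseSd)
        noiseB <- stats::rnorm(n * n, 0, config@noiseSd)
    })
    cut <- function(dr, dc)
        field[(pad + 1L + dr):(pad + n + dr),
              (pad + 1L + dc):(pad + n + dc)]
    ## camera-fixed vignetting in frame coordinates
    rr <- matrix(seq_len(n), n, n); cc <- t(rr)
    rad2 <- ((rr - (n + 1) / 2)^2 + (cc - (n + 1) / 2)^2) / (n / 2)^2
    vig <- -config@vignettingStrength * rad2
    enc <- function(scene, noise)
        ThermalFrame(clip(round(config@baseLevel + scene + vig +
                                matrix(noise, n, n)), 0, 65535),
                     sensorTemp = 25, frameId = "scene")
    a <- enc(cut(0L, 0L), noiseA)
    b <- enc(cut(tr[1], tr[2]), noiseB)
    a@frameId <- "scene_a"; b@frameId <- "scene_b"
    list(a = a, b = b, offset = tr)
}

#' Simulate a GCP error table
#'
#' Zero-mean Gaussian signed errors per axis.
#'
#' @param n_points number of control points.
#' @param axis_sds numeric(3) of per-axis error SDs (m).
#' @param seed integer RNG seed.
#' @return A [GcpErrorTable-class].
#' @export
simulateGcpTable <- function(n_points, axis_sds = c(0.6, 0.4, 1.0),
                             seed = 1L) {
    if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
    if (any(axis_sds < 0)) stop("axis_sds must be >= 0", call. = FALSE)
    withSeed(seed, {
        ex <- stats::rnorm(n_points, 0, axis_sds[1])
        ey <- stats::rnorm(n_points, 0, axis_sds[2])
        ez <- stats::rnorm(n_points, 0, axis_sds[3])
    })
    GcpErrorTable(seq_len(n_points), ex, ey, ez)
}
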
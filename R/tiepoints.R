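## Desk-scale tie-point surrogate: Harris corner detection plus normalized
## cross-correlation matching, run on raw-stretched versus Wallis-filtered
## versions of overlapping image pairs to measure the filtering gain.

gaussKernel1d <- function(sigma) {
    r <- ceiling(3 * sigma)
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k / sum(k)
}

## separable convolution with reflection padding
convSep <- function(image, k) {
    r <- (length(k) - 1L) / 2L
    p <- padReflect(image, r)
    nr <- nrow(image); nc <- ncol(image)
    ## rows pass
    tmp <- matrix(0, nr, ncol(p))
    for (d in seq_along(k))
        tmp <- tmp + k[d] * p[(d):(d + nr - 1L), , drop = FALSE]
    out <- matrix(0, nr, nc)
    for (d in seq_along(k))
        out <- out + k[d] * tmp[, (d):(d + nc - 1L), drop = FALSE]
    out
}

#' Harris corner response map
#'
#' Image gradients by central differences (reflection padding), structure
#' tensor smoothed with a Gaussian window, response
#' \code{det - k * trace^2}.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian window scale (default 1.5).
#' @param k trace weighting constant (default 0.05).
#' @return Numeric matrix of responses, same shape as the input.
#' @export
harrisResponse <- function(image, sigma = 1.5, k = 0.05) {
    p <- padReflect(image, 1L)
    nr <- nrow(image); nc <- ncol(image)
    gx <- (p[2:(nr + 1), 3:(nc + 2)] - p[2:(nr + 1), 1:nc]) / 2
    gy <- (p[3:(nr + 2), 2:(nc + 1)] - p[1:nr, 2:(nc + 1)]) / 2
    kk <- gaussKernel1d(sigma)
    sxx <- convSep(gx * gx, kk)
    syy <- convSep(gy * gy, kk)
    sxy <- convSep(gx * gy, kk)
    sxx * syy - sxy^2 - k * (sxx + syy)^2
}

#' Detect Harris interest points
#'
#' Non-maximum suppression in 3x3 neighborhoods of the Harris response,
#' keeping points whose response is at least \code{threshold} times the
#' global maximum response, capped at \code{maxPoints} by descending score.
#' Deterministic; a constant image yields an empty set.
#'
#' @param image numeric matrix, at least 16x16.
#' @param threshold response fraction in (0, 1) (default 1e-4; the Harris
#'   response scales as contrast to the fourth power, so this keeps corners
#'   within about 10 percent of the maximum contrast).
#' @param maxPoints cap on the number of returned points (default 500).
#' @param sigma,k Harris response parameters (see [harrisResponse()]).
#' @return A [KeypointSet-class]; coordinates are 1-based (row, col).
#' @export
detectKeypoints <- function(image, threshold = 1e-4, maxPoints = 500,
                            sigma = 1.5, k = 0.05) {
    if (nrow(image) < 16 || ncol(image) < 16)
        stop("image must be at least 16x16", call. = FALSE)
    R <- harrisResponse(image, sigma, k)
    mx <- max(R)
    empty <- new("KeypointSet",
                 coords = matrix(integer(), 0, 2,
                                 dimnames = list(NULL, c("row", "col"))),
                 scores = numeric())
    if (mx <= 0) return(empty)
    p <- padReflect(R, 1L)
    nr <- nrow(R); nc <- ncol(R)
    isMax <- matrix(TRUE, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        isMax <- isMax &
            (R >= p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
    }
    keep <- which(isMax & R >= threshold * mx, arr.ind = TRUE)
    if (nrow(keep) == 0) return(empty)
    sc <- R[keep]
    ## order by descending score, ties by row then col for determinism
    o <- order(-sc, keep[, 1], keep[, 2])
    o <- o[seq_len(min(length(o), maxPoints))]
    new("KeypointSet",
        coords = matrix(as.integer(keep[o, , drop = FALSE]),
                        ncol = 2, dimnames = list(NULL, c("row", "col"))),
        scores = sc[o])
}

#' @describeIn KeypointSet-class number of keypoints.
#' @param x a KeypointSet.
#' @export
setMethod("length", "KeypointSet", function(x) nrow(x@coords))

## centered, L2-normalized patch vectors for keypoints with a full patch
## inside the image; returns matrix (patch^2 x n) plus kept indices
patchMatrix <- function(image, kps, r) {
    co <- kps@coords
    inb <- co[, 1] > r & co[, 1] <= nrow(image) - r &
           co[, 2] > r & co[, 2] <= ncol(image) - r
    idx <- which(inb)
    P <- matrix(NA_real_, (2 * r + 1)^2, length(idx))
    keepVar <- rep(TRUE, length(idx))
    for (q in seq_along(idx)) {
        i <- co[idx[q], 1]; j <- co[idx[q], 2]
        v <- as.numeric(image[(i - r):(i + r), (j - r):(j + r)])
        v <- v - mean(v)
        nv <- sqrt(sum(v^2))
        if (nv == 0) keepVar[q] <- FALSE else P[, q] <- v / nv
    }
    list(P = P[, keepVar, drop = FALSE], idx = idx[keepVar])
}

#' Match keypoints by normalized cross-correlation
#'
#' Centers and normalizes the square patch around each keypoint, computes
#' all pairwise NCCs, and keeps mutual-best pairs with NCC at least
#' \code{minNcc}. Keypoints whose patch leaves the image, or with constant
#' patches, are excluded. Ties are broken toward the smaller row-then-col
#' position in the first image.
#'
#' @param imageA,imageB numeric matrices.
#' @param kpsA,kpsB [KeypointSet-class] objects for the two images.
#' @param patch odd patch side length (default 11).
#' @param minNcc acceptance threshold in (0, 1) (default 0.8).
#' @return data.frame with columns \code{row_a}, \code{col_a}, \code{row_b},
#'   \code{col_b}, \code{ncc}.
#' @export
matchKeypoints <- function(imageA, kpsA, imageB, kpsB, patch = 11,
                           minNcc = 0.8) {
    if (patch %% 2 == 0) stop("patch must be odd", call. = FALSE)
    r <- (patch - 1L) / 2L
    empty <- data.frame(row_a = integer(), col_a = integer(),
                        row_b = integer(), col_b = integer(),
                        ncc = numeric())
    if (length(kpsA) == 0 || length(kpsB) == 0) return(empty)
    ## order A's candidates by row then col so argmax ties resolve that way
    oa <- order(kpsA@coords[, 1], kpsA@coords[, 2])
    kpsA <- new("KeypointSet", coords = kpsA@coords[oa, , drop = FALSE],
                scores = kpsA@scores[oa])
    pa <- patchMatrix(imageA, kpsA, r)
    pb <- patchMatrix(imageB, kpsB, r)
    if (ncol(pa$P) == 0 || ncol(pb$P) == 0) return(empty)
    ncc <- crossprod(pa$P, pb$P)               # nA x nB
    bestB <- max.col(ncc, ties.method = "first")
    bestA <- max.col(t(ncc), ties.method = "first")
    ia <- seq_len(nrow(ncc))
    mutual <- bestA[bestB[ia]] == ia
    val <- ncc[cbind(ia, bestB)]
    sel <- which(mutual & val >= minNcc)
    ca <- kpsA@coords[pa$idx[sel], , drop = FALSE]
    cb <- kpsB@coords[pb$idx[bestB[sel]], , drop = FALSE]
    data.frame(row_a = ca[, 1], col_a = ca[, 2],
               row_b = cb[, 1], col_b = cb[, 2], ncc = val[sel])
}

#' Percent increase between two counts
#'
#' @param before,after counts; \code{before} must be positive.
#' @return Percent change, \code{100 * (after - before) / before}.
#' @examples
#' percentIncrease(58193, 110089)  # tie-point gain of a filtered block
#' @export
percentIncrease <- function(before, after) {
    if (any(before <= 0))
        stop("percent increase undefined for nonpositive baseline",
             call. = FALSE)
    100 * (after - before) / before
}

#' Compare tie-point pipelines with and without Wallis filtering
#'
#' For each overlapping pair, detects and matches keypoints on the
#' percentile-stretched images and on their Wallis-filtered versions with
#' identical detector/matcher settings, and reports per-pair and aggregate
#' counts with the percent change.
#'
#' @param pairs nonempty list; each element a list with components \code{a}
#'   and \code{b} ([ThermalFrame-class] or numeric matrix).
#' @param params a [WallisParams-class].
#' @param threshold,maxPoints detector settings (see [detectKeypoints()]).
#' @param patch,minNcc matcher settings (see [matchKeypoints()]).
#' @return A [MatchReport-class].
#' @export
comparePipelines <- function(pairs, params = WallisParams(),
                             threshold = 1e-4, maxPoints = 500,
                             patch = 11, minNcc = 0.8) {
    if (length(pairs) == 0)
        stop("empty pair list", call. = FALSE)
    rows <- lapply(seq_along(pairs), function(k) {
        a <- percentileStretch(pairs[[k]]$a, params@stretchLow,
                               params@stretchHigh)
        b <- percentileStretch(pairs[[k]]$b, params@stretchLow,
                               params@stretchHigh)
        fa <- wallis(a, params); fb <- wallis(b, params)
        run <- function(x, y) {
            kx <- detectKeypoints(x, threshold, maxPoints)
            ky <- detectKeypoints(y, threshold, maxPoints)
            list(kx = length(kx), ky = length(ky),
                 m = nrow(matchKeypoints(x, kx, y, ky, patch, minNcc)))
        }
        raw <- run(a, b); fil <- run(fa, fb)
        data.frame(pair = k, kp_a_raw = raw$kx, kp_b_raw = raw$ky,
                   matches_raw = raw$m, kp_a_filtered = fil$kx,
                   kp_b_filtered = fil$ky, matches_filtered = fil$m,
                   pct_gain = if (raw$m > 0)
                       percentIncrease(raw$m, fil$m) else NA_real_)
    })
    tab <- do.call(rbind, rows)
    tu <- sum(tab$matches_raw); tf <- sum(tab$matches_filtered)
    new("MatchReport", pairs = tab, totalUnfiltered = tu,
        totalFiltered = tf,
        percentChange = if (tu > 0) percentIncrease(tu, tf) else NA_real_)
}
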
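## Wallis local-contrast filtering: percentile pre-stretch of raw counts to
## an 8-bit working range, sliding-window local statistics, and the
## two-constant Wallis transform that drives each neighborhood's mean and
## standard deviation toward user targets.

#' Percentile stretch to the 8-bit working range
#'
#' Linearly maps the \code{low}/\code{high} percentiles of the pixel
#' distribution to 0/255 and clips; raw thermal counts occupy a narrow band
#' of the 16-bit container, so this pre-stretch is what makes 8-bit Wallis
#' targets meaningful. A constant image maps to mid-gray (127).
#'
#' @param frame a [ThermalFrame-class] or a numeric matrix.
#' @param low,high percentiles in [0, 100], \code{low < high}.
#' @return Integer-valued numeric matrix in [0, 255].
#' @export
percentileStretch <- function(frame, low = 2, high = 98) {
    if (low >= high)
        stop("low percentile must be below high", call. = FALSE)
    x <- asPixelMatrix(frame)
    q <- stats::quantile(x, c(low, high) / 100, names = FALSE)
    if (q[2] <= q[1])
        return(matrix(127, nrow(x), ncol(x)))
    round(clip((x - q[1]) / (q[2] - q[1]) * 255, 0, 255))
}

#' Sliding-window local mean and standard deviation
#'
#' Per-pixel mean and population standard deviation over the odd-sided
#' square window centered at each pixel, with reflection padding at the
#' edges. Computed with summed-area tables, so cost is independent of the
#' window size.
#'
#' @param image numeric matrix (working image).
#' @param window odd window side length, at most the smaller image
#'   dimension.
#' @return List with matrices \code{mean} and \code{sd}.
#' @export
localStats <- function(image, window) {
    if (window %% 2 == 0 || window < 1)
        stop("window must be odd and positive", call. = FALSE)
    if (window > min(dim(image)))
        stop("window larger than the image", call. = FALSE)
    r <- (window - 1L) / 2L
    p <- padReflect(image, r)
    boxSum <- function(m, w) {
        ## summed-area table with a leading zero row/col
        S <- rbind(0, apply(m, 2, cumsum))
        S <- cbind(0, t(apply(S, 1, cumsum)))
        nr <- nrow(m) - w + 1L; nc <- ncol(m) - w + 1L
        S[(1L + w):(nr + w), (1L + w):(nc + w)] -
            S[(1L + w):(nr + w), 1L:nc] -
            S[1L:nr, (1L + w):(nc + w)] + S[1L:nr, 1L:nc]
    }
    npix <- window^2
    m <- boxSum(p, window) / npix
    v <- boxSum(p^2, window) / npix - m^2
    list(mean = m, sd = sqrt(pmax(v, 0)))
}

#' Wallis local-contrast filter
#'
#' Applies the two-constant Wallis transform
#' \deqn{G' = (G - m) \frac{c\,s_t}{c\,s + (1-c)\,s_t + \epsilon}
#'        + b\,m_t + (1-b)\,m}
#' where \eqn{m} and \eqn{s} are the local window mean and standard
#' deviation, \eqn{m_t}/\eqn{s_t} the targets and \eqn{b}/\eqn{c} the
#' brightness and contrast constants. Output is clipped to [0, 255] and
#' rounded to 8-bit levels.
#'
#' @param image numeric matrix in the 8-bit working range (see
#'   [percentileStretch()]).
#' @param params a [WallisParams-class].
#' @return Integer-valued numeric matrix in [0, 255].
#' @export
wallis <- function(image, params = WallisParams()) {
    stopifnot(is(params, "WallisParams"))
    ls <- localStats(image, params@window)
    cc <- params@contrast; b <- params@brightness
    st <- params@targetStd; mt <- params@targetMean
    gain <- (cc * st) / (cc * ls$sd + (1 - cc) * st + params@epsilon)
    out <- (image - ls$mean) * gain + b * mt + (1 - b) * ls$mean
    round(clip(out, 0, 255))
}

#' Batch Wallis filtering with a processing manifest
#'
#' Applies [percentileStretch()] then [wallis()] with identical parameters
#' to every frame. Frames given as file paths that cannot be read are
#' recorded as failed in the manifest and processing continues.
#'
#' @param frames nonempty list of [ThermalFrame-class] objects, numeric
#'   matrices, or TIFF file paths.
#' @param params a [WallisParams-class].
#' @return List with \code{images} (filtered matrices, NULL where failed)
#'   and \code{manifest} (data.frame of per-image status and before/after
#'   global mean/SD of the working image).
#' @export
wallisBatch <- function(frames, params = WallisParams()) {
    if (length(frames) == 0)
        stop("empty frame set", call. = FALSE)
    ids <- names(frames)
    if (is.null(ids)) ids <- sprintf("frame_%03d", seq_along(frames))
    out <- vector("list", length(frames))
    rows <- vector("list", length(frames))
    for (k in seq_along(frames)) {
        fr <- frames[[k]]
        res <- tryCatch({
            if (is.character(fr)) {
                ids[k] <- sub("\\.[^.]*$", "", basename(fr))
                fr <- matrix2d(tiff::readTIFF(fr, as.is = TRUE))
            }
            w <- percentileStretch(fr, params@stretchLow,
                                   params@stretchHigh)
            f <- wallis(w, params)
            list(ok = TRUE, w = w, f = f)
        }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
        if (res$ok) {
            out[[k]] <- res$f
            rows[[k]] <- data.frame(frame = ids[k], status = "ok",
                                    mean_before = mean(res$w),
                                    sd_before = stats::sd(res$w),
                                    mean_after = mean(res$f),
                                    sd_after = stats::sd(res$f),
                                    stringsAsFactors = FALSE)
        } else {
            rows[[k]] <- data.frame(frame = ids[k], status = "failed",
                                    mean_before = NA_real_,
                                    sd_before = NA_real_,
                                    mean_after = NA_real_,
                                    sd_after = NA_real_,
                                    stringsAsFactors = FALSE)
        }
    }
    names(out) <- ids
    list(images = out, manifest = do.call(rbind, rows))
}

## force a 2-d array (readTIFF can return 3-d for multi-channel)
matrix2d <- function(img) {
    if (length(dim(img)) != 2)
        stop("unsupported format: expected a single-channel image",
             call. = FALSE)
    matrix(as.numeric(img), nrow = nrow(img))
}
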
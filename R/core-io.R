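## Readers and writers for the tabular and raster formats the toolkit
## touches, plus the ROI digital-response extraction.

#' Read a blackbody calibration CSV
#'
#' Expects header columns \code{frame_id}, \code{dl_mean},
#' \code{sensor_temp_c}, \code{blackbody_temp_c}; extra columns are ignored.
#' Decimal separator is always the dot, independent of locale.
#'
#' @param path CSV file path.
#' @param tbbRange plausible blackbody range passed through to the dataset.
#' @return A [CalibrationDataset-class], one record per row in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeCalibrationCsv(CalibrationDataset(dl = c(7000, 7450), tc = c(18, 24),
#'                                        tbb = c(25, 40)), f)
#' readCalibrationCsv(f)
#' @export
readCalibrationCsv <- function(path, tbbRange = c(-20, 100)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = NA, check.names = TRUE)
    need <- c("frame_id", "dl_mean", "sensor_temp_c", "blackbody_temp_c")
    missing <- setdiff(need, names(tab))
    if (length(missing) > 0)
        stop("calibration CSV is missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    for (col in c("dl_mean", "sensor_temp_c", "blackbody_temp_c")) {
        v <- tab[[col]]
        if (!is.numeric(v)) {
            parsed <- suppressWarnings(as.numeric(v))
            bad <- which(is.na(parsed) & !is.na(v))
            if (length(bad) > 0)
                stop(sprintf(
                    "non-numeric value in column '%s' at data row %d",
                    col, bad[1]), call. = FALSE)
            tab[[col]] <- parsed
        }
    }
    CalibrationDataset(frame_id = tab$frame_id, dl = tab$dl_mean,
                       tc = tab$sensor_temp_c, tbb = tab$blackbody_temp_c,
                       tbbRange = tbbRange)
}

#' Write a blackbody calibration CSV
#'
#' Values are rendered with 10 significant digits so a round trip through
#' [readCalibrationCsv()] preserves them well below 1e-6.
#'
#' @param dataset a [CalibrationDataset-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeCalibrationCsv <- function(dataset, path) {
    stopifnot(is(dataset, "CalibrationDataset"))
    rec <- dataset@records
    out <- data.frame(frame_id = rec$frame_id,
                      dl_mean = formatC(rec$dl, digits = 10, format = "g"),
                      sensor_temp_c = formatC(rec$tc, digits = 10,
                                              format = "g"),
                      blackbody_temp_c = formatC(rec$tbb, digits = 10,
                                                 format = "g"),
                      stringsAsFactors = FALSE)
    tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
             error = function(e) stop("cannot write calibration CSV to '",
                                      path, "': ", conditionMessage(e),
                                      call. = FALSE))
    invisible(path)
}

#' Read a raw thermal frame
#'
#' Reads a single-channel 8- or 16-bit TIFF of raw digital levels and a
#' key-value sidecar file carrying the sensor temperature recorded at
#' acquisition. The sidecar is JSON-style text with the required key
#' \code{sensor_temperature_c}. Pixel values are widened to the 16-bit
#' container unchanged.
#'
#' @param image_path TIFF file path.
#' @param sidecar_path sidecar file path.
#' @return A [ThermalFrame-class].
#' @export
readThermalFrame <- function(image_path, sidecar_path) {
    img <- tiff::readTIFF(image_path, as.is = TRUE)
    if (length(dim(img)) != 2)
        stop("unsupported format: expected a single-channel image, got ",
             dim(img)[3], " channels", call. = FALSE)
    meta <- tryCatch(jsonlite::fromJSON(sidecar_path),
                     error = function(e) stop("cannot parse sidecar '",
                                              sidecar_path, "'",
                                              call. = FALSE))
    if (is.null(meta$sensor_temperature_c))
        stop("sidecar lacks required key 'sensor_temperature_c'",
             call. = FALSE)
    ThermalFrame(pixels = matrix(as.numeric(img), nrow = nrow(img)),
                 sensorTemp = as.numeric(meta$sensor_temperature_c),
                 frameId = sub("\\.[^.]*$", "", basename(image_path)))
}

#' Write a raw thermal frame and its sidecar
#'
#' Counterpart of [readThermalFrame()]: 16-bit grayscale TIFF plus a JSON
#' sidecar with \code{sensor_temperature_c}.
#'
#' @param frame a [ThermalFrame-class].
#' @param image_path,sidecar_path output paths.
#' @return Invisibly, \code{image_path}.
#' @export
writeThermalFrame <- function(frame, image_path, sidecar_path) {
    stopifnot(is(frame, "ThermalFrame"))
    tiff::writeTIFF(round(frame@pixels) / 65535, image_path,
                    bits.per.sample = 16L)
    jsonlite::write_json(list(sensor_temperature_c = frame@sensorTemp),
                         sidecar_path, auto_unbox = TRUE, digits = NA)
    invisible(image_path)
}

#' Mean digital level inside a region of interest
#'
#' Arithmetic mean of the digital levels inside the half-open rectangle, as
#' used to summarize the blackbody area of a calibration frame.
#'
#' @param frame a [ThermalFrame-class].
#' @param roi an [RoiSelection-class] (0-based, half-open).
#' @return Scalar mean counts.
#' @export
extractRoiMean <- function(frame, roi) {
    stopifnot(is(frame, "ThermalFrame"), is(roi, "RoiSelection"))
    p <- frame@pixels
    if (roi@rmax > nrow(p) || roi@cmax > ncol(p))
        stop("roi exceeds frame bounds", call. = FALSE)
    rows <- (roi@rmin + 1L):roi@rmax
    cols <- (roi@cmin + 1L):roi@cmax
    mean(p[rows, cols])
}

## ---------------------------------------------------------------------------
## Float32 TIFF for temperature maps
## ---------------------------------------------------------------------------
## Temperature maps are stored as single-strip, uncompressed, little-endian
## grayscale TIFFs with 32-bit IEEE floating-point samples (degrees
## Celsius). TIFF tag ids: 256 width, 257 length, 258 bits/sample,
## 259 compression, 262 photometric, 273 strip offset, 277 samples/pixel,
## 278 rows/strip, 279 strip byte count, 339 sample format (3 = IEEE float).

#' Write a temperature map as a 32-bit float TIFF
#'
#' Values are stored in degrees Celsius as IEEE single-precision floats;
#' a round trip through [readTemperatureMap()] is lossless to well below
#' 1e-5 over typical environmental temperature ranges.
#'
#' @param map a [TemperatureMap-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeTemperatureMap <- function(map, path) {
    stopifnot(is(map, "TemperatureMap"))
    m <- map@temps
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stop("cannot write to '", path, "'",
                                             call. = FALSE))
    on.exit(close(con))
    w <- ncol(m); h <- nrow(m)
    tags <- list(  # id, type (3 short, 4 long), value
        c(256L, 4L, w), c(257L, 4L, h), c(258L, 3L, 32L), c(259L, 3L, 1L),
        c(262L, 3L, 1L), c(273L, 4L, 0L),  # offset patched below
        c(277L, 3L, 1L), c(278L, 4L, h), c(279L, 4L, 4L * w * h),
        c(339L, 3L, 3L))
    nTags <- length(tags)
    dataOffset <- 8L + 2L + nTags * 12L + 4L
    tags[[6]][3] <- dataOffset
    writeChar("II", con, nchars = 2, eos = NULL)
    writeBin(42L, con, size = 2L, endian = "little")
    writeBin(8L, con, size = 4L, endian = "little")           # first IFD
    writeBin(as.integer(nTags), con, size = 2L, endian = "little")
    for (tg in tags) {
        writeBin(as.integer(tg[1]), con, size = 2L, endian = "little")
        writeBin(as.integer(tg[2]), con, size = 2L, endian = "little")
        writeBin(1L, con, size = 4L, endian = "little")        # count
        if (tg[2] == 3L) {                                     # SHORT value
            writeBin(as.integer(tg[3]), con, size = 2L, endian = "little")
            writeBin(0L, con, size = 2L, endian = "little")
        } else {
            writeBin(as.integer(tg[3]), con, size = 4L, endian = "little")
        }
    }
    writeBin(0L, con, size = 4L, endian = "little")            # no next IFD
    ## pixel data, row-major (TIFF scanline order)
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    invisible(path)
}

#' Read a temperature map written by [writeTemperatureMap()]
#'
#' @param path TIFF file path (32-bit float, single channel, uncompressed).
#' @return A [TemperatureMap-class].
#' @export
readTemperatureMap <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 2)
    if (magic != "II")
        stop("not a little-endian TIFF: '", path, "'", call. = FALSE)
    readBin(con, "integer", 1, size = 2, endian = "little")    # 42
    ifd <- readBin(con, "integer", 1, size = 4, endian = "little")
    seek(con, ifd)
    nTags <- readBin(con, "integer", 1, size = 2, endian = "little")
    tagVal <- list()
    for (i in seq_len(nTags)) {
        id <- readBin(con, "integer", 1, size = 2, endian = "little")
        type <- readBin(con, "integer", 1, size = 2, endian = "little")
        readBin(con, "integer", 1, size = 4, endian = "little")  # count
        if (type == 3L) {
            v <- readBin(con, "integer", 1, size = 2, endian = "little")
            readBin(con, "integer", 1, size = 2, endian = "little")
        } else {
            v <- readBin(con, "integer", 1, size = 4, endian = "little")
        }
        tagVal[[as.character(id)]] <- v
    }
    w <- tagVal[["256"]]; h <- tagVal[["257"]]
    if (is.null(w) || is.null(h) || !identical(tagVal[["258"]], 32L) ||
        !identical(tagVal[["339"]], 3L))
        stop("unsupported TIFF layout (expected 32-bit float, 1 channel)",
             call. = FALSE)
    seek(con, tagVal[["273"]])
    v <- readBin(con, "numeric", n = w * h, size = 4, endian = "little")
    TemperatureMap(matrix(v, nrow = h, byrow = TRUE),
                   provenance = sub("\\.[^.]*$", "", basename(path)))
}
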
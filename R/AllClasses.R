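#' @import methods
NULL

## ---------------------------------------------------------------------------
## Calibration data
## ---------------------------------------------------------------------------

#' Blackbody calibration dataset
#'
#' One row per calibration frame: the mean digital level (counts) of the
#' blackbody region of interest, the microbolometer (sensor) temperature and
#' the blackbody reference temperature. An optional split label assigns each
#' record to the calibration or validation subset.
#'
#' @slot records data.frame with columns \code{frame_id} (character),
#'   \code{dl} (counts), \code{tc} (degC), \code{tbb} (degC).
#' @slot split character vector, either empty or one label per record, each
#'   \code{"calibration"} or \code{"validation"}.
#' @slot tbbRange numeric(2), plausible blackbody temperature range used for
#'   validity checking (default -20..100 degC).
#'
#' @seealso [CalibrationDataset()], [splitDataset()], [fitPolynomial()]
#' @exportClass CalibrationDataset
setClass("CalibrationDataset",
    representation(records = "data.frame", split = "character",
                   tbbRange = "numeric"),
    prototype(records = data.frame(frame_id = character(), dl = numeric(),
                                   tc = numeric(), tbb = numeric()),
              split = character(), tbbRange = c(-20, 100)))

setValidity("CalibrationDataset", function(object) {
    rec <- object@records
    need <- c("frame_id", "dl", "tc", "tbb")
    if (!all(need %in% names(rec)))
        return(paste("records must have columns",
                     paste(need, collapse = ", ")))
    if (nrow(rec) > 0) {
        if (any(!is.finite(rec$dl)) || any(rec$dl < 0) || any(rec$dl > 65535))
            return("dl must be finite and within [0, 65535]")
        if (any(!is.finite(rec$tc)) || any(!is.finite(rec$tbb)))
            return("tc and tbb must be finite")
        rng <- object@tbbRange
        if (any(rec$tbb < rng[1]) || any(rec$tbb > rng[2]))
            return(sprintf("tbb outside plausible range [%g, %g]",
                           rng[1], rng[2]))
    }
    if (length(object@split) > 0) {
        if (length(object@split) != nrow(rec))
            return("split labels must cover all records")
        if (!all(object@split %in% c("calibration", "validation")))
            return("split labels must be 'calibration' or 'validation'")
    }
    TRUE
})

#' Construct a CalibrationDataset
#'
#' @param frame_id character identifiers (recycled from an integer sequence
#'   when missing).
#' @param dl numeric, mean digital level in counts (0..65535).
#' @param tc numeric, sensor temperature in degC.
#' @param tbb numeric, blackbody reference temperature in degC.
#' @param split optional character vector of per-record labels
#'   ("calibration"/"validation").
#' @param tbbRange numeric(2), plausible blackbody range (default -20..100).
#' @return A [CalibrationDataset-class] object.
#' @examples
#' cd <- CalibrationDataset(dl = c(7000, 7100), tc = c(20, 21),
#'                          tbb = c(25, 30))
#' nRecords(cd)
#' @export
CalibrationDataset <- function(frame_id = NULL, dl, tc, tbb,
                               split = character(),
                               tbbRange = c(-20, 100)) {
    n <- length(dl)
    if (is.null(frame_id))
        frame_id <- sprintf("frame_%04d", seq_len(n))
    rec <- data.frame(frame_id = as.character(frame_id),
                      dl = as.numeric(dl), tc = as.numeric(tc),
                      tbb = as.numeric(tbb), stringsAsFactors = FALSE)
    new("CalibrationDataset", records = rec, split = as.character(split),
        tbbRange = tbbRange)
}

## ---------------------------------------------------------------------------
## Raster containers
## ---------------------------------------------------------------------------

#' Raw thermal frame
#'
#' A single-channel image of raw digital levels together with the sensor
#' (microbolometer) temperature recorded at acquisition time.
#'
#' @slot pixels numeric matrix of digital levels in [0, 65535].
#' @slot sensorTemp scalar sensor temperature (degC).
#' @slot frameId opaque identifier.
#' @exportClass ThermalFrame
setClass("ThermalFrame",
    representation(pixels = "matrix", sensorTemp = "numeric",
                   frameId = "character"))

setValidity("ThermalFrame", function(object) {
    p <- object@pixels
    if (nrow(p) < 2 || ncol(p) < 2)
        return("pixels must be at least 2x2")
    if (any(!is.finite(p)) || any(p < 0) || any(p > 65535))
        return("pixels must be finite and within [0, 65535]")
    if (length(object@sensorTemp) != 1 || !is.finite(object@sensorTemp))
        return("sensorTemp must be a finite scalar")
    TRUE
})

#' Construct a ThermalFrame
#'
#' @param pixels numeric matrix of counts.
#' @param sensorTemp sensor temperature (degC).
#' @param frameId identifier string.
#' @return A [ThermalFrame-class] object.
#' @export
ThermalFrame <- function(pixels, sensorTemp, frameId = "frame") {
    new("ThermalFrame", pixels = pixels, sensorTemp = as.numeric(sensorTemp),
        frameId = as.character(frameId))
}

#' Calibrated temperature map
#'
#' Per-pixel calibrated temperatures (degC) with provenance recording the
#' model and source frame that produced it.
#'
#' @slot temps numeric matrix of temperatures (degC).
#' @slot provenance character, model identifier plus frame identifier.
#' @exportClass TemperatureMap
setClass("TemperatureMap",
    representation(temps = "matrix", provenance = "character"))

setValidity("TemperatureMap", function(object) {
    if (any(!is.finite(object@temps)))
        return("temps must be finite")
    TRUE
})

#' Construct a TemperatureMap
#' @param temps numeric matrix (degC).
#' @param provenance character provenance string.
#' @return A [TemperatureMap-class] object.
#' @export
TemperatureMap <- function(temps, provenance = "unknown") {
    new("TemperatureMap", temps = temps,
        provenance = as.character(provenance))
}

#' Rectangular region of interest
#'
#' Row/column bounds of the blackbody region in a frame, 0-based and
#' half-open (the pixel at \code{rmax}/\code{cmax} is excluded), matching the
#' command-line \code{rmin,rmax,cmin,cmax} convention.
#'
#' @slot rmin,rmax,cmin,cmax integer bounds, 0-based half-open.
#' @exportClass RoiSelection
setClass("RoiSelection",
    representation(rmin = "integer", rmax = "integer",
                   cmin = "integer", cmax = "integer"))

setValidity("RoiSelection", function(object) {
    if (object@rmin < 0 || object@cmin < 0)
        return("roi bounds must be non-negative")
    if (object@rmax <= object@rmin || object@cmax <= object@cmin)
        return("roi must be non-empty (half-open bounds)")
    TRUE
})

#' Construct an RoiSelection
#' @param rmin,rmax,cmin,cmax 0-based half-open row/column bounds.
#' @return An [RoiSelection-class] object.
#' @export
RoiSelection <- function(rmin, rmax, cmin, cmax) {
    new("RoiSelection", rmin = as.integer(rmin), rmax = as.integer(rmax),
        cmin = as.integer(cmin), cmax = as.integer(cmax))
}

## ---------------------------------------------------------------------------
## Calibration models
## ---------------------------------------------------------------------------

#' Polynomial calibration model
#'
#' A fitted least-squares mapping (DL, TC) -> temperature. The form tag
#' selects the term list: \code{LINEAR_DL} uses \{1, DL\}; \code{P1} is the
#' bivariate linear model \{1, DL, TC\}; \code{P2}..\code{P4} successively add
#' the quadratic terms, the mixed cubic terms, and TC^3. Coefficients are
#' named \code{pij} where i is the DL power and j the TC power.
#'
#' @slot form character form tag.
#' @slot coefficients named numeric vector of regression coefficients.
#' @exportClass PolynomialModel
setClass("PolynomialModel",
    representation(form = "character", coefficients = "numeric"))

setValidity("PolynomialModel", function(object) {
    if (!object@form %in% polynomialForms())
        return(paste("unknown form:", object@form))
    terms <- modelTerms(object@form)
    if (length(object@coefficients) != nrow(terms))
        return("coefficient count does not match the form's term list")
    if (any(!is.finite(object@coefficients)))
        return("coefficients must be finite")
    TRUE
})

#' Neural-network calibration model
#'
#' A single-hidden-layer network with tanh activations and a linear output
#' unit mapping standardized (DL, TC) to a standardized temperature, plus the
#' input/output centering and scaling learned from the calibration subset.
#'
#' @slot W1 hidden-layer weight matrix (hidden_size x 2).
#' @slot b1 hidden-layer biases (hidden_size).
#' @slot w2 output weights (hidden_size).
#' @slot b2 output bias (scalar).
#' @slot inputCenter,inputScale per-input standardization (DL, TC).
#' @slot outputCenter,outputScale target standardization.
#' @slot seed integer seed used for weight initialization.
#' @slot valRmse best validation RMSE seen during training (degC).
#' @slot epochs number of epochs actually run.
#' @exportClass AnnModel
setClass("AnnModel",
    representation(W1 = "matrix", b1 = "numeric", w2 = "numeric",
                   b2 = "numeric", inputCenter = "numeric",
                   inputScale = "numeric", outputCenter = "numeric",
                   outputScale = "numeric", seed = "integer",
                   valRmse = "numeric", epochs = "integer"))

setValidity("AnnModel", function(object) {
    h <- nrow(object@W1)
    if (ncol(object@W1) != 2)
        return("W1 must have 2 columns (DL, TC)")
    if (length(object@b1) != h || length(object@w2) != h)
        return("b1/w2 length must equal hidden size")
    if (length(object@b2) != 1)
        return("b2 must be scalar")
    if (length(object@inputCenter) != 2 || length(object@inputScale) != 2)
        return("input scaling must have 2 elements")
    if (any(object@inputScale == 0) || any(object@outputScale == 0))
        return("scalings must be nonzero")
    TRUE
})

#' Training configuration for the backpropagation network
#'
#' @slot hiddenSize number of tanh hidden units (default 10).
#' @slot learningRate gradient-descent step size on standardized data
#'   (default 0.05).
#' @slot momentum momentum coefficient (default 0.9).
#' @slot maxEpochs full-batch epoch budget (default 5000).
#' @slot patience epochs without validation-RMSE improvement before early
#'   stop (default 200).
#' @slot seed integer RNG seed for weight initialization.
#' @exportClass AnnTrainConfig
setClass("AnnTrainConfig",
    representation(hiddenSize = "integer", learningRate = "numeric",
                   momentum = "numeric", maxEpochs = "integer",
                   patience = "integer", seed = "integer"))

setValidity("AnnTrainConfig", function(object) {
    if (object@hiddenSize < 1) return("hiddenSize must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@maxEpochs < 1) return("maxEpochs must be >= 1")
    TRUE
})

#' @param hiddenSize,learningRate,momentum,maxEpochs,patience,seed see slots.
#' @return An [AnnTrainConfig-class] object.
#' @rdname AnnTrainConfig-class
#' @export
AnnTrainConfig <- function(hiddenSize = 10L, learningRate = 0.05,
                           momentum = 0.9, maxEpochs = 5000L,
                           patience = 200L, seed = 1L) {
    new("AnnTrainConfig", hiddenSize = as.integer(hiddenSize),
        learningRate = learningRate, momentum = momentum,
        maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
        seed = as.integer(seed))
}

#' Calibration/validation split specification
#'
#' @slot fraction calibration fraction (default 0.65).
#' @slot seed integer RNG seed.
#' @slot stratifyByTbb logical; stratify the draw within blackbody-setpoint
#'   bins so both subsets cover the whole temperature range (default TRUE).
#' @exportClass SplitSpec
setClass("SplitSpec",
    representation(fraction = "numeric", seed = "integer",
                   stratifyByTbb = "logical"))

setValidity("SplitSpec", function(object) {
    if (object@fraction <= 0 || object@fraction >= 1)
        return("fraction must be in (0, 1)")
    TRUE
})

#' @param fraction,seed,stratifyByTbb see slots.
#' @return A [SplitSpec-class] object.
#' @rdname SplitSpec-class
#' @export
SplitSpec <- function(fraction = 0.65, seed = 1L, stratifyByTbb = TRUE) {
    new("SplitSpec", fraction = fraction, seed = as.integer(seed),
        stratifyByTbb = stratifyByTbb)
}

## ---------------------------------------------------------------------------
## Diagnostics containers
## ---------------------------------------------------------------------------

#' Goodness-of-fit report
#'
#' Bundles the agreement statistics used to score a calibration model:
#' observation count, means of observed and simulated series, coefficient of
#' determination, RMSE, relative error (percent of the observed mean) and the
#' similarity (Willmott agreement) index, plus the residual series.
#'
#' @slot n observation count.
#' @slot meanObs,meanSim series means (degC).
#' @slot r2 coefficient of determination.
#' @slot rmse root mean square error (degC).
#' @slot relativeError percent.
#' @slot similarityIndex dimensionless, at most 1.
#' @slot residuals simulated minus observed, in input order.
#' @exportClass FitReport
setClass("FitReport",
    representation(n = "integer", meanObs = "numeric", meanSim = "numeric",
                   r2 = "numeric", rmse = "numeric",
                   relativeError = "numeric", similarityIndex = "numeric",
                   residuals = "numeric"))

#' Residual diagnostics of an observed-vs-simulated regression
#'
#' @slot slope,intercept least-squares fit of observed on simulated.
#' @slot slopeSE,interceptSE their standard errors.
#' @slot normalityP Shapiro-Wilk p-value for residual normality.
#' @slot normalityTest name of the normality test used.
#' @slot homoscedasticityP Breusch-Pagan p-value.
#' @slot homoscedasticityTest name of the variance-constancy test used.
#' @slot cooksDistances per-observation Cook's distances.
#' @slot outlierFlags indices with Cook's distance above the threshold.
#' @slot threshold Cook's distance flagging threshold (4/n).
#' @exportClass ResidualDiagnostics
setClass("ResidualDiagnostics",
    representation(slope = "numeric", intercept = "numeric",
                   slopeSE = "numeric", interceptSE = "numeric",
                   normalityP = "numeric", normalityTest = "character",
                   homoscedasticityP = "numeric",
                   homoscedasticityTest = "character",
                   cooksDistances = "numeric", outlierFlags = "integer",
                   threshold = "numeric"))

## ---------------------------------------------------------------------------
## Wallis filter parameters
## ---------------------------------------------------------------------------

#' Wallis filter configuration
#'
#' Window and target-statistics configuration of the adaptive local-contrast
#' filter. The filter drives each neighborhood's mean and standard deviation
#' toward \code{targetMean}/\code{targetStd}, with \code{contrast} (c) and
#' \code{brightness} (b) blending constants.
#'
#' @slot window odd neighborhood side length in pixels (default 31).
#' @slot targetMean target local mean in 8-bit working-range units
#'   (default 127).
#' @slot targetStd target local standard deviation (default 50).
#' @slot contrast contrast expansion constant c in (0, 1] (default 0.8).
#' @slot brightness brightness forcing constant b in [0, 1] (default 0.9).
#' @slot epsilon variance guard added to the denominator (default 1e-6).
#' @slot stretchLow,stretchHigh percentiles of the pre-stretch mapping raw
#'   counts to the 8-bit working range (defaults 2 and 98).
#' @exportClass WallisParams
setClass("WallisParams",
    representation(window = "integer", targetMean = "numeric",
                   targetStd = "numeric", contrast = "numeric",
                   brightness = "numeric", epsilon = "numeric",
                   stretchLow = "numeric", stretchHigh = "numeric"))

setValidity("WallisParams", function(object) {
    if (object@window < 3 || object@window %% 2 == 0)
        return("window must be odd and >= 3")
    if (object@targetStd <= 0) return("targetStd must be > 0")
    if (object@contrast <= 0 || object@contrast > 1)
        return("contrast must be in (0, 1]")
    if (object@brightness < 0 || object@brightness > 1)
        return("brightness must be in [0, 1]")
    if (object@stretchLow >= object@stretchHigh)
        return("stretchLow must be below stretchHigh")
    TRUE
})

#' @param window,targetMean,targetStd,contrast,brightness,epsilon see slots.
#' @param stretchLow,stretchHigh pre-stretch percentiles.
#' @return A [WallisParams-class] object.
#' @rdname WallisParams-class
#' @export
WallisParams <- function(window = 31L, targetMean = 127, targetStd = 50,
                         contrast = 0.8, brightness = 0.9, epsilon = 1e-6,
                         stretchLow = 2, stretchHigh = 98) {
    new("WallisParams", window = as.integer(window), targetMean = targetMean,
        targetStd = targetStd, contrast = contrast, brightness = brightness,
        epsilon = epsilon, stretchLow = stretchLow,
        stretchHigh = stretchHigh)
}

## ---------------------------------------------------------------------------
## Tie-point evaluation
## ---------------------------------------------------------------------------

#' Detected interest points of one image
#'
#' Positions are 1-based (row, col) matrix indices; scores are the Harris
#' corner responses at those positions.
#'
#' @slot coords integer matrix (n x 2) of row/col positions.
#' @slot scores numeric corner responses, descending.
#' @exportClass KeypointSet
setClass("KeypointSet",
    representation(coords = "matrix", scores = "numeric"))

#' Tie-point comparison report
#'
#' Per-pair keypoint and match counts for the raw-stretched and
#' Wallis-filtered pipelines, plus aggregate totals and the percent change.
#'
#' @slot pairs data.frame of per-pair counts.
#' @slot totalUnfiltered,totalFiltered aggregate accepted-match counts.
#' @slot percentChange percent change of filtered vs unfiltered totals.
#' @exportClass MatchReport
setClass("MatchReport",
    representation(pairs = "data.frame", totalUnfiltered = "numeric",
                   totalFiltered = "numeric", percentChange = "numeric"))

## ---------------------------------------------------------------------------
## Geo accuracy
## ---------------------------------------------------------------------------

#' Ground-control-point error table
#'
#' Signed per-GCP positional errors (estimated minus input coordinate) per
#' axis, in meters, with an optional image-space residual in pixels.
#'
#' @slot data data.frame with columns \code{gcp_id}, \code{error_x},
#'   \code{error_y}, \code{error_z} and optionally \code{image_residual}.
#' @exportClass GcpErrorTable
setClass("GcpErrorTable", representation(data = "data.frame"))

setValidity("GcpErrorTable", function(object) {
    d <- object@data
    need <- c("gcp_id", "error_x", "error_y", "error_z")
    if (!all(need %in% names(d)))
        return(paste("data must have columns", paste(need, collapse = ", ")))
    if (nrow(d) < 1) return("at least one GCP row required")
    if (any(!is.finite(d$error_x)) || any(!is.finite(d$error_y)) ||
        any(!is.finite(d$error_z)))
        return("errors must be finite")
    TRUE
})

#' @param gcp_id identifiers.
#' @param error_x,error_y,error_z signed axis errors (m).
#' @param image_residual optional image residual (pixels).
#' @return A [GcpErrorTable-class] object.
#' @rdname GcpErrorTable-class
#' @export
GcpErrorTable <- function(gcp_id, error_x, error_y, error_z,
                          image_residual = NULL) {
    d <- data.frame(gcp_id = as.character(gcp_id),
                    error_x = as.numeric(error_x),
                    error_y = as.numeric(error_y),
                    error_z = as.numeric(error_z),
                    stringsAsFactors = FALSE)
    if (!is.null(image_residual))
        d$image_residual <- as.numeric(image_residual)
    new("GcpErrorTable", data = d)
}

#' GCP accuracy summary
#'
#' Per-axis root-mean-square errors and the total 3-D positioning error
#' (root of the mean squared per-GCP 3-D error); by construction
#' \code{total3d^2 = rmsX^2 + rmsY^2 + rmsZ^2}.
#'
#' @slot rmsX,rmsY,rmsZ per-axis RMS errors (m).
#' @slot total3d total 3-D error (m).
#' @slot perGcp per-GCP 3-D errors (m).
#' @exportClass GcpSummary
setClass("GcpSummary",
    representation(rmsX = "numeric", rmsY = "numeric", rmsZ = "numeric",
                   total3d = "numeric", perGcp = "numeric"))

#' Field-versus-product temperature pairs
#'
#' One row per validation point: the reference (ground) temperature mean/SD
#' and the imagery-product temperature mean/SD, with a label and a surface
#' class (for example rain-fed vines, irrigated vines, soil).
#'
#' @slot data data.frame with columns \code{label}, \code{class},
#'   \code{ref_mean}, \code{ref_sd}, \code{prod_mean}, \code{prod_sd}.
#' @exportClass ValidationPairTable
setClass("ValidationPairTable", representation(data = "data.frame"))

setValidity("ValidationPairTable", function(object) {
    d <- object@data
    need <- c("label", "class", "ref_mean", "ref_sd", "prod_mean", "prod_sd")
    if (!all(need %in% names(d)))
        return(paste("data must have columns", paste(need, collapse = ", ")))
    if (nrow(d) < 2) return("at least two rows required")
    if (any(!is.finite(d$ref_mean)) || any(!is.finite(d$prod_mean)))
        return("temperatures must be finite")
    TRUE
})

#' @param label,class row labels and surface classes.
#' @param ref_mean,ref_sd reference temperature mean/SD (degC).
#' @param prod_mean,prod_sd product temperature mean/SD (degC).
#' @return A [ValidationPairTable-class] object.
#' @rdname ValidationPairTable-class
#' @export
ValidationPairTable <- function(label, class, ref_mean, ref_sd,
                                prod_mean, prod_sd) {
    d <- data.frame(label = as.character(label), class = as.character(class),
                    ref_mean = as.numeric(ref_mean),
                    ref_sd = as.numeric(ref_sd),
                    prod_mean = as.numeric(prod_mean),
                    prod_sd = as.numeric(prod_sd), stringsAsFactors = FALSE)
    new("ValidationPairTable", data = d)
}

## ---------------------------------------------------------------------------
## Synthetic-data configurations
## ---------------------------------------------------------------------------

#' TEC-less sensor forward-model configuration
#'
#' Parameters of the synthetic sensor used to generate blackbody campaigns:
#' counts respond to a quartic radiance proxy of the scene temperature and,
#' in the manner of an unstabilized microbolometer, drift linearly and
#' quadratically with the sensor temperature.
#'
#' @slot k1 radiance gain, counts per (K^4 x 1e-8) radiance unit.
#' @slot k2 linear sensor-temperature drift (counts/degC).
#' @slot k3 quadratic sensor-temperature drift (counts/degC^2).
#' @slot offset base counts.
#' @slot noiseSd additive Gaussian noise SD (counts).
#' @slot t0 reference sensor temperature (degC).
#' @slot seed integer RNG seed.
#' @exportClass SensorSimConfig
setClass("SensorSimConfig",
    representation(k1 = "numeric", k2 = "numeric", k3 = "numeric",
                   offset = "numeric", noiseSd = "numeric", t0 = "numeric",
                   seed = "integer"))

setValidity("SensorSimConfig", function(object) {
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
})

#' @param k1,k2,k3,offset,noiseSd,t0,seed see slots. The defaults give
#'   counts around 7000-9000 over blackbody temperatures 5-65 degC, a
#'   sensitivity near 32 counts/degC, and noise equivalent to about 0.5 degC.
#' @return A [SensorSimConfig-class] object.
#' @rdname SensorSimConfig-class
#' @export
SensorSimConfig <- function(k1 = 30, k2 = -12, k3 = -0.3, offset = 5000,
                            noiseSd = 16, t0 = 20, seed = 1L) {
    new("SensorSimConfig", k1 = k1, k2 = k2, k3 = k3, offset = offset,
        noiseSd = noiseSd, t0 = t0, seed = as.integer(seed))
}

#' Low-contrast scene-pair configuration
#'
#' The base scene is a smooth random thermal field plus many weak fine
#' texture blobs (the matchable detail), a few strong "hotspot" objects
#' (reflective targets or bare soil that dominate the dynamic range, the
#' reason raw thermal frames display so flat), and camera-fixed radial
#' vignetting.
#'
#' @slot size image side length (pixels).
#' @slot smoothAmplitude SD of the smooth background field (counts).
#' @slot textureAmplitude peak amplitude of the weak fine-texture blobs
#'   (counts).
#' @slot nTexture number of fine-texture blobs.
#' @slot hotspotAmplitude peak amplitude of the strong hotspots (counts).
#' @slot nHotspots number of hotspots.
#' @slot hotspotSigma Gaussian radius of the hotspots (pixels).
#' @slot vignettingStrength peak radial vignetting drop (counts).
#' @slot translation integer (row, col) offset of the second frame (pixels).
#' @slot noiseSd per-frame Gaussian noise SD (counts).
#' @slot baseLevel background count level.
#' @slot seed integer RNG seed.
#' @exportClass SceneSimConfig
setClass("SceneSimConfig",
    representation(size = "integer", smoothAmplitude = "numeric",
                   textureAmplitude = "numeric", nTexture = "integer",
                   hotspotAmplitude = "numeric", nHotspots = "integer",
                   hotspotSigma = "numeric",
                   vignettingStrength = "numeric", translation = "integer",
                   noiseSd = "numeric", baseLevel = "numeric",
                   seed = "integer"))

setValidity("SceneSimConfig", function(object) {
    if (object@smoothAmplitude < 0 || object@textureAmplitude < 0 ||
        object@hotspotAmplitude < 0)
        return("amplitudes must be >= 0")
    if (any(abs(object@translation) >= object@size))
        return("translation must be smaller than the image size")
    TRUE
})

#' @param size,smoothAmplitude,textureAmplitude,nTexture see slots.
#' @param hotspotAmplitude,nHotspots,hotspotSigma,vignettingStrength see
#'   slots.
#' @param translation,noiseSd,baseLevel,seed see slots.
#' @return A [SceneSimConfig-class] object.
#' @rdname SceneSimConfig-class
#' @export
SceneSimConfig <- function(size = 96L, smoothAmplitude = 60,
                           textureAmplitude = 10, nTexture = 40L,
                           hotspotAmplitude = 2500, nHotspots = 2L,
                           hotspotSigma = 1.5, vignettingStrength = 20,
                           translation = c(3L, 5L), noiseSd = 1.5,
                           baseLevel = 7000, seed = 1L) {
    new("SceneSimConfig", size = as.integer(size),
        smoothAmplitude = smoothAmplitude,
        textureAmplitude = textureAmplitude, nTexture = as.integer(nTexture),
        hotspotAmplitude = hotspotAmplitude,
        nHotspots = as.integer(nHotspots), hotspotSigma = hotspotSigma,
        vignettingStrength = vignettingStrength,
        translation = as.integer(translation), noiseSd = noiseSd,
        baseLevel = baseLevel, seed = as.integer(seed))
}
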
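#' Predict temperature from digital level and sensor temperature
#'
#' Evaluates a fitted calibration model at digital level \code{dl} (counts)
#' and sensor temperature \code{tc} (degC). Vectorizes elementwise; \code{dl}
#' and \code{tc} must be the same length or \code{tc} a scalar.
#'
#' @param model a [PolynomialModel-class] or [AnnModel-class].
#' @param dl numeric digital levels (counts).
#' @param tc numeric sensor temperatures (degC).
#' @return Numeric vector of temperatures (degC).
#' @export
setGeneric("predictTemperature",
           function(model, dl, tc) standardGeneric("predictTemperature"))

#' Apply a calibration model to a thermal frame
#'
#' Predicts a per-pixel temperature using the frame's single recorded sensor
#' temperature for TC.
#'
#' @param frame a [ThermalFrame-class].
#' @param model a fitted calibration model.
#' @return A [TemperatureMap-class] with provenance
#'   \code{"<form>:<frame_id>"}.
#' @export
setGeneric("applyModel",
           function(frame, model) standardGeneric("applyModel"))

#' Serialize a calibration model to JSON
#'
#' @param model a fitted calibration model.
#' @param path output file path.
#' @return Invisibly, the path. Reload with [loadModel()]; the reloaded
#'   model predicts identically (within 1e-12).
#' @export
setGeneric("saveModel",
           function(model, path) standardGeneric("saveModel"))

## accessors -----------------------------------------------------------------

#' @describeIn CalibrationDataset-class number of records.
#' @param object,x a CalibrationDataset.
#' @export
setGeneric("nRecords", function(object) standardGeneric("nRecords"))

#' @describeIn CalibrationDataset-class records data.frame.
#' @export
setGeneric("calRecords", function(object) standardGeneric("calRecords"))

#' @describeIn CalibrationDataset-class split labels (possibly empty).
#' @export
setGeneric("splitLabels", function(object) standardGeneric("splitLabels"))

#' @describeIn CalibrationDataset-class replace split labels.
#' @param value character vector of labels.
#' @export
setGeneric("splitLabels<-",
           function(object, value) standardGeneric("splitLabels<-"))

#' @describeIn CalibrationDataset-class subset by split label.
#' @param label "calibration" or "validation".
#' @export
setGeneric("subsetByLabel",
           function(object, label) standardGeneric("subsetByLabel"))

#' @describeIn ThermalFrame-class pixel matrix.
#' @param object a ThermalFrame.
#' @export
setGeneric("pixelMatrix", function(object) standardGeneric("pixelMatrix"))

#' @describeIn ThermalFrame-class sensor temperature (degC).
#' @export
setGeneric("sensorTemp", function(object) standardGeneric("sensorTemp"))

#' @describeIn ThermalFrame-class frame identifier.
#' @export
setGeneric("frameId", function(object) standardGeneric("frameId"))

#' @describeIn TemperatureMap-class temperature matrix (degC).
#' @param object a TemperatureMap.
#' @export
setGeneric("temps", function(object) standardGeneric("temps"))

#' @describeIn PolynomialModel-class the model form tag.
#' @param object a model object.
#' @export
setGeneric("modelForm", function(object) standardGeneric("modelForm"))
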
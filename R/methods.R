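## Accessor and show methods for the central classes.

#' @rdname CalibrationDataset-class
#' @export
setMethod("nRecords", "CalibrationDataset",
          function(object) nrow(object@records))

#' @rdname CalibrationDataset-class
#' @export
setMethod("calRecords", "CalibrationDataset",
          function(object) object@records)

#' @rdname CalibrationDataset-class
#' @export
setMethod("splitLabels", "CalibrationDataset",
          function(object) object@split)

#' @rdname CalibrationDataset-class
#' @export
setReplaceMethod("splitLabels", "CalibrationDataset",
                 function(object, value) {
    object@split <- as.character(value)
    validObject(object)
    object
})

#' @rdname CalibrationDataset-class
#' @export
setMethod("subsetByLabel", "CalibrationDataset",
          function(object, label) {
    if (length(object@split) == 0)
        stop("dataset has no split labels", call. = FALSE)
    keep <- object@split == label
    new("CalibrationDataset", records = object@records[keep, , drop = FALSE],
        split = character(), tbbRange = object@tbbRange)
})

#' @rdname ThermalFrame-class
#' @export
setMethod("pixelMatrix", "ThermalFrame", function(object) object@pixels)

#' @rdname ThermalFrame-class
#' @export
setMethod("sensorTemp", "ThermalFrame", function(object) object@sensorTemp)

#' @rdname ThermalFrame-class
#' @export
setMethod("frameId", "ThermalFrame", function(object) object@frameId)

#' @rdname TemperatureMap-class
#' @export
setMethod("temps", "TemperatureMap", function(object) object@temps)

setMethod("show", "CalibrationDataset", function(object) {
    cat("CalibrationDataset with", nrow(object@records), "records\n")
    if (nrow(object@records) > 0) {
        r <- object@records
        cat(sprintf("  dl: %.0f..%.0f counts | tc: %.1f..%.1f degC | ",
                    min(r$dl), max(r$dl), min(r$tc), max(r$tc)))
        cat(sprintf("tbb: %.1f..%.1f degC\n", min(r$tbb), max(r$tbb)))
    }
    if (length(object@split) > 0)
        cat("  split:", sum(object@split == "calibration"), "calibration /",
            sum(object@split == "validation"), "validation\n")
})

setMethod("show", "ThermalFrame", function(object) {
    cat(sprintf("ThermalFrame '%s': %d x %d pixels, sensor %.2f degC\n",
                object@frameId, nrow(object@pixels), ncol(object@pixels),
                object@sensorTemp))
})

setMethod("show", "TemperatureMap", function(object) {
    cat(sprintf(
        "TemperatureMap [%s]: %d x %d, range %.2f..%.2f degC\n",
        object@provenance, nrow(object@temps), ncol(object@temps),
        min(object@temps), max(object@temps)))
})

setMethod("show", "PolynomialModel", function(object) {
    cat("PolynomialModel form", object@form, "\n")
    print(signif(object@coefficients, 6))
})

setMethod("show", "AnnModel", function(object) {
    cat(sprintf(
        "AnnModel: %d tanh hidden units, seed %d, val RMSE %.3f degC (%d epochs)\n",
        nrow(object@W1), object@seed, object@valRmse, object@epochs))
})

setMethod("show", "FitReport", function(object) {
    cat(sprintf(
        "FitReport (n = %d): R2 %.4f | RMSE %.3f degC | RE %.2f%% | SI %.4f\n",
        object@n, object@r2, object@rmse, object@relativeError,
        object@similarityIndex))
})

setMethod("show", "ResidualDiagnostics", function(object) {
    cat(sprintf("ResidualDiagnostics: slope %.3f (SE %.3f), intercept %.3f (SE %.3f)\n",
                object@slope, object@slopeSE, object@intercept,
                object@interceptSE))
    cat(sprintf("  %s p = %.3g | %s p = %.3g | %d point(s) above Cook's 4/n\n",
                object@normalityTest, object@normalityP,
                object@homoscedasticityTest, object@homoscedasticityP,
                length(object@outlierFlags)))
})

setMethod("show", "GcpSummary", function(object) {
    cat(sprintf(
        "GcpSummary (%d GCPs): RMS X %.2f m | Y %.2f m | Z %.2f m | total 3-D %.2f m\n",
        length(object@perGcp), object@rmsX, object@rmsY, object@rmsZ,
        object@total3d))
})

setMethod("show", "MatchReport", function(object) {
    cat(sprintf(
        "MatchReport over %d pair(s): %d unfiltered vs %d filtered matches (%+.1f%%)\n",
        nrow(object@pairs), object@totalUnfiltered, object@totalFiltered,
        object@percentChange))
})
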
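## Calibration models mapping (digital level, sensor temperature) to object
## temperature: the linear/polynomial family and the apply/serialize
## machinery shared with the neural-network variant.

#' Supported polynomial form tags
#'
#' \code{LINEAR_DL} regresses on the digital level alone; \code{P1} is the
#' bivariate linear model in DL and TC; \code{P2}-\code{P4} add the
#' quadratic terms, the mixed cubic terms, and finally TC^3.
#'
#' @return Character vector of form tags.
#' @export
polynomialForms <- function() c("LINEAR_DL", "P1", "P2", "P3", "P4")

## Term list of a form: data.frame with DL power i, TC power j and the
## conventional coefficient name pij.
modelTerms <- function(form) {
    base <- list(
        LINEAR_DL = rbind(c(0, 0), c(1, 0)),
        P1 = rbind(c(0, 0), c(1, 0), c(0, 1)),
        P2 = rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 0), c(1, 1), c(0, 2)),
        P3 = rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 0), c(1, 1), c(0, 2),
                   c(3, 0), c(2, 1), c(1, 2)),
        P4 = rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 0), c(1, 1), c(0, 2),
                   c(3, 0), c(2, 1), c(1, 2), c(0, 3)))
    if (!form %in% names(base))
        stop("unknown polynomial form '", form, "'; valid forms: ",
             paste(polynomialForms(), collapse = ", "), call. = FALSE)
    m <- base[[form]]
    data.frame(i = m[, 1], j = m[, 2],
               name = sprintf("p%d%d", m[, 1], m[, 2]))
}

designMatrix <- function(form, dl, tc) {
    terms <- modelTerms(form)
    X <- vapply(seq_len(nrow(terms)),
                function(k) dl^terms$i[k] * tc^terms$j[k],
                numeric(length(dl)))
    X <- matrix(X, nrow = length(dl))
    colnames(X) <- terms$name
    X
}

#' Stratified calibration/validation split
#'
#' Assigns each record to the calibration or validation subset. With
#' stratification (the default), records are grouped into bins by their
#' rounded blackbody temperature (the setpoint) and sampled within each bin,
#' so both subsets cover the whole measured range. A bin holding a single
#' record goes to calibration with a warning. Deterministic given the seed.
#'
#' @param dataset a [CalibrationDataset-class] with at least 4 records.
#' @param spec a [SplitSpec-class].
#' @return The dataset with split labels filled in.
#' @export
splitDataset <- function(dataset, spec = SplitSpec()) {
    stopifnot(is(dataset, "CalibrationDataset"), is(spec, "SplitSpec"))
    n <- nrow(dataset@records)
    if (n < 4)
        stop("need at least 4 records to split", call. = FALSE)
    tbb <- dataset@records$tbb
    bins <- if (spec@stratifyByTbb) round(tbb) else rep(0, n)
    labels <- rep("validation", n)
    binVals <- sort(unique(bins))
    idxList <- lapply(binVals, function(b) which(bins == b))
    m <- lengths(idxList)
    single <- m == 1
    if (any(single)) {
        warning("blackbody bin(s) ",
                paste(binVals[single], collapse = ", "),
                " hold a single record; assigned to calibration")
        labels[unlist(idxList[single])] <- "calibration"
    }
    ## per-bin calibration counts by largest-remainder allocation, so the
    ## overall count hits round(fraction * n) while every multi-record bin
    ## keeps at least one record in each subset
    multi <- which(!single)
    k <- pmax(floor(spec@fraction * m[multi]), 1L)
    target <- round(spec@fraction * sum(m[multi]))
    rem <- spec@fraction * m[multi] - k
    free <- k < m[multi] - 1L
    for (b in order(-rem, seq_along(multi))) {
        if (sum(k) >= target) break
        if (free[b]) { k[b] <- k[b] + 1L; free[b] <- k[b] < m[multi][b] - 1L }
    }
    withSeed(spec@seed, {
        for (q in seq_along(multi)) {
            idx <- idxList[[multi[q]]]
            labels[idx[sample.int(length(idx), k[q])]] <- "calibration"
        }
    })
    dataset@split <- labels
    validObject(dataset)
    dataset
}

#' Fit a polynomial calibration model by least squares
#'
#' Ordinary least squares of the blackbody temperature on the form's term
#' list, solved by QR on a column-equilibrated design (each column scaled to
#' unit Euclidean norm) so that raw-count powers up to DL^3 do not degrade
#' the solution. When the dataset carries split labels only the calibration
#' subset is used; otherwise all records are.
#'
#' @param dataset a [CalibrationDataset-class].
#' @param form one of [polynomialForms()].
#' @return A [PolynomialModel-class].
#' @examples
#' d <- CalibrationDataset(dl = c(1000, 2000, 3000, 1500),
#'                         tc = c(10, 20, 15, 25),
#'                         tbb = 1 + 0.001 * c(1000, 2000, 3000, 1500) +
#'                               0.5 * c(10, 20, 15, 25))
#' coef(fitPolynomial(d, "P1"))
#' @export
fitPolynomial <- function(dataset, form = "P2") {
    stopifnot(is(dataset, "CalibrationDataset"))
    terms <- modelTerms(form)
    rec <- dataset@records
    if (length(dataset@split) > 0)
        rec <- rec[dataset@split == "calibration", , drop = FALSE]
    if (nrow(rec) < nrow(terms))
        stop("calibration subset (", nrow(rec),
             " records) smaller than the number of terms (",
             nrow(terms), ")", call. = FALSE)
    X <- designMatrix(form, rec$dl, rec$tc)
    s <- sqrt(colSums(X^2))
    s[s == 0] <- 1
    qrX <- qr(sweep(X, 2, s, "/"))
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("singular fit: design is rank-deficient; collinear term(s): ",
             paste(dropped, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qrX, rec$tbb) / s
    names(beta) <- colnames(X)
    new("PolynomialModel", form = form, coefficients = beta)
}

#' @describeIn PolynomialModel-class fitted coefficients.
#' @param object a PolynomialModel.
#' @param ... ignored.
#' @export
setMethod("coef", "PolynomialModel", function(object, ...)
    object@coefficients)

#' @rdname predictTemperature
#' @export
setMethod("predictTemperature",
          signature(model = "PolynomialModel"),
          function(model, dl, tc) {
    stopIfNotFinite(dl, "dl"); stopIfNotFinite(tc, "tc")
    if (length(tc) == 1) tc <- rep(tc, length(dl))
    if (length(tc) != length(dl))
        stop("dl and tc must have equal length (or tc scalar)",
             call. = FALSE)
    drop(designMatrix(model@form, as.numeric(dl), as.numeric(tc)) %*%
         model@coefficients)
})

#' @rdname applyModel
#' @export
setMethod("applyModel",
          signature(frame = "ThermalFrame"),
          function(frame, model) {
    p <- frame@pixels
    v <- predictTemperature(model, as.numeric(p),
                            rep(frame@sensorTemp, length(p)))
    TemperatureMap(matrix(v, nrow = nrow(p)),
                   provenance = paste0(modelForm(model), ":",
                                       frame@frameId))
})

#' @describeIn PolynomialModel-class form tag.
#' @export
setMethod("modelForm", "PolynomialModel", function(object) object@form)

## ---------------------------------------------------------------------------
## Model serialization
## ---------------------------------------------------------------------------

#' @rdname saveModel
#' @export
setMethod("saveModel", signature(model = "PolynomialModel"),
          function(model, path) {
    jsonlite::write_json(
        list(form = model@form,
             coefficients = as.list(model@coefficients)),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
})

#' @rdname saveModel
#' @export
setMethod("saveModel", signature(model = "AnnModel"),
          function(model, path) {
    jsonlite::write_json(
        list(form = "ANN",
             weights = list(W1 = unname(apply(model@W1, 1, as.list,
                                              simplify = FALSE)),
                            b1 = model@b1, w2 = model@w2, b2 = model@b2),
             scaling = list(input_center = model@inputCenter,
                            input_scale = model@inputScale,
                            output_center = model@outputCenter,
                            output_scale = model@outputScale),
             seed = model@seed),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
})

#' Load a calibration model from JSON
#'
#' @param path file written by [saveModel()].
#' @return A [PolynomialModel-class] or [AnnModel-class].
#' @export
loadModel <- function(path) {
    obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                    error = function(e)
                        stop("not a valid model JSON file: '", path, "'",
                             call. = FALSE))
    if (is.null(obj$form))
        stop("not a valid model JSON file: missing 'form'", call. = FALSE)
    if (obj$form == "ANN") {
        W1 <- do.call(rbind, lapply(obj$weights$W1, unlist))
        new("AnnModel", W1 = matrix(as.numeric(W1), ncol = 2),
            b1 = as.numeric(obj$weights$b1),
            w2 = as.numeric(obj$weights$w2),
            b2 = as.numeric(obj$weights$b2),
            inputCenter = as.numeric(obj$scaling$input_center),
            inputScale = as.numeric(obj$scaling$input_scale),
            outputCenter = as.numeric(obj$scaling$output_center),
            outputScale = as.numeric(obj$scaling$output_scale),
            seed = as.integer(obj$seed %||% 0L),
            valRmse = NA_real_, epochs = 0L)
    } else if (obj$form %in% polynomialForms()) {
        new("PolynomialModel", form = obj$form,
            coefficients = unlist(obj$coefficients))
    } else {
        stop("unknown model form tag '", obj$form, "' in '", path, "'",
             call. = FALSE)
    }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
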
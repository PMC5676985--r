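## Backpropagation neural-network calibration model: a single hidden layer
## of tanh units and a linear output, trained by full-batch gradient descent
## with momentum on the mean squared error of the standardized target.

annForwardStd <- function(W1, b1, w2, b2, Xs) {
    ## Xs: 2 x n standardized inputs; returns list(H, yhat) in std units
    H <- tanh(W1 %*% Xs + b1)          # h x n
    list(H = H, yhat = drop(crossprod(H, w2)) + b2)
}

#' Train the backpropagation calibration network
#'
#' Inputs (DL, TC) and the target temperature are standardized by the
#' calibration subset's mean and standard deviation. Weights are initialized
#' from a seeded uniform(-0.5, 0.5) draw; training is full-batch gradient
#' descent with momentum on the mean squared error. Training stops at
#' \code{maxEpochs} or when the validation RMSE has not improved for
#' \code{patience} epochs, and the returned model carries the weights with
#' the best validation RMSE seen. Deterministic given the seed.
#'
#' @param dataset a [CalibrationDataset-class] carrying split labels (see
#'   [splitDataset()]); both labels must be present.
#' @param config an [AnnTrainConfig-class].
#' @return An [AnnModel-class].
#' @export
trainAnn <- function(dataset, config = AnnTrainConfig()) {
    stopifnot(is(dataset, "CalibrationDataset"), is(config, "AnnTrainConfig"))
    if (length(dataset@split) == 0 ||
        !all(c("calibration", "validation") %in% dataset@split))
        stop("dataset must carry both calibration and validation labels; ",
             "run splitDataset() first", call. = FALSE)
    rec <- dataset@records
    cal <- rec[dataset@split == "calibration", ]
    val <- rec[dataset@split == "validation", ]

    inCenter <- c(mean(cal$dl), mean(cal$tc))
    inScale <- c(stats::sd(cal$dl), stats::sd(cal$tc))
    inScale[inScale == 0] <- 1
    outCenter <- mean(cal$tbb)
    outScale <- stats::sd(cal$tbb)
    if (outScale == 0) outScale <- 1

    std <- function(d) rbind((d$dl - inCenter[1]) / inScale[1],
                             (d$tc - inCenter[2]) / inScale[2])
    Xc <- std(cal); yc <- (cal$tbb - outCenter) / outScale
    Xv <- std(val); yv <- val$tbb
    h <- config@hiddenSize
    n <- ncol(Xc)

    withSeed(config@seed, {
        W1 <- matrix(stats::runif(h * 2, -0.5, 0.5), h, 2)
        b1 <- stats::runif(h, -0.5, 0.5)
        w2 <- stats::runif(h, -0.5, 0.5)
        b2 <- stats::runif(1, -0.5, 0.5)
    })
    vW1 <- W1 * 0; vb1 <- b1 * 0; vw2 <- w2 * 0; vb2 <- 0
    lr <- config@learningRate; mom <- config@momentum

    best <- list(rmse = Inf)
    sinceBest <- 0L
    epoch <- 0L
    valRmse <- function() {
        fw <- annForwardStd(W1, b1, w2, b2, Xv)
        sqrt(mean((fw$yhat * outScale + outCenter - yv)^2))
    }
    while (epoch < config@maxEpochs) {
        epoch <- epoch + 1L
        fw <- annForwardStd(W1, b1, w2, b2, Xc)
        e <- fw$yhat - yc                         # n
        loss <- mean(e^2)
        if (!is.finite(loss))
            stop("training diverged (non-finite loss); ",
                 "reduce learning_rate", call. = FALSE)
        dy <- 2 * e / n                           # n
        gw2 <- drop(fw$H %*% dy)                  # h
        gb2 <- sum(dy)
        dH <- outer(w2, dy)                       # h x n
        dS <- dH * (1 - fw$H^2)
        gW1 <- dS %*% t(Xc)                       # h x 2
        gb1 <- rowSums(dS)
        vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
        vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
        vw2 <- mom * vw2 - lr * gw2; w2 <- w2 + vw2
        vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2

        vr <- valRmse()
        if (vr < best$rmse - 1e-12) {
            best <- list(rmse = vr, W1 = W1, b1 = b1, w2 = w2, b2 = b2)
            sinceBest <- 0L
        } else {
            sinceBest <- sinceBest + 1L
            if (sinceBest >= config@patience) break
        }
    }
    new("AnnModel", W1 = best$W1, b1 = best$b1, w2 = best$w2,
        b2 = best$b2, inputCenter = inCenter, inputScale = inScale,
        outputCenter = outCenter, outputScale = outScale,
        seed = config@seed, valRmse = best$rmse, epochs = epoch)
}

#' @rdname predictTemperature
#' @export
setMethod("predictTemperature", signature(model = "AnnModel"),
          function(model, dl, tc) {
    stopIfNotFinite(dl, "dl"); stopIfNotFinite(tc, "tc")
    if (length(tc) == 1) tc <- rep(tc, length(dl))
    if (length(tc) != length(dl))
        stop("dl and tc must have equal length (or tc scalar)",
             call. = FALSE)
    Xs <- rbind((as.numeric(dl) - model@inputCenter[1]) / model@inputScale[1],
                (as.numeric(tc) - model@inputCenter[2]) / model@inputScale[2])
    fw <- annForwardStd(model@W1, model@b1, model@w2, model@b2, Xs)
    fw$yhat * model@outputScale + model@outputCenter
})

#' @describeIn AnnModel-class form tag ("ANN").
#' @param object an AnnModel.
#' @export
setMethod("modelForm", "AnnModel", function(object) "ANN")
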
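## Agreement statistics and residual analysis used to score and compare the
## calibration models: RMSE, R^2, relative error, similarity (agreement)
## index, and the four-part residual diagnosis (obs-vs-sim regression,
## normality, homoscedasticity, Cook's distance).

checkPaired <- function(observed, simulated) {
    if (length(observed) != length(simulated))
        stop("observed and simulated must have equal length", call. = FALSE)
    if (length(observed) == 0)
        stop("series must be nonzero length", call. = FALSE)
    stopIfNotFinite(observed, "observed")
    stopIfNotFinite(simulated, "simulated")
}

#' Root mean square error
#'
#' @param observed,simulated paired series (degC).
#' @return Scalar RMSE (degC).
#' @export
rmse <- function(observed, simulated) {
    checkPaired(observed, simulated)
    sqrt(mean((simulated - observed)^2))
}

#' Coefficient of determination
#'
#' The squared Pearson correlation between observed and simulated values,
#' computed from the covariance form directly.
#'
#' @param observed,simulated paired series, length at least 2, each with
#'   nonzero variance.
#' @return Scalar in [0, 1].
#' @export
rSquared <- function(observed, simulated) {
    checkPaired(observed, simulated)
    if (length(observed) < 2)
        stop("need at least 2 observations", call. = FALSE)
    so <- observed - mean(observed)
    ss <- simulated - mean(simulated)
    den <- sum(so^2) * sum(ss^2)
    if (den == 0)
        stop("undefined statistic: a series has zero variance",
             call. = FALSE)
    sum(so * ss)^2 / den
}

#' Relative error
#'
#' RMSE expressed as a percentage of the observed mean.
#'
#' @param rmse_value RMSE (degC).
#' @param mean_obs observed mean (degC), nonzero.
#' @return Percent.
#' @export
relativeError <- function(rmse_value, mean_obs) {
    if (mean_obs == 0)
        stop("relative error undefined for zero observed mean",
             call. = FALSE)
    100 * rmse_value / mean_obs
}

#' Similarity (agreement) index
#'
#' One minus the ratio of the summed squared prediction errors to the summed
#' squared potential errors about the observed mean. The default uses the
#' absolute-value (Willmott agreement) denominator
#' \code{sum((|S - MO| + |O - MO|)^2)}; \code{literal = TRUE} drops the
#' absolute values, a variant that can degenerate when deviations cancel.
#'
#' @param observed,simulated paired series.
#' @param literal use the signed-sum denominator instead of the
#'   absolute-value form.
#' @return Scalar at most 1 (1 for a perfect match).
#' @export
similarityIndex <- function(observed, simulated, literal = FALSE) {
    checkPaired(observed, simulated)
    mo <- mean(observed)
    den <- if (literal) sum(((simulated - mo) + (observed - mo))^2)
           else sum((abs(simulated - mo) + abs(observed - mo))^2)
    num <- sum((simulated - observed)^2)
    if (den == 0) {
        if (num == 0) return(1)
        stop("undefined statistic: zero denominator", call. = FALSE)
    }
    1 - num / den
}

#' Full goodness-of-fit report
#'
#' Bundles the agreement statistics consistently: the relative error uses
#' this report's own RMSE and observed mean.
#'
#' @param observed,simulated paired series (degC), length at least 2.
#' @return A [FitReport-class].
#' @examples
#' fitReport(observed = c(20, 25, 30), simulated = c(21, 24.5, 30.5))
#' @export
fitReport <- function(observed, simulated) {
    checkPaired(observed, simulated)
    if (length(observed) < 2)
        stop("need at least 2 observations", call. = FALSE)
    rm <- rmse(observed, simulated)
    new("FitReport", n = length(observed), meanObs = mean(observed),
        meanSim = mean(simulated),
        r2 = rSquared(observed, simulated), rmse = rm,
        relativeError = relativeError(rm, mean(observed)),
        similarityIndex = similarityIndex(observed, simulated),
        residuals = as.numeric(simulated - observed))
}

#' Residual diagnostics of the observed-vs-simulated regression
#'
#' Fits observed ~ simulated by least squares and diagnoses its residuals:
#' Shapiro-Wilk for normality, Breusch-Pagan (via \pkg{lmtest}) for variance
#' constancy, and Cook's distances with the common 4/n flagging threshold.
#'
#' @param observed,simulated paired series, n at least 4; simulated must not
#'   be constant.
#' @return A [ResidualDiagnostics-class].
#' @export
residualDiagnostics <- function(observed, simulated) {
    checkPaired(observed, simulated)
    n <- length(observed)
    if (n < 4)
        stop("need at least 4 observations", call. = FALSE)
    if (stats::sd(simulated) == 0)
        stop("undefined regression: simulated series is constant",
             call. = FALSE)
    fit <- stats::lm(observed ~ simulated)
    cf <- summary(fit)$coefficients
    cd <- stats::cooks.distance(fit)
    thr <- 4 / n
    sw <- stats::shapiro.test(stats::residuals(fit))
    bp <- lmtest::bptest(fit)
    new("ResidualDiagnostics",
        slope = cf["simulated", "Estimate"],
        intercept = cf["(Intercept)", "Estimate"],
        slopeSE = cf["simulated", "Std. Error"],
        interceptSE = cf["(Intercept)", "Std. Error"],
        normalityP = sw$p.value, normalityTest = "Shapiro-Wilk",
        homoscedasticityP = as.numeric(bp$p.value),
        homoscedasticityTest = "Breusch-Pagan (studentized)",
        cooksDistances = as.numeric(cd),
        outlierFlags = as.integer(which(cd > thr)),
        threshold = thr)
}
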
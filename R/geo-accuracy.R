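## Ground-control-point accuracy summaries and the paired field-vs-product
## temperature comparison.

#' Per-GCP total 3-D error
#'
#' Euclidean norm of the signed X/Y/Z errors. Vectorizes over rows.
#'
#' @param error_x,error_y,error_z signed axis errors (m).
#' @return 3-D error(s) in meters.
#' @examples
#' perGcpTotal(1.00, -1.12, 0.80)  # 1.70 m
#' @export
perGcpTotal <- function(error_x, error_y, error_z) {
    stopIfNotFinite(c(error_x, error_y, error_z), "errors")
    sqrt(error_x^2 + error_y^2 + error_z^2)
}

#' Summarize a GCP error table
#'
#' Per-axis RMS error (root of the mean squared signed axis error) and the
#' total 3-D positioning error, the root of the mean squared per-GCP 3-D
#' error. The total satisfies
#' \code{total3d^2 = rmsX^2 + rmsY^2 + rmsZ^2} exactly.
#'
#' @param table a [GcpErrorTable-class].
#' @return A [GcpSummary-class].
#' @export
gcpSummary <- function(table) {
    stopifnot(is(table, "GcpErrorTable"))
    d <- table@data
    if (nrow(d) == 0) stop("empty GCP table", call. = FALSE)
    per <- perGcpTotal(d$error_x, d$error_y, d$error_z)
    new("GcpSummary",
        rmsX = sqrt(mean(d$error_x^2)), rmsY = sqrt(mean(d$error_y^2)),
        rmsZ = sqrt(mean(d$error_z^2)), total3d = sqrt(mean(per^2)),
        perGcp = per)
}

#' Read a GCP error CSV
#'
#' Columns: \code{gcp_id}, \code{error_x_m}, \code{error_y_m},
#' \code{error_z_m} and optionally \code{image_residual_px}.
#'
#' @param path CSV file path.
#' @return A [GcpErrorTable-class].
#' @export
readGcpCsv <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("gcp_id", "error_x_m", "error_y_m", "error_z_m")
    missing <- setdiff(need, names(tab))
    if (length(missing) > 0)
        stop("GCP CSV is missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    GcpErrorTable(tab$gcp_id, tab$error_x_m, tab$error_y_m, tab$error_z_m,
                  image_residual = tab$image_residual_px)
}

#' Read a field-vs-product validation CSV
#'
#' Expects \code{label}, \code{class}, \code{ref_mean_c}, \code{ref_sd_c}
#' and either generic \code{prod_mean_c}/\code{prod_sd_c} columns or
#' per-product \code{corr_mean_c}/\code{corr_sd_c} and
#' \code{orig_mean_c}/\code{orig_sd_c} pairs selected with \code{column}.
#'
#' @param path CSV file path.
#' @param column which product column set to compare against the reference:
#'   \code{"corrected"} (radiometrically calibrated) or \code{"original"}.
#' @return A [ValidationPairTable-class].
#' @export
readValidationCsv <- function(path, column = c("corrected", "original")) {
    column <- match.arg(column)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "class", "ref_mean_c", "ref_sd_c")
    missing <- setdiff(need, names(tab))
    if (length(missing) > 0)
        stop("validation CSV is missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    if (all(c("prod_mean_c", "prod_sd_c") %in% names(tab))) {
        pm <- tab$prod_mean_c; ps <- tab$prod_sd_c
    } else {
        pre <- if (column == "corrected") "corr" else "orig"
        cm <- paste0(pre, "_mean_c"); cs <- paste0(pre, "_sd_c")
        if (!all(c(cm, cs) %in% names(tab)))
            stop("validation CSV is missing required column(s): ",
                 paste(setdiff(c(cm, cs), names(tab)), collapse = ", "),
                 call. = FALSE)
        pm <- tab[[cm]]; ps <- tab[[cs]]
    }
    ValidationPairTable(tab$label, tab$class, tab$ref_mean_c, tab$ref_sd_c,
                        pm, ps)
}

#' Paired field-versus-product temperature statistics
#'
#' Compares the product temperature means against the reference (ground)
#' means: RMSE of the differences, maximum absolute difference, sample
#' (n - 1) standard deviation of the differences, mean bias, and the full
#' [fitReport()] of the paired means.
#'
#' @param table a [ValidationPairTable-class].
#' @return List with components \code{rmse}, \code{maxAbsDiff},
#'   \code{sdDiff}, \code{meanBias}, \code{report} (a
#'   [FitReport-class]), and \code{n}.
#' @export
validationCompare <- function(table) {
    stopifnot(is(table, "ValidationPairTable"))
    d <- table@data
    diff <- d$prod_mean - d$ref_mean
    list(rmse = rmse(d$ref_mean, d$prod_mean),
         maxAbsDiff = max(abs(diff)),
         sdDiff = stats::sd(diff),
         meanBias = mean(diff),
         report = fitReport(d$ref_mean, d$prod_mean),
         n = nrow(d))
}
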
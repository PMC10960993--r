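#' Calibration / prediction error metrics
#'
#' Figures of merit for predicted vs actual concentrations: bias is the
#' mean signed residual, rmse is sqrt(sum(e^2)/n) (reported as RMSEC on the
#' calibration set and RMSEP on an independent validation set), and sec is
#' the bias-corrected standard error sqrt(sum((e - bias)^2)/(n - 1)).
#'
#' @param actual,predicted numeric vectors of equal length >= 2, ng/mL.
#' @param context \code{"calibration"} or \code{"prediction"}; controls the
#'   rmse label in the returned list.
#' @return list with \code{rmse}, \code{sec}, \code{bias} and the
#'   context-specific alias (\code{rmsec} or \code{rmsep}).
#' @export
error_metrics <- function(actual, predicted,
                          context = c("calibration", "prediction")) {
  context <- match.arg(context)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (length(actual) < 2)
    stop("insufficient data: need at least 2 points")
  e <- predicted - actual
  bias <- mean(e)
  rmse <- sqrt(mean(e^2))
  sec <- sqrt(sum((e - bias)^2) / (length(e) - 1))
  out <- list(rmse = rmse, sec = sec, bias = bias)
  out[[if (context == "calibration") "rmsec" else "rmsep"]] <- rmse
  out
}

#' Linearity diagnostics of predicted vs actual
#'
#' Ordinary least squares of predicted on actual plus the Pearson
#' correlation; \code{r_squared} is the squared correlation.
#'
#' @param actual,predicted numeric vectors, >= 3 points, actual with
#'   nonzero variance.
#' @return list with \code{slope}, \code{intercept}, \code{r},
#'   \code{r_squared}.
#' @export
linearity_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 3)
    stop("insufficient data: need >= 3 paired points")
  if (stats::var(actual) <= 0)
    stop("degenerate fit: actual values have zero variance")
  slope <- stats::cov(actual, predicted) / stats::var(actual)
  intercept <- mean(predicted) - slope * mean(actual)
  r <- stats::cor(actual, predicted)
  list(slope = slope, intercept = intercept, r = r, r_squared = r^2)
}

#' Spiked-sample recovery table
#'
#' Recovery percent is 100 * found / added per row (rounded to 2 decimals
#' for reporting); the summary gives the arithmetic mean of the row
#' recoveries and their relative standard deviation
#' (100 * sd / mean, sample sd).
#'
#' @param added,found numeric vectors of equal length, ng/mL;
#'   \code{added} strictly positive.
#' @return list with \code{rows} (data.frame added / found / recovery),
#'   \code{mean_recovery}, \code{rsd} (NA for a single row).
#' @export
recovery_table <- function(added, found) {
  if (length(added) != length(found))
    stop("added and found must have equal length")
  if (any(added <= 0))
    stop("domain error: added concentrations must be positive")
  rec <- round(100 * found / added, 2)
  mean_rec <- mean(rec)
  rsd <- if (length(rec) > 1) 100 * stats::sd(rec) / mean_rec else NA_real_
  list(rows = data.frame(added = added, found = found, recovery = rec),
       mean_recovery = mean_rec, rsd = rsd)
}

#' Enhancement factor of a coated substrate
#'
#' Concentration-normalised intensity ratio of the surface-enhanced
#' measurement to the normal (uncoated) one:
#' EF = (I_seira / C_seira) / (I_normal / C_normal). All four inputs must
#' be strictly positive.
#'
#' @param i_seira,i_normal band intensity (absorbance) on the coated and
#'   uncoated substrate.
#' @param c_seira,c_normal concentration (ng/mL) of the corresponding
#'   samples.
#' @return unitless enhancement factor.
#' @export
enhancement_factor <- function(i_seira, c_seira, i_normal, c_normal) {
  vals <- c(i_seira, c_seira, i_normal, c_normal)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("domain error: all enhancement-factor inputs must be positive")
  (i_seira / c_seira) / (i_normal / c_normal)
}

#' Band intensity at a named wavenumber
#'
#' Reads the absorbance at the grid point closest to the requested
#' wavenumber, optionally after subtracting the spectrum minimum as a flat
#' baseline. Default band 1640 cm-1, the C=N stretch shared by both
#' analytes.
#'
#' @param sp a \code{\link{spectrum}}.
#' @param wavenumber target band position, cm-1.
#' @param baseline_correct subtract the spectrum minimum first.
#' @return absorbance value.
#' @export
band_intensity <- function(sp, wavenumber = 1640, baseline_correct = TRUE) {
  stopifnot(inherits(sp, "spectrum"))
  i <- which.min(abs(as.numeric(sp$grid) - wavenumber))
  v <- sp$absorbance[i]
  if (baseline_correct) v <- v - min(sp$absorbance)
  v
}
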
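#' Fit the SEIRA-PLSR calibration model
#'
#' Front-end for the whole calibration workflow: preprocesses the
#' calibration spectra (region exclusion, Savitzky-Golay derivative),
#' selects the latent-variable count by cross-validated RMSECV (unless
#' fixed via \code{lv}), fits the NIPALS PLSR at that count and computes
#' the calibration figures of merit per analyte.
#'
#' @param spectra calibration \code{\link{spectrum_set}}.
#' @param design matching \code{\link{design_table}} (ng/mL).
#' @param config a \code{\link{preprocess_config}}.
#' @param lv fixed latent-variable count; NULL (default) selects by
#'   cross-validation.
#' @param max_lv largest candidate LV count for cross-validation.
#' @param cv cross-validation scheme, \code{"loo"} (default, one sample
#'   omitted at a time) or \code{"kfold"}.
#' @param rule LV selection rule, \code{"one_se"} (default: smallest LV
#'   count within one standard error of the RMSECV minimum, the usual
#'   parsimony rule for near-flat curves) or \code{"global_min"}; see
#'   \code{\link{select_lv}}.
#' @param seed seed for random fold assignment under \code{"kfold"}.
#' @return an object of class \code{"seira_plsr"}: the \code{fit}
#'   (\code{\link{plsr_fit}}), the \code{cv} curve (\code{\link{plsr_cv}},
#'   NULL when \code{lv} was fixed), the preprocessing \code{config}, the
#'   training \code{design}, fitted values, residuals and per-analyte
#'   calibration \code{metrics}.
#'
#' @examples
#' cal <- multilevel_design(2, 5, 15, 240)
#' ds <- simulate_dataset(cal, replicates = 3)
#' fit <- seira_plsr(ds$spectra, ds$design, max_lv = 5)
#' fit$n_lv
#' summary(fit)
#' @export
seira_plsr <- function(spectra, design, config = preprocess_config(),
                       lv = NULL, max_lv = 10, cv = c("loo", "kfold"),
                       rule = c("one_se", "global_min"), seed = 1L) {
  cv <- match.arg(cv); rule <- match.arg(rule)
  stopifnot(inherits(spectra, "spectrum_set"),
            inherits(design, "design_table"))
  if (!identical(spectra$sample_ids, design$sample_ids))
    stop("alignment error: spectra and design sample ids differ")
  pm <- preprocess(spectra, config)
  cv_res <- NULL
  if (is.null(lv)) {
    cv_res <- plsr_cv(pm, design, lv_grid = seq_len(max_lv), scheme = cv,
                      seed = seed)
    lv <- select_lv(cv_res, rule)
  }
  fit <- plsr_fit(pm, design, n_lv = lv)
  fitted_vals <- predict(fit, pm)
  resid <- fitted_vals - design$concentrations
  metrics <- lapply(seq_along(design$analyte_names), function(j) {
    c(error_metrics(design$concentrations[, j], fitted_vals[, j],
                    "calibration"),
      linearity_metrics(design$concentrations[, j], fitted_vals[, j]))
  })
  names(metrics) <- design$analyte_names
  structure(list(fit = fit, cv = cv_res, config = config, design = design,
                 n_lv = fit$n_lv, fitted = fitted_vals, residuals = resid,
                 metrics = metrics, call = match.call()),
            class = "seira_plsr")
}

#' @export
print.seira_plsr <- function(x, ...) {
  cat("SEIRA-PLSR calibration model\n")
  cat(sprintf("  samples: %d   features after preprocessing: %d\n",
              nrow(x$design$concentrations), length(x$fit$x_mean)))
  cat(sprintf("  latent variables: %d%s\n", x$n_lv,
              if (is.null(x$cv)) " (fixed)" else " (selected by RMSECV)"))
  cat("  analytes:", paste(x$fit$analyte_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.seira_plsr <- function(object, ...) {
  tab <- sapply(object$metrics, function(m)
    c(RMSEC = m$rmsec, SEC = m$sec, Bias = m$bias, Slope = m$slope,
      Intercept = m$intercept, r = m$r, R2 = m$r_squared))
  structure(list(model = object, table = tab),
            class = "summary.seira_plsr")
}

#' @export
print.summary.seira_plsr <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$cv)) {
    cat("\nRMSECV (pooled) by latent-variable count:\n")
    print(round(stats::setNames(x$model$cv$overall,
                                paste0("lv", x$model$cv$lv_grid)), 4))
  }
  cat("\nCalibration figures of merit (concentrations in ng/mL):\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.seira_plsr <- function(object, ...) object$fit$coefficients

#' @export
fitted.seira_plsr <- function(object, ...) object$fitted

#' @export
residuals.seira_plsr <- function(object, ...) object$residuals

#' Predict concentrations for new spectra
#'
#' New spectra are preprocessed with the model's stored configuration and
#' passed through the PLSR regression vector. Predictions may be negative;
#' any negative value is flagged via the \code{"negative"} attribute rather
#' than clipped.
#'
#' @param object a \code{\link{seira_plsr}} model.
#' @param newdata a \code{\link{spectrum_set}} on the training grid, or an
#'   already-preprocessed \code{\link{processed_matrix}}.
#' @param ... unused.
#' @return matrix of predicted concentrations (ng/mL) with attribute
#'   \code{"negative"}: logical matrix marking negative predictions.
#' @export
predict.seira_plsr <- function(object, newdata, ...) {
  pm <- if (inherits(newdata, "spectrum_set"))
    preprocess(newdata, object$config) else newdata
  pred <- predict(object$fit, pm)
  attr(pred, "negative") <- pred < 0
  pred
}

#' Plot the cross-validation curve and calibration fit
#'
#' Left panel: pooled RMSECV versus latent-variable count with the chosen
#' count marked. Right panel: predicted vs actual concentrations on the
#' calibration set, one colour per analyte, with the identity line.
#'
#' @param x a \code{\link{seira_plsr}} model.
#' @param ... passed to \code{plot}.
#' @export
plot.seira_plsr <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$cv)) 1 else 2))
  on.exit(graphics::par(op))
  if (!is.null(x$cv)) {
    plot(x$cv$lv_grid, x$cv$overall, type = "b", xlab = "latent variables",
         ylab = "RMSECV (ng/mL)", main = "LV selection", ...)
    graphics::abline(v = x$n_lv, lty = 2)
  }
  actual <- x$design$concentrations
  cols <- seq_along(x$fit$analyte_names)
  plot(range(actual), range(actual), type = "n",
       xlab = "actual (ng/mL)", ylab = "predicted (ng/mL)",
       main = "calibration fit")
  for (j in cols)
    graphics::points(actual[, j], x$fitted[, j], col = j, pch = 16)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("topleft", legend = x$fit$analyte_names, col = cols,
                   pch = 16, bty = "n")
  invisible(x)
}

#' Full validation metrics report
#'
#' Combines the model's calibration figures of merit with prediction-set
#' metrics (RMSEP, bias, linearity) and, when spike levels are supplied,
#' a recovery table per analyte.
#'
#' @param model a \code{\link{seira_plsr}}.
#' @param val_spectra,val_design optional validation set.
#' @return list of class \code{"metrics_report"} keyed by analyte, each
#'   entry holding calibration and (if available) prediction metrics.
#' @export
metrics_report <- function(model, val_spectra = NULL, val_design = NULL) {
  stopifnot(inherits(model, "seira_plsr"))
  analytes <- model$fit$analyte_names
  rep_list <- lapply(analytes, function(a)
    list(calibration = model$metrics[[a]]))
  names(rep_list) <- analytes
  if (!is.null(val_spectra)) {
    stopifnot(inherits(val_design, "design_table"))
    pred <- predict(model, val_spectra)
    for (j in seq_along(analytes)) {
      actual <- val_design$concentrations[, j]
      rep_list[[j]]$prediction <-
        c(error_metrics(actual, pred[, j], "prediction"),
          linearity_metrics(actual, pred[, j]),
          recovery_table(actual, pred[, j])[c("mean_recovery", "rsd")])
    }
    attr(rep_list, "validation_predictions") <- pred
  }
  class(rep_list) <- "metrics_report"
  rep_list
}

#' @export
print.metrics_report <- function(x, ...) {
  for (a in names(x)) {
    cat("==", a, "==\n")
    for (ctx in names(x[[a]])) {
      v <- unlist(x[[a]][[ctx]])
      cat(sprintf("  %s: %s\n", ctx,
                  paste(names(v), round(v, 4), sep = "=", collapse = "  ")))
    }
  }
  invisible(x)
}
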
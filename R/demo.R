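#' Serialize / restore a fitted model
#'
#' The model (PLSR fit plus its preprocessing configuration) is written as
#' JSON at full double precision so that predictions from a restored model
#' are bit-identical.
#'
#' @param model a \code{\link{seira_plsr}} model.
#' @param path destination file.
#' @return \code{write_model}: the path, invisibly; \code{read_model}: a
#'   \code{\link{seira_plsr}} object (without cross-validation history).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "seira_plsr"))
  fit <- model$fit
  payload <- list(
    format = "seirapls-model",
    n_lv = fit$n_lv,
    analyte_names = fit$analyte_names,
    feature_wavenumbers = fit$feature_wavenumbers,
    x_mean = fit$x_mean, y_mean = as.numeric(fit$y_mean),
    weights = fit$weights, x_loadings = fit$x_loadings,
    y_loadings = fit$y_loadings,
    coefficients = unname(fit$coefficients),
    config = list(
      excluded_regions = model$config$excluded_regions,
      sg_window = model$config$sg_window,
      sg_polyorder = model$config$sg_polyorder,
      sg_derivative = model$config$sg_derivative))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("format error: ",
                                         conditionMessage(e)))
  if (!identical(p$format, "seirapls-model"))
    stop("format error: not a serialized SEIRA-PLSR model")
  m <- length(p$analyte_names)
  coefs <- matrix(p$coefficients, ncol = m,
                  dimnames = list(NULL, p$analyte_names))
  n_lv <- as.integer(p$n_lv)
  fit <- structure(list(
    x_mean = p$x_mean, y_mean = p$y_mean,
    weights = matrix(p$weights, ncol = n_lv),
    x_loadings = matrix(p$x_loadings, ncol = n_lv),
    y_loadings = matrix(p$y_loadings, ncol = n_lv),
    scores = NULL,
    coefficients = coefs,
    coef_by_lv = stats::setNames(rep(list(NULL), n_lv), NULL),
    n_lv = n_lv, analyte_names = p$analyte_names,
    feature_wavenumbers = p$feature_wavenumbers), class = "plsr_fit")
  fit$coef_by_lv[[n_lv]] <- coefs
  config <- preprocess_config(
    excluded_regions = lapply(seq_len(nrow(p$config$excluded_regions)),
                              function(i) p$config$excluded_regions[i, ]),
    sg_window = p$config$sg_window, sg_polyorder = p$config$sg_polyorder,
    sg_derivative = p$config$sg_derivative)
  structure(list(fit = fit, cv = NULL, config = config, design = NULL,
                 n_lv = n_lv, fitted = NULL, residuals = NULL,
                 metrics = NULL, call = NULL),
            class = "seira_plsr")
}

#' Run the full simulated SEIRA-PLSR protocol
#'
#' End-to-end demonstration on synthetic data: a 25-mixture multilevel
#' factorial calibration set and a 10-mixture random validation set over
#' 15-240 ng/mL are simulated on a gold-coated substrate in a plasma
#' background (each mixture scan-averaged), the calibration model is fitted
#' with leave-one-out latent-variable selection, the validation set is
#' predicted, spiked-plasma samples at the reported blood-level
#' concentrations (26, 100 and 236 ng/mL) are quantified, and
#' silver/gold enhancement factors are measured against an uncoated
#' substrate. When \code{out_dir} is given, all tables, the model and a
#' run log are written there deterministically.
#'
#' @param seed single integer governing every stochastic step.
#' @param out_dir optional output directory (created if missing).
#' @param noise a \code{\link{noise_model}} (its seed is overridden by
#'   \code{seed}).
#' @param replicates scans averaged per mixture.
#' @param max_lv largest candidate LV count.
#' @param n_validation validation mixtures.
#' @param spike_levels matrix of spiked-plasma concentrations
#'   (samples x analytes, ng/mL).
#' @return list with the fitted \code{model}, the \code{report}
#'   (\code{\link{metrics_report}} incl. validation), \code{recovery} per
#'   analyte for the spiked samples, \code{ef} (gold and silver enhancement
#'   factors) and the selected \code{n_lv}.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL,
                     noise = noise_model(), replicates = 45L,
                     max_lv = 10, n_validation = 10,
                     spike_levels = cbind(BIS = c(26, 100, 236),
                                          metabolite = c(236, 100, 26))) {
  seed <- as.integer(seed)
  grid <- wn_grid(4500, 400, 1.95)
  substrate <- substrate_profile("gold")
  plasma <- plasma_background()
  noise$seed <- seed

  cal_design <- multilevel_design(2, 5, 15, 240)
  val_design <- validation_design(n_validation, cal_design$analyte_names,
                                  15, 240, seed = seed + 1L)
  cal <- simulate_dataset(cal_design, substrate, plasma, noise, grid,
                          replicates)
  noise_val <- noise; noise_val$seed <- seed + 2L
  val <- simulate_dataset(val_design, substrate, plasma, noise_val, grid,
                          replicates)

  model <- seira_plsr(cal$spectra, cal_design, max_lv = max_lv)
  report <- metrics_report(model, val$spectra, val_design)

  # spiked plasma at the reported blood-level concentrations
  spike_design <- design_table(sprintf("spike%02d", seq_len(nrow(spike_levels))),
                               cal_design$analyte_names, spike_levels)
  noise_spk <- noise; noise_spk$seed <- seed + 3L
  spk <- simulate_dataset(spike_design, substrate, plasma, noise_spk, grid,
                          replicates)
  spk_pred <- predict(model, spk$spectra)
  recovery <- lapply(seq_along(cal_design$analyte_names), function(j)
    recovery_table(spike_levels[, j], spk_pred[, j]))
  names(recovery) <- cal_design$analyte_names

  ef <- demo_enhancement_factors(grid)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_spectra_csv(cal$spectra, file.path(out_dir, "calibration_spectra.csv"))
    write_spectra_csv(val$spectra, file.path(out_dir, "validation_spectra.csv"))
    write_design_csv(cal_design, file.path(out_dir, "calibration_design.csv"))
    write_design_csv(val_design, file.path(out_dir, "validation_design.csv"))
    write_model(model, file.path(out_dir, "model.json"))
    rep_json <- list(seed = seed, n_lv = model$n_lv,
                     metrics = lapply(report, function(x) x),
                     recovery = lapply(recovery, function(r)
                       list(rows = r$rows, mean_recovery = r$mean_recovery,
                            rsd = r$rsd)),
                     enhancement_factors = ef)
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, na = "null")
    writeLines(c(
      sprintf("seed: %d", seed),
      sprintf("grid: 4500 -> 400 cm-1, step 1.95 (%d points)", length(grid)),
      sprintf("substrate: gold, gain %.1f", substrate$gain),
      sprintf("replicates averaged: %d", replicates),
      sprintf("noise relative sigma: %g", noise$relative_sigma),
      sprintf("features after preprocessing: %d", length(model$fit$x_mean)),
      sprintf("selected latent variables: %d", model$n_lv)),
      file.path(out_dir, "run_log.txt"))
  }
  list(model = model, report = report, recovery = recovery, ef = ef,
       n_lv = model$n_lv, validation_predictions =
         attr(report, "validation_predictions"))
}

# gold and silver enhancement factors measured from noiseless simulations
# of the same mixture on coated vs uncoated substrates
demo_enhancement_factors <- function(grid = wn_grid(4500, 400, 1.95),
                                     conc = c(BIS = 100, metabolite = 100)) {
  models <- list(preset_band_model("BIS"), preset_band_model("metabolite"))
  quiet <- noise_model(0, 0, 0)
  off <- plasma_background(enabled = FALSE)
  sim <- function(metal) simulate_spectrum(
    conc, models, substrate_profile(metal), off, quiet, grid)
  i_none <- band_intensity(sim("none"))
  list(
    gold = enhancement_factor(band_intensity(sim("gold")), conc[["BIS"]],
                              i_none, conc[["BIS"]]),
    silver = enhancement_factor(band_intensity(sim("silver")), conc[["BIS"]],
                                i_none, conc[["BIS"]]))
}

#' Predict concentrations from saved artifacts
#'
#' Loads a serialized model and a spectra CSV, preprocesses the spectra
#' with the model's stored configuration and writes (or returns) the
#' predicted concentration table. Negative predictions are flagged, not
#' clipped.
#'
#' @param model_file path to a JSON model from \code{\link{write_model}}.
#' @param spectra_file path to a wide spectra CSV.
#' @param out_file optional destination for the predicted concentration
#'   CSV.
#' @return a data.frame with \code{sample_id} and one
#'   \code{<analyte>_ng_per_mL} column per analyte, plus attribute
#'   \code{"negative"} (logical matrix flagging negative predictions).
#' @export
run_predict <- function(model_file, spectra_file, out_file = NULL) {
  model <- read_model(model_file)
  spectra <- read_spectra_csv(spectra_file)
  pred <- predict(model, spectra)
  out <- data.frame(sample_id = spectra$sample_ids)
  for (j in seq_along(model$fit$analyte_names))
    out[[paste0(model$fit$analyte_names[j], "_ng_per_mL")]] <- pred[, j]
  attr(out, "negative") <- attr(pred, "negative")
  if (!is.null(out_file))
    utils::write.csv(format(out, digits = 15, trim = TRUE), out_file,
                     row.names = FALSE, quote = FALSE)
  out
}
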
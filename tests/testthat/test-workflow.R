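# end-to-end workflow: front-end model object, serialization, demo runs

test_that("the fitted model object exposes the standard methods", {
  d <- multilevel_design(2, 5, 15, 240, analyte_names = c("A", "B"))
  ds <- toy_dataset(d, noise = noise_model(0.002, 1, 0.001, seed = 2),
                    replicates = 3)
  cfg <- preprocess_config(excluded_regions = list())
  model <- seira_plsr(ds$spectra, d, config = cfg, max_lv = 5)

  expect_s3_class(model, "seira_plsr")
  expect_identical(dim(coef(model)),
                   c(length(model$fit$x_mean), 2L))
  expect_equal(unname(fitted(model) - residuals(model)),
               unname(d$concentrations))
  expect_output(print(model), "SEIRA-PLSR")
  expect_output(print(summary(model)), "RMSEC")

  pred <- predict(model, ds$spectra)
  expect_identical(dim(attr(pred, "negative")), dim(pred))
  attr(pred, "negative") <- NULL
  expect_equal(unname(pred), unname(fitted(model)))

  # plot method draws without error
  tf <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(tf)
  expect_silent(plot(model))
  grDevices::dev.off()
})

test_that("noiseless calibration is recovered essentially exactly", {
  d <- multilevel_design(2, 5, 15, 240, analyte_names = c("A", "B"))
  ds <- toy_dataset(d)
  model <- seira_plsr(ds$spectra, d,
                      config = preprocess_config(excluded_regions = list()),
                      max_lv = 4)
  expect_identical(model$n_lv, 2L)
  for (a in c("A", "B")) {
    expect_lt(model$metrics[[a]]$rmsec, 1e-6)
    expect_lt(abs(model$metrics[[a]]$bias), 1e-8)
    expect_equal(model$metrics[[a]]$slope, 1, tolerance = 1e-6)
    expect_equal(model$metrics[[a]]$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("models survive a JSON round trip bit-for-bit", {
  d <- multilevel_design(2, 5, 15, 240)
  ds <- simulate_dataset(d, replicates = 2,
                         noise = noise_model(seed = 4))
  model <- seira_plsr(ds$spectra, d, lv = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  m2 <- read_model(path)
  expect_identical(m2$n_lv, model$n_lv)
  expect_equal(m2$fit$coefficients, model$fit$coefficients)
  expect_equal(unname(predict(m2, ds$spectra)),
               unname(predict(model, ds$spectra)))
  expect_error(read_model(withr::local_tempfile(fileext = ".json")),
               "file not found")
})

test_that("run_predict works from saved artifacts and flags grid problems", {
  d <- multilevel_design(2, 5, 15, 240)
  ds <- simulate_dataset(d, replicates = 2, noise = noise_model(seed = 6))
  model <- seira_plsr(ds$spectra, d, lv = 2)
  mpath <- withr::local_tempfile(fileext = ".json")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_model(model, mpath)
  write_spectra_csv(ds$spectra, spath)

  pred <- run_predict(mpath, spath)
  expect_identical(pred$sample_id, d$sample_ids)
  # centering: mean residual on the calibration spectra is zero
  for (j in seq_along(d$analyte_names)) {
    res <- pred[[paste0(d$analyte_names[j], "_ng_per_mL")]] -
      d$concentrations[, j]
    expect_lt(abs(mean(res)), 1e-8)
  }

  # spectra on a truncated grid are refused
  tg <- wn_grid(4500, 1000, 1.95)
  trunc <- spectrum_set(tg, ds$spectra$matrix[, seq_along(tg)],
                        d$sample_ids)
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(trunc, tpath)
  expect_error(run_predict(mpath, tpath), "grid mismatch")
})

test_that("the demo protocol runs deterministically end to end", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- run_demo(seed = 3, out_dir = out1, replicates = 2, max_lv = 6,
                 n_validation = 4)
  r2 <- run_demo(seed = 3, out_dir = out2, replicates = 2, max_lv = 6,
                 n_validation = 4)

  expect_identical(r1$n_lv, r2$n_lv)
  for (f in c("report.json", "model.json", "calibration_design.csv",
              "calibration_spectra.csv", "run_log.txt"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))

  # report covers both analytes with calibration and prediction blocks
  for (a in c("BIS", "metabolite")) {
    expect_true(all(c("calibration", "prediction") %in% names(r1$report[[a]])))
    expect_true(r1$report[[a]]$calibration$rmsec >= 0)
  }
  expect_equal(r1$ef$gold, 3.0)
  expect_equal(r1$ef$silver, 2.0)
  expect_identical(nrow(r1$recovery$BIS$rows), 3L)
})
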
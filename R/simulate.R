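#' Simulate one SEIRA absorbance spectrum
#'
#' Forward model: absorbance(v) = gain * sum over analytes of
#' c_a * k_a * sum of Gaussian bands (shifted by the substrate band shift)
#' + plasma background + random polynomial baseline + iid Gaussian noise.
#' The concentration response is linear (Beer-Lambert); the substrate gain
#' multiplies only the analyte signal, not the plasma matrix. Deterministic
#' given the noise model's seed.
#'
#' @param concentrations named numeric vector, ng/mL per analyte (>= 0).
#' @param models list of \code{\link{band_model}} covering every analyte
#'   named in \code{concentrations}.
#' @param substrate a \code{\link{substrate_profile}}.
#' @param plasma a \code{\link{plasma_background}}.
#' @param noise a \code{\link{noise_model}}.
#' @param grid a \code{\link{wn_grid}}.
#' @param sample_id label for the resulting spectrum.
#' @param seed optional override of the noise model's seed.
#' @return a \code{\link{spectrum}}.
#' @export
simulate_spectrum <- function(concentrations, models, substrate, plasma,
                              noise, grid, sample_id = "sim", seed = NULL) {
  stopifnot(inherits(substrate, "substrate_profile"),
            inherits(plasma, "plasma_background"),
            inherits(noise, "noise_model"))
  if (!inherits(grid, "wn_grid")) grid <- as_wn_grid(grid)
  if (any(concentrations < 0))
    stop("domain error: concentrations must be nonnegative")
  model_names <- vapply(models, `[[`, character(1), "analyte_name")
  wn <- as.numeric(grid)
  clean <- numeric(length(wn))
  for (a in names(concentrations)) {
    j <- match(a, model_names)
    if (is.na(j)) stop("unknown component: no band model for '", a, "'")
    m <- models[[j]]
    clean <- clean + concentrations[[a]] * m$response_coefficient *
      gaussian_bands(wn, m$bands, shift = substrate$band_shift)
  }
  clean <- substrate$gain * clean
  if (plasma$enabled)
    clean <- clean + gaussian_bands(wn, plasma$bands)
  eps <- sim_noise(noise, wn, max_clean = max(clean, 0),
                   seed = if (is.null(seed)) noise$seed else seed)
  spectrum(grid, clean + eps, sample_id)
}

# additive noise realization: polynomial baseline + white Gaussian noise,
# fully determined by `seed`
sim_noise <- function(noise, wn, max_clean, seed) {
  n <- length(wn)
  if (noise$relative_sigma == 0 && noise$baseline_scale == 0)
    return(numeric(n))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  out <- numeric(n)
  if (noise$baseline_scale > 0) {
    u <- seq(0, 1, length.out = n)
    coefs <- stats::rnorm(noise$baseline_order + 1L, 0, noise$baseline_scale)
    for (k in seq_along(coefs)) out <- out + coefs[k] * u^(k - 1L)
  }
  if (noise$relative_sigma > 0)
    out <- out + stats::rnorm(n, 0, noise$relative_sigma * max_clean)
  out
}

#' Simulate a full mixture dataset
#'
#' One spectrum per row of the concentration design; each mixture is
#' simulated \code{replicates} times with distinct deterministic sub-seeds
#' and the replicate scans averaged, mimicking instrument scan averaging.
#'
#' @param design a \code{\link{design_table}} (sample x analyte, ng/mL).
#' @param substrate,plasma,noise,grid forward-model components, see
#'   \code{\link{simulate_spectrum}}.
#' @param replicates number of scans to average per mixture (>= 1).
#' @param models band models; defaults to the two preset analyte models
#'   matching the design's analyte names when those are BIS/metabolite.
#' @return list with elements \code{spectra} (a
#'   \code{\link{spectrum_set}}, rows matching the design sample ids) and
#'   \code{design} (the input design, unchanged).
#' @export
simulate_dataset <- function(design, substrate = substrate_profile("gold"),
                             plasma = plasma_background(),
                             noise = noise_model(),
                             grid = wn_grid(4500, 400, 1.95),
                             replicates = 45L, models = NULL) {
  stopifnot(inherits(design, "design_table"))
  if (nrow(design$concentrations) == 0) stop("empty design")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!inherits(grid, "wn_grid")) grid <- as_wn_grid(grid)
  if (is.null(models))
    models <- lapply(design$analyte_names, preset_band_model)
  mat <- matrix(0, nrow(design$concentrations), length(grid))
  for (i in seq_len(nrow(design$concentrations))) {
    conc <- design$concentrations[i, ]
    names(conc) <- design$analyte_names
    reps <- lapply(seq_len(replicates), function(r) {
      sub_seed <- (noise$seed + 7919 * i + r) %% .Machine$integer.max
      simulate_spectrum(conc, models, substrate, plasma, noise, grid,
                        sample_id = design$sample_ids[i], seed = sub_seed)
    })
    mat[i, ] <- average_scans(reps)$absorbance
  }
  list(spectra = spectrum_set(grid, mat, design$sample_ids),
       design = design)
}
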
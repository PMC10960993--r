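# shared fixtures: everything is generated in code at test time

# a noise model that contributes nothing (no baseline, no white noise)
quiet_noise <- function(seed = 1L) noise_model(0, 0, 0, seed = seed)

# small fast grid for unit tests (201 points)
small_grid <- function() wn_grid(3500, 1500, 10)

# two synthetic band models with overlapping bands on the small grid
toy_models <- function() list(
  band_model("A", data.frame(center = c(2800, 2000), fwhm = 60,
                             amplitude = 1), response_coefficient = 0.002),
  band_model("B", data.frame(center = c(2400, 2000), fwhm = 60,
                             amplitude = 1), response_coefficient = 0.002))

# simulate a noiseless toy dataset on the small grid for a given design
toy_dataset <- function(design, noise = quiet_noise(), replicates = 1,
                        plasma = plasma_background(enabled = FALSE),
                        substrate = substrate_profile("none")) {
  simulate_dataset(design, substrate, plasma, noise, small_grid(),
                   replicates, models = toy_models())
}

# the study-condition protocol: 25-mixture multilevel design, preset BIS /
# metabolite band models, gold substrate, plasma background, 0.5% noise
protocol_dataset <- function(seed, replicates = 45) {
  cal <- multilevel_design(2, 5, 15, 240)
  simulate_dataset(cal, substrate_profile("gold"), plasma_background(),
                   noise_model(seed = seed), wn_grid(4500, 400, 1.95),
                   replicates)
}

# independent minimum-norm least squares oracle (SVD pseudo-inverse on
# centered blocks)
lsq_oracle <- function(X, Y) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  s <- svd(Xc)
  pos <- s$d > max(dim(Xc)) * .Machine$double.eps * s$d[1]
  B <- s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) %*% Yc / s$d[pos])
  list(coefficients = B, x_mean = xm, y_mean = ym,
       predict = function(Xnew) sweep(sweep(Xnew, 2, xm) %*% B, 2, ym, `+`))
}

# independent Savitzky-Golay oracle: explicit local polynomial least
# squares; edge points evaluated off-center on the boundary window
sg_oracle <- function(y, x, window, polyorder, deriv) {
  n <- length(y)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    c0 <- min(max(i, h + 1), n - h)          # window center index
    idx <- (c0 - h):(c0 + h)
    fit <- stats::lm(y[idx] ~ poly(x[idx], polyorder, raw = TRUE))
    cf <- coef(fit)
    # analytic derivative of the fitted polynomial at x[i]
    val <- 0
    for (k in deriv:polyorder)
      val <- val + cf[k + 1] * factorial(k) / factorial(k - deriv) *
        x[i]^(k - deriv)
    out[i] <- val
  }
  out
}
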
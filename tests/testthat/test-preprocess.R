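test_that("region exclusion drops the right points and records segments", {
  g <- wn_grid(5, 1, 1)
  s <- spectrum_set(g, matrix(1:10, 2, 5, byrow = TRUE), c("a", "b"))
  pm <- exclude_regions(s, list(c(3.5, 2.5)))
  expect_equal(pm$wavenumbers, c(5, 4, 2, 1))
  expect_identical(pm$segment_id, c(1L, 1L, 2L, 2L))
  expect_equal(unname(pm$matrix[1, ]), c(1, 2, 4, 5))

  # default protocol regions on the instrument grid: count by enumeration
  g2 <- wn_grid(4500, 400, 1.95)
  wn <- as.numeric(g2)
  expected <- sum(!(wn >= 4000 & wn <= 4600) & !(wn >= 1950 & wn <= 2200))
  s2 <- spectrum_set(g2, matrix(0, 1, length(g2)), "x")
  pm2 <- exclude_regions(s2, list(c(4600, 4000), c(2200, 1950)))
  expect_identical(ncol(pm2$matrix), expected)
  expect_identical(length(unique(pm2$segment_id)), 2L)

  # idempotence: excluding the same regions again changes nothing (the
  # first region no longer overlaps the retained span, which warns)
  expect_warning(
    pm3 <- exclude_regions(pm2, list(c(4600, 4000), c(2200, 1950))),
    "outside")
  expect_equal(pm3$wavenumbers, pm2$wavenumbers)
  expect_identical(pm3$segment_id, pm2$segment_id)

  # empty exclusion list is the identity
  pm4 <- exclude_regions(s, list())
  expect_equal(pm4$wavenumbers, as.numeric(g))
  expect_equal(unname(pm4$matrix), unname(s$matrix))

  expect_error(exclude_regions(s, list(c(2, 4))), "inverted")
  expect_warning(exclude_regions(s, list(c(100, 50))), "outside")
})

test_that("Savitzky-Golay derivative matches analytic polynomial derivatives", {
  g <- wn_grid(3000, 2000, 5)
  wn <- as.numeric(g)

  # linear ramp: derivative is the slope everywhere including edges
  a <- 0.37; b <- 2
  pm <- processed_matrix(matrix(a * wn + b, 1), wn)
  d <- sg_derivative(pm, preprocess_config(excluded_regions = list()))
  expect_equal(unname(d$matrix[1, ]), rep(a, length(wn)), tolerance = 1e-9)

  # quadratic: derivative 2*a*wn + b within 1e-8 (filter exact to order 2)
  qa <- 3e-4; qb <- -0.2; qc <- 5
  pm2 <- processed_matrix(matrix(qa * wn^2 + qb * wn + qc, 1), wn)
  d2 <- sg_derivative(pm2, preprocess_config(excluded_regions = list()))
  expect_equal(unname(d2$matrix[1, ]), 2 * qa * wn + qb, tolerance = 1e-8)

  # constant spectrum: derivative identically zero
  pm3 <- processed_matrix(matrix(7, 1, length(wn)), wn)
  d3 <- sg_derivative(pm3, preprocess_config(excluded_regions = list()))
  expect_equal(unname(d3$matrix[1, ]), rep(0, length(wn)))

  # non-polynomial data against the explicit local least squares oracle
  set.seed(21)
  y <- sin(wn / 100) + 0.01 * rnorm(length(wn))
  pm4 <- processed_matrix(matrix(y, 1), wn)
  d4 <- sg_derivative(pm4, preprocess_config(excluded_regions = list()))
  oracle <- sg_oracle(y, wn, window = 11, polyorder = 2, deriv = 1)
  expect_equal(unname(d4$matrix[1, ]), oracle, tolerance = 1e-8)

  # segment shorter than the window is refused with the segment named
  short <- processed_matrix(matrix(1:5, 1), c(50, 40, 30, 20, 10))
  expect_error(sg_derivative(short, preprocess_config(excluded_regions = list())),
               "segment 1")
})

test_that("filters never cross a segment seam", {
  g <- wn_grid(300, 100, 5)
  wn <- as.numeric(g)
  # piecewise: different slopes on each side of an excluded gap
  y <- ifelse(wn > 200, 2 * wn, -3 * wn)
  s <- spectrum_set(g, matrix(y, 1), "x")
  pm <- exclude_regions(s, list(c(210, 190)))
  d <- sg_derivative(pm, preprocess_config(excluded_regions = list()))
  seg1 <- pm$segment_id == 1
  expect_equal(unname(d$matrix[1, seg1]), rep(2, sum(seg1)), tolerance = 1e-9)
  expect_equal(unname(d$matrix[1, !seg1]), rep(-3, sum(!seg1)),
               tolerance = 1e-9)
})

test_that("the preprocessing pipeline is ordered, linear and shape-stable", {
  g <- small_grid()
  set.seed(13)
  A <- matrix(rnorm(2 * length(g)), 2)
  s <- spectrum_set(g, A, c("a", "b"))

  # no exclusions + derivative 0 -> identity
  cfg0 <- preprocess_config(excluded_regions = list(), sg_derivative = 0)
  expect_equal(unname(preprocess(s, cfg0)$matrix), unname(A))

  # identical inputs give identical rows
  s_dup <- spectrum_set(g, rbind(A[1, ], A[1, ]), c("a", "b"))
  out_dup <- preprocess(s_dup,
                        preprocess_config(excluded_regions =
                                            list(c(3000, 2800))))$matrix
  expect_equal(out_dup[1, ], out_dup[2, ])

  # linearity: pipeline(alpha A + beta B) = alpha pipeline(A) + beta pipeline(B)
  B <- matrix(rnorm(2 * length(g)), 2)
  cfg <- preprocess_config(excluded_regions = list(c(3000, 2800)))
  pa <- preprocess(s, cfg)$matrix
  pb <- preprocess(spectrum_set(g, B, c("a", "b")), cfg)$matrix
  pab <- preprocess(spectrum_set(g, 2 * A + 3 * B, c("a", "b")), cfg)$matrix
  expect_equal(unname(pab), unname(2 * pa + 3 * pb), tolerance = 1e-9)

  # protocol config on a simulated 25-mixture set: uniform feature count,
  # two segments, count derived from grid arithmetic
  d <- multilevel_design(2, 5, 15, 240)
  ds <- simulate_dataset(d, replicates = 1, noise = quiet_noise())
  pm <- preprocess(ds$spectra)
  wn <- as.numeric(ds$spectra$grid)
  expected <- sum(!(wn >= 4000 & wn <= 4600) & !(wn >= 1950 & wn <= 2200))
  expect_identical(ncol(pm$matrix), expected)
  expect_identical(attr(pm, "n_features"), expected)
  expect_identical(length(unique(pm$segment_id)), 2L)
  expect_identical(nrow(pm$matrix), 25L)
})

test_that("configuration invariants are enforced", {
  expect_error(preprocess_config(sg_window = 10), "odd")
  expect_error(preprocess_config(sg_window = 3, sg_polyorder = 3), "odd|exceed")
  expect_error(preprocess_config(sg_derivative = 3, sg_polyorder = 2),
               "sg_derivative")
  expect_error(preprocess_config(excluded_regions = list(c(1000, 2000))),
               "inverted")
})
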
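#' Construct a descending wavenumber grid
#'
#' FTIR spectra are conventionally reported from high to low wavenumber, so
#' grids run descending (e.g. 4500 down to 400 cm-1). The grid starts exactly
#' at \code{start} and steps down by \code{step}; the last point is the
#' smallest grid value that is still >= \code{end}.
#'
#' @param start highest wavenumber, cm-1 (must exceed \code{end}).
#' @param end lowest wavenumber, cm-1 (must be positive).
#' @param step grid spacing, cm-1 (positive).
#'
#' @return An object of class \code{"wn_grid"}: a numeric vector of strictly
#'   decreasing wavenumbers with attributes \code{start}, \code{end},
#'   \code{step}.
#'
#' @examples
#' g <- wn_grid(4500, 400, 1.95)
#' length(g)  # 2103 points
#' @export
wn_grid <- function(start, end, step) {
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(step))
  if (!(start > end) || end <= 0)
    stop("invalid grid: require start > end > 0 (descending wavenumber convention)")
  if (step <= 0)
    stop("invalid grid: step must be positive")
  n <- floor((start - end) / step + 1e-9) + 1L
  values <- start - step * (0:(n - 1L))
  structure(values, start = start, end = end, step = step,
            class = "wn_grid")
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("wavenumber grid: %g -> %g cm-1, step %g (%d points)\n",
              x[1], x[length(x)], attr(x, "step"), length(x)))
  invisible(x)
}

# spacing of an arbitrary descending wavenumber vector, with uniformity check
grid_step <- function(values, tol = 1e-6) {
  d <- diff(values)
  if (any(d >= 0))
    stop("wavenumbers must be strictly decreasing")
  step <- -d[1]
  if (any(abs(d + step) > tol * max(1, step)))
    stop("wavenumbers must be uniformly spaced")
  step
}

# coerce a numeric vector (already descending, uniform) to wn_grid
as_wn_grid <- function(values) {
  step <- grid_step(values)
  structure(as.numeric(values), start = values[1],
            end = values[length(values)], step = step, class = "wn_grid")
}

grids_identical <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) <= tol)
}
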
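#' Preprocessing configuration
#'
#' Spectral regions dominated by atmospheric interference (CO2 around
#' 2200-1950 cm-1, humidity and detector roll-off above 4000 cm-1) are
#' excluded before modelling; a Savitzky-Golay derivative then resolves
#' band overlap. Defaults follow the SEIRA quantification protocol:
#' exclude 4600-4000 and 2200-1950 cm-1, first derivative with an 11-point
#' quadratic filter.
#'
#' @param excluded_regions list of \code{c(high, low)} wavenumber intervals
#'   (cm-1, closed); may be empty.
#' @param sg_window odd filter window length in points, > \code{sg_polyorder}.
#' @param sg_polyorder polynomial order of the local fit.
#' @param sg_derivative derivative order (0 = smoothing only), must not
#'   exceed \code{sg_polyorder}.
#' @return an object of class \code{"preprocess_config"}.
#' @export
preprocess_config <- function(excluded_regions = list(c(4600, 4000),
                                                      c(2200, 1950)),
                              sg_window = 11, sg_polyorder = 2,
                              sg_derivative = 1) {
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2 == 0 || sg_window <= sg_polyorder)
    stop("config error: sg_window must be odd and exceed sg_polyorder")
  if (sg_derivative > sg_polyorder)
    stop("config error: sg_derivative must not exceed sg_polyorder")
  for (r in excluded_regions) {
    if (length(r) != 2) stop("config error: regions are c(high, low) pairs")
    if (r[2] > r[1]) stop("config error: inverted interval (low > high)")
  }
  structure(list(excluded_regions = excluded_regions,
                 sg_window = sg_window,
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_derivative = as.integer(sg_derivative)),
            class = "preprocess_config")
}

#' Processed feature matrix
#'
#' Samples x retained-wavenumbers matrix with the retained wavenumbers and
#' the contiguous-segment id of every column (filters are applied within
#' segments, never across the seam left by an excluded region).
#'
#' @param matrix numeric samples x features matrix.
#' @param wavenumbers retained wavenumbers, strictly decreasing within each
#'   segment.
#' @param segment_id integer per column.
#' @param sample_ids optional row labels.
#' @return an object of class \code{"processed_matrix"}.
#' @export
processed_matrix <- function(matrix, wavenumbers, segment_id = NULL,
                             sample_ids = NULL) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != length(wavenumbers))
    stop("wavenumbers must match matrix columns")
  if (is.null(segment_id)) segment_id <- rep(1L, length(wavenumbers))
  if (!is.null(sample_ids)) rownames(matrix) <- sample_ids
  structure(list(matrix = matrix, wavenumbers = as.numeric(wavenumbers),
                 segment_id = as.integer(segment_id)),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("processed matrix: %d samples x %d points in %d segment(s)\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$segment_id))))
  invisible(x)
}

#' Drop spectral regions
#'
#' Removes every grid point whose wavenumber lies inside any excluded closed
#' interval and records where the retained grid becomes discontiguous.
#' Regions entirely outside the grid span produce a warning, not an error.
#'
#' @param spectra a \code{\link{spectrum_set}} or
#'   \code{\link{processed_matrix}}.
#' @param regions list of \code{c(high, low)} intervals (cm-1).
#' @return a \code{\link{processed_matrix}}.
#' @export
exclude_regions <- function(spectra, regions) {
  if (inherits(spectra, "spectrum_set")) {
    wn <- as.numeric(spectra$grid)
    mat <- spectra$matrix
    seg <- rep(1L, length(wn))
  } else if (inherits(spectra, "processed_matrix")) {
    wn <- spectra$wavenumbers
    mat <- spectra$matrix
    seg <- spectra$segment_id
  } else stop("expected a spectrum_set or processed_matrix")
  keep <- rep(TRUE, length(wn))
  for (r in regions) {
    if (r[2] > r[1]) stop("config error: inverted interval (low > high)")
    inside <- wn <= r[1] & wn >= r[2]
    if (!any(wn >= r[2] & wn <= r[1]) &&
        (r[1] < min(wn) || r[2] > max(wn)))
      warning("excluded region [", r[2], ", ", r[1],
              "] lies outside the grid span")
    keep <- keep & !inside
  }
  wn_out <- wn[keep]
  # new segment wherever points were dropped between neighbours or the
  # input was already discontiguous there
  seg_in <- seg[keep]
  idx <- which(keep)
  new_seg <- integer(length(idx))
  if (length(idx) > 0) {
    new_seg[1] <- 1L
    for (k in seq_along(idx)[-1]) {
      brk <- (idx[k] - idx[k - 1] > 1L) || (seg_in[k] != seg_in[k - 1])
      new_seg[k] <- new_seg[k - 1] + as.integer(brk)
    }
  }
  processed_matrix(mat[, keep, drop = FALSE], wn_out, new_seg,
                   sample_ids = rownames(mat))
}

#' Savitzky-Golay derivative of a processed matrix
#'
#' Applies the Savitzky-Golay filter independently within each contiguous
#' segment (never across a seam). The local polynomial fit handles the
#' segment edges on one-sided windows, and the derivative is scaled by the
#' wavenumber step so that the output is in absorbance per cm-1 (signed
#' with respect to increasing wavenumber, although the grid is stored
#' descending).
#'
#' @param pm a \code{\link{processed_matrix}}.
#' @param config a \code{\link{preprocess_config}} (exclusions ignored here).
#' @return a \code{\link{processed_matrix}} of identical shape.
#' @export
sg_derivative <- function(pm, config = preprocess_config()) {
  stopifnot(inherits(pm, "processed_matrix"),
            inherits(config, "preprocess_config"))
  out <- pm$matrix
  for (s in unique(pm$segment_id)) {
    cols <- which(pm$segment_id == s)
    if (length(cols) < config$sg_window)
      stop("preprocessing error: segment ", s, " has ", length(cols),
           " points, fewer than the filter window (", config$sg_window, ")")
    step <- grid_step(pm$wavenumbers[cols])
    # columns run from high to low wavenumber: d/d(wavenumber) flips sign
    sgn <- (-1)^config$sg_derivative
    for (i in seq_len(nrow(out))) {
      out[i, cols] <- sgn * signal::sgolayfilt(
        pm$matrix[i, cols], p = config$sg_polyorder, n = config$sg_window,
        m = config$sg_derivative, ts = step)
    }
  }
  processed_matrix(out, pm$wavenumbers, pm$segment_id,
                   sample_ids = rownames(pm$matrix))
}

#' Full preprocessing pipeline
#'
#' Region exclusion followed by the Savitzky-Golay derivative, in that
#' order. The retained feature count is recorded as attribute
#' \code{n_features}.
#'
#' @param spectra a \code{\link{spectrum_set}}.
#' @param config a \code{\link{preprocess_config}}.
#' @return a \code{\link{processed_matrix}}.
#' @export
preprocess <- function(spectra, config = preprocess_config()) {
  pm <- exclude_regions(spectra, config$excluded_regions)
  if (config$sg_derivative > 0)
    pm <- sg_derivative(pm, config)
  attr(pm, "n_features") <- ncol(pm$matrix)
  pm
}
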
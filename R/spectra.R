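#' Spectrum and spectrum-set containers
#'
#' A \code{spectrum} is a single absorbance trace on a wavenumber grid; a
#' \code{spectrum_set} holds several samples measured on one shared grid as a
#' samples x wavenumbers matrix. Absorbance is unitless.
#'
#' @param grid a \code{\link{wn_grid}} (or strictly decreasing uniform
#'   numeric vector of wavenumbers).
#' @param absorbance numeric vector, one value per grid point, all finite.
#' @param sample_id single character label.
#'
#' @return \code{spectrum}: list with elements \code{grid},
#'   \code{absorbance}, \code{sample_id}, class \code{"spectrum"}.
#' @export
spectrum <- function(grid, absorbance, sample_id = "sample") {
  if (!inherits(grid, "wn_grid")) grid <- as_wn_grid(grid)
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(grid))
    stop("absorbance length must equal grid length")
  if (!all(is.finite(absorbance)))
    stop("absorbance values must all be finite")
  structure(list(grid = grid, absorbance = absorbance,
                 sample_id = as.character(sample_id)[1]),
            class = "spectrum")
}

#' @rdname spectrum
#' @param matrix numeric matrix, samples in rows, wavenumbers in columns.
#' @param sample_ids unique character labels, one per row.
#' @export
spectrum_set <- function(grid, matrix, sample_ids = NULL) {
  if (!inherits(grid, "wn_grid")) grid <- as_wn_grid(grid)
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != length(grid))
    stop("matrix column count must equal grid length")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(matrix)
    if (is.null(sample_ids))
      sample_ids <- if (nrow(matrix) > 0) paste0("s", seq_len(nrow(matrix))) else character(0)
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(matrix))
    stop("need one sample id per matrix row")
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique")
  if (nrow(matrix) > 0 && !all(is.finite(matrix)))
    stop("absorbance values must all be finite")
  storage.mode(matrix) <- "double"
  rownames(matrix) <- sample_ids
  colnames(matrix) <- NULL
  structure(list(grid = grid, matrix = matrix, sample_ids = sample_ids),
            class = "spectrum_set")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum '%s': %d points, %g -> %g cm-1\n", x$sample_id,
              length(x$grid), x$grid[1], x$grid[length(x$grid)]))
  invisible(x)
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum set: %d samples x %d points, %g -> %g cm-1\n",
              nrow(x$matrix), length(x$grid), x$grid[1],
              x$grid[length(x$grid)]))
  invisible(x)
}

#' Read a wide spectra CSV
#'
#' Expected layout: first column \code{wavenumber_cm-1} (strictly decreasing,
#' uniformly spaced), one further column per sample with the sample id as
#' header. Ascending files are rejected under the descending FTIR convention
#' unless \code{resort = TRUE}.
#'
#' @param path CSV file path.
#' @param resort if TRUE, an ascending wavenumber column is re-sorted to
#'   descending instead of raising an error.
#' @return a \code{\link{spectrum_set}}.
#' @export
read_spectra_csv <- function(path, resort = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 1) stop("format error: empty spectra file")
  wn <- as.numeric(df[[1]])
  ids <- names(df)[-1]
  if (anyDuplicated(ids)) stop("format error: duplicate sample ids")
  if (length(wn) >= 2 && all(diff(wn) > 0)) {
    if (!resort)
      stop("format error: ascending wavenumber column (descending convention; use resort = TRUE)")
    ord <- order(wn, decreasing = TRUE)
    wn <- wn[ord]
    df <- df[ord, , drop = FALSE]
  }
  grid <- tryCatch(as_wn_grid(wn),
                   error = function(e) stop("format error: ", conditionMessage(e)))
  mat <- if (length(ids) > 0) t(as.matrix(df[, -1, drop = FALSE])) else
    matrix(0, nrow = 0, ncol = length(grid))
  spectrum_set(grid, mat, ids)
}

#' Write a spectrum set as wide CSV
#'
#' Column 1 is \code{wavenumber_cm-1}; remaining columns are samples. Values
#' are written at full double precision (15 significant digits) so a
#' write/read round trip is lossless to well below 1e-9.
#'
#' @param spectra a \code{\link{spectrum_set}}.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectrum_set"))
  df <- data.frame(`wavenumber_cm-1` = as.numeric(spectra$grid),
                   check.names = FALSE)
  for (i in seq_along(spectra$sample_ids))
    df[[spectra$sample_ids[i]]] <- spectra$matrix[i, ]
  ok <- tryCatch({
    utils::write.table(format(df, digits = 15, scientific = FALSE,
                              trim = TRUE),
                       path, sep = ",", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Average replicate scans of one mixture
#'
#' Pointwise arithmetic mean of replicate spectra measured on identical
#' grids; mirrors instrument scan averaging (each mixture scanned many times
#' and averaged). The result keeps the first replicate's sample id and
#' records the replicate count as attribute \code{n_scans}.
#'
#' @param replicates list of \code{\link{spectrum}} objects on identical
#'   grids (at least one).
#' @return a \code{\link{spectrum}}.
#' @export
average_scans <- function(replicates) {
  if (length(replicates) == 0) stop("empty input: no replicates to average")
  if (!all(vapply(replicates, inherits, logical(1), "spectrum")))
    stop("replicates must be spectrum objects")
  g <- replicates[[1]]$grid
  for (r in replicates[-1])
    if (!grids_identical(g, r$grid)) stop("grid mismatch between replicates")
  m <- vapply(replicates, `[[`, numeric(length(g)), "absorbance")
  avg <- if (length(replicates) == 1) replicates[[1]]$absorbance else
    rowMeans(m)
  out <- spectrum(g, avg, replicates[[1]]$sample_id)
  attr(out, "n_scans") <- length(replicates)
  out
}
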
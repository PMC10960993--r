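#' Concentration design tables
#'
#' A design table pairs sample labels with a samples x analytes matrix of
#' concentrations in ng/mL.
#'
#' @param sample_ids character labels, unique.
#' @param analyte_names character labels, unique.
#' @param concentrations numeric matrix, samples x analytes, nonnegative.
#' @return an object of class \code{"design_table"}.
#' @export
design_table <- function(sample_ids, analyte_names, concentrations) {
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  sample_ids <- as.character(sample_ids)
  analyte_names <- as.character(analyte_names)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyDuplicated(analyte_names)) stop("analyte names must be unique")
  if (nrow(concentrations) != length(sample_ids) ||
      ncol(concentrations) != length(analyte_names))
    stop("concentration matrix shape must match labels")
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  dimnames(concentrations) <- list(sample_ids, analyte_names)
  structure(list(sample_ids = sample_ids, analyte_names = analyte_names,
                 concentrations = concentrations),
            class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("design table: %d samples x %d analytes (ng/mL)\n",
              length(x$sample_ids), length(x$analyte_names)))
  print(utils::head(x$concentrations, 6))
  if (length(x$sample_ids) > 6) cat("...\n")
  invisible(x)
}

#' Multilevel partial factorial calibration design
#'
#' Builds the classical cyclic multilevel calibration design: n_levels^2
#' mixtures in which every analyte takes each of the equally spaced
#' concentration levels the same number of times and the concentration
#' columns of any two analytes are (near-)orthogonal. With five levels the
#' codes are -2..+2; factor j of run (a, b) carries code
#' (a + (j-1) b) mod n_levels, so for two factors the design covers the full
#' n_levels x n_levels grid. Rows are sorted lexicographically by
#' concentration for a reproducible order.
#'
#' @param n_factors number of analytes (>= 1, at most n_levels^2 - 1).
#' @param n_levels odd number of concentration levels (3, 5, 7, ...).
#' @param range_min,range_max concentration range, ng/mL
#'   (\code{range_max > range_min > 0}).
#' @param analyte_names optional labels; default \code{c("BIS",
#'   "metabolite")} for two factors, else \code{A1, A2, ...}.
#' @return a \code{\link{design_table}} with \code{n_levels^2} rows.
#'
#' @examples
#' d <- multilevel_design(2, 5, 15, 240)
#' nrow(d$concentrations)           # 25 mixtures
#' sort(unique(d$concentrations[, 1]))  # 5 equally spaced levels
#' @export
multilevel_design <- function(n_factors = 2, n_levels = 5,
                              range_min = 15, range_max = 240,
                              analyte_names = NULL) {
  if (n_levels %% 2 == 0 || n_levels < 3)
    stop("unsupported design: n_levels must be odd and >= 3")
  if (n_factors < 1) stop("unsupported design: need at least one factor")
  if (n_factors > n_levels^2 - 1)
    stop("unsupported design: n_factors exceeds n_levels^2 - 1")
  if (!(range_max > range_min && range_min > 0))
    stop("unsupported design: require range_max > range_min > 0")
  l <- as.integer(n_levels)
  runs <- expand.grid(b = 0:(l - 1L), a = 0:(l - 1L))  # a varies slowest
  codes <- sapply(seq_len(n_factors), function(j)
    (runs$a + (j - 1L) * runs$b) %% l)
  codes <- matrix(codes, ncol = n_factors)
  levels <- range_min + codes * (range_max - range_min) / (l - 1L)
  ord <- do.call(order, as.data.frame(levels))
  levels <- levels[ord, , drop = FALSE]
  if (is.null(analyte_names))
    analyte_names <- if (n_factors == 2) c("BIS", "metabolite") else
      paste0("A", seq_len(n_factors))
  ids <- sprintf("cal%02d", seq_len(nrow(levels)))
  design_table(ids, analyte_names, levels)
}

#' Random in-range validation design
#'
#' Uniform random concentrations strictly inside the calibration range,
#' deterministic given the seed; any row that would land exactly on a
#' calibration grid point is redrawn.
#'
#' @param n_samples number of validation mixtures (>= 1).
#' @param analyte_names analyte labels.
#' @param range_min,range_max concentration range, ng/mL.
#' @param seed integer seed.
#' @param n_levels level count of the calibration design whose grid points
#'   are avoided (default 5).
#' @return a \code{\link{design_table}}.
#' @export
validation_design <- function(n_samples = 10,
                              analyte_names = c("BIS", "metabolite"),
                              range_min = 15, range_max = 240, seed = 1L,
                              n_levels = 5) {
  if (n_samples < 1) stop("empty design: n_samples must be >= 1")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  grid_levels <- range_min +
    (0:(n_levels - 1L)) * (range_max - range_min) / (n_levels - 1L)
  p <- length(analyte_names)
  draw <- function(n) matrix(stats::runif(n * p, range_min, range_max), n, p)
  conc <- draw(n_samples)
  for (k in 1:10) {
    bad <- apply(conc, 1, function(r) any(r %in% grid_levels))
    if (!any(bad)) break
    conc[bad, ] <- draw(sum(bad))
  }
  design_table(sprintf("val%02d", seq_len(n_samples)), analyte_names, conc)
}

#' Read / write concentration CSV
#'
#' Layout: column \code{sample_id}, then one \code{<analyte>_ng_per_mL}
#' column per analyte.
#'
#' @param design a \code{\link{design_table}}.
#' @param path CSV path.
#' @return \code{write_design_csv}: the path, invisibly;
#'   \code{read_design_csv}: a \code{\link{design_table}}.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "design_table"))
  df <- data.frame(sample_id = design$sample_ids)
  for (j in seq_along(design$analyte_names))
    df[[paste0(design$analyte_names[j], "_ng_per_mL")]] <-
      design$concentrations[, j]
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("format error: missing sample_id column")
  conc_cols <- grep("_ng_per_mL$", names(df), value = TRUE)
  if (length(conc_cols) == 0)
    stop("format error: no *_ng_per_mL analyte columns")
  analytes <- sub("_ng_per_mL$", "", conc_cols)
  design_table(df$sample_id, analytes,
               as.matrix(df[, conc_cols, drop = FALSE]))
}
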
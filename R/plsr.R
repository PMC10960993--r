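#' Fit a PLSR model by NIPALS
#'
#' Partial least squares regression fitted with the nonlinear iterative
#' partial least squares (NIPALS) algorithm: X and Y are mean-centered (no
#' variance scaling, the convention for spectral calibration), components
#' are extracted one at a time by iterating weight/score/loading updates to
#' convergence (tolerance 1e-10 on the score vector, at most 500 iterations
#' per component) and both blocks are deflated after each component.
#' Regression coefficients are assembled as B = W (P'W)^-1 Q' so that
#' predictions are y_mean + (x - x_mean) B.
#'
#' @param X a \code{\link{processed_matrix}} or plain numeric matrix
#'   (samples x features).
#' @param Y a \code{\link{design_table}} or numeric matrix
#'   (samples x analytes); rows must align with X (matching sample ids when
#'   both carry them).
#' @param n_lv number of latent variables, between 1 and
#'   \code{min(nrow(X) - 1, ncol(X))}.
#' @return an object of class \code{"plsr_fit"} with fields \code{x_mean},
#'   \code{y_mean}, \code{weights}, \code{x_loadings}, \code{y_loadings},
#'   \code{scores}, \code{coefficients} (features x analytes, for
#'   \code{n_lv} components), \code{coef_by_lv} (list of coefficient
#'   matrices for 1..n_lv components), \code{n_lv}, \code{analyte_names},
#'   \code{feature_wavenumbers}.
#' @export
plsr_fit <- function(X, Y, n_lv) {
  wn <- NULL
  if (inherits(X, "processed_matrix")) {
    wn <- X$wavenumbers
    X <- X$matrix
  }
  analytes <- NULL
  if (inherits(Y, "design_table")) {
    ids_x <- rownames(X)
    if (!is.null(ids_x) && !identical(ids_x, Y$sample_ids))
      stop("alignment error: sample ids of X and Y differ")
    analytes <- Y$analyte_names
    Y <- Y$concentrations
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("alignment error: X and Y row counts differ")
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  max_lv <- min(n - 1L, p)
  if (n_lv < 1 || n_lv > max_lv)
    stop("model error: n_lv must be in 1..", max_lv)
  if (is.null(analytes))
    analytes <- colnames(Y) %||% paste0("y", seq_len(m))

  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, m, n_lv); Tm <- matrix(0, n, n_lv)
  tol <- 1e-10; max_iter <- 500L
  frob0 <- sqrt(sum(Xc^2))
  a_eff <- 0L
  for (a in seq_len(n_lv)) {
    # X block numerically exhausted (rank < n_lv): remaining components
    # are null and contribute nothing, as for duplicate-sample folds
    if (sqrt(sum(Xc^2)) <= 1e-12 * max(frob0, .Machine$double.xmin)) {
      if (a == 1L)
        stop("convergence error: degenerate X block at component 1")
      break
    }
    # start the score iteration at its fixed point: the dominant
    # eigenvector of the m x m cross-product matrix (exact for the
    # converged NIPALS weight direction, cf. the kernel algorithm); this
    # keeps late, noise-dominated components from stalling in slow power
    # iteration when eigenvalues are nearly tied
    Cm <- crossprod(Xc, Yc)
    G <- crossprod(Cm)
    q0 <- eigen(G, symmetric = TRUE)$vectors[, 1]
    u <- drop(Yc %*% q0)
    if (sum(u^2) < .Machine$double.eps)
      u <- Yc[, which.max(apply(Yc, 2, stats::var)), drop = TRUE]
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u))
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps)
        stop("convergence error: degenerate X block at component ", a)
      w <- w / nw
      tt <- drop(Xc %*% w)
      q <- drop(crossprod(Yc, tt)) / sum(tt^2)
      if (m == 1) { converged <- TRUE; t_old <- tt; break }
      u <- drop(Yc %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * max(1, sqrt(sum(tt^2)))) {
        converged <- TRUE; t_old <- tt; break
      }
      t_old <- tt
    }
    if (!converged)
      stop("convergence error: component ", a, " did not converge in ",
           max_iter, " iterations")
    tt <- t_old
    pvec <- drop(crossprod(Xc, tt)) / sum(tt^2)
    q <- drop(crossprod(Yc, tt)) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pvec)
    Yc <- Yc - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pvec; Q[, a] <- q; Tm[, a] <- tt
    a_eff <- a
  }
  coef_by_lv <- vector("list", n_lv)
  for (a in seq_len(n_lv)) {
    k <- min(a, a_eff)
    Wa <- W[, 1:k, drop = FALSE]; Pa <- P[, 1:k, drop = FALSE]
    Qa <- Q[, 1:k, drop = FALSE]
    coef_by_lv[[a]] <- Wa %*% solve(crossprod(Pa, Wa), t(Qa))
  }
  B <- coef_by_lv[[n_lv]]
  dimnames(B) <- list(NULL, analytes)
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = W,
                 x_loadings = P, y_loadings = Q, scores = Tm,
                 coefficients = B, coef_by_lv = coef_by_lv,
                 n_lv = as.integer(n_lv), analyte_names = analytes,
                 feature_wavenumbers = wn),
            class = "plsr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("PLSR (NIPALS) fit: %d latent variable(s), %d features, analytes: %s\n",
              x$n_lv, length(x$x_mean), paste(x$analyte_names, collapse = ", ")))
  invisible(x)
}

#' Predict concentrations from a PLSR fit
#'
#' @param object a \code{\link{plsr_fit}}.
#' @param newdata a \code{\link{processed_matrix}} or numeric matrix whose
#'   features match the model's training features exactly (same count and,
#'   when wavenumbers are known, same wavenumbers).
#' @param n_lv optionally predict with fewer components than fitted.
#' @param ... unused.
#' @return numeric matrix of predicted concentrations (samples x analytes);
#'   values may be negative (not clipped).
#' @export
predict.plsr_fit <- function(object, newdata, n_lv = object$n_lv, ...) {
  if (inherits(newdata, "processed_matrix")) {
    if (!is.null(object$feature_wavenumbers)) {
      if (length(newdata$wavenumbers) != length(object$feature_wavenumbers) ||
          any(abs(newdata$wavenumbers - object$feature_wavenumbers) > 1e-9))
        stop("grid mismatch: features differ from the model's training grid")
    }
    newdata <- newdata$matrix
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("grid mismatch: expected ", length(object$x_mean), " features, got ",
         ncol(newdata))
  if (n_lv < 1 || n_lv > object$n_lv)
    stop("model error: n_lv out of fitted range")
  B <- object$coef_by_lv[[n_lv]]
  pred <- sweep(newdata, 2, object$x_mean) %*% B
  pred <- sweep(pred, 2, object$y_mean, `+`)
  colnames(pred) <- object$analyte_names
  rownames(pred) <- rownames(newdata)
  pred
}

#' Cross-validate the latent-variable count
#'
#' Leave-one-out (default) or seeded random k-fold cross-validation of the
#' NIPALS PLSR over a grid of latent-variable counts. For leave-one-out
#' every sample is omitted exactly once; for each fold a single model at the
#' largest LV count is fitted and truncated to every smaller count.
#' RMSECV per analyte is sqrt(mean squared out-of-fold error); the overall
#' curve is the root mean square across analytes.
#'
#' @param X,Y as in \code{\link{plsr_fit}}.
#' @param lv_grid integer vector of candidate LV counts (default 1..10,
#'   capped at the largest count every training fold supports).
#' @param scheme \code{"loo"} or \code{"kfold"}.
#' @param seed seed for fold assignment under \code{"kfold"}.
#' @param k fold count for \code{"kfold"}.
#' @return an object of class \code{"plsr_cv"}: \code{lv_grid},
#'   \code{rmsecv} (LV x analyte matrix), \code{overall} (pooled curve),
#'   \code{se_overall} (standard error of the pooled curve),
#'   \code{selected_lv} (global-minimum choice), \code{scheme}, \code{seed}.
#' @export
plsr_cv <- function(X, Y, lv_grid = 1:10, scheme = c("loo", "kfold"),
                    seed = 1L, k = 10L) {
  scheme <- match.arg(scheme)
  if (inherits(X, "processed_matrix")) X <- X$matrix
  analytes <- NULL
  if (inherits(Y, "design_table")) {
    analytes <- Y$analyte_names
    Y <- Y$concentrations
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(Y)
  if (is.null(analytes)) analytes <- colnames(Y) %||% paste0("y", seq_len(m))
  folds <- if (scheme == "loo") as.list(seq_len(n)) else {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    split(sample(n), rep_len(seq_len(k), n))
  }
  min_train <- min(vapply(folds, function(f) n - length(f), integer(1)))
  max_lv <- min(min_train - 1L, ncol(X))
  lv_grid <- lv_grid[lv_grid >= 1 & lv_grid <= max_lv]
  if (length(lv_grid) == 0)
    stop("cv error: no feasible latent-variable count for these folds")
  A <- max(lv_grid)
  sq_err <- array(NA_real_, c(n, length(lv_grid), m))
  for (f in folds) {
    fit <- plsr_fit(X[-f, , drop = FALSE], Y[-f, , drop = FALSE], n_lv = A)
    for (j in seq_along(lv_grid)) {
      pred <- predict(fit, X[f, , drop = FALSE], n_lv = lv_grid[j])
      sq_err[f, j, ] <- (pred - Y[f, , drop = FALSE])^2
    }
  }
  rmsecv <- sqrt(apply(sq_err, c(2, 3), mean))
  dimnames(rmsecv) <- list(paste0("lv", lv_grid), analytes)
  # pooled curve: RMS across analytes; SE via the dispersion of per-sample
  # pooled squared errors (delta method on sqrt)
  pooled_sq <- apply(sq_err, c(1, 2), mean)
  mse <- colMeans(pooled_sq)
  overall <- sqrt(mse)
  se_overall <- apply(pooled_sq, 2, stats::sd) / sqrt(n) / (2 * overall)
  structure(list(lv_grid = lv_grid, rmsecv = rmsecv, overall = overall,
                 se_overall = se_overall,
                 selected_lv = lv_grid[which.min(overall)],
                 scheme = scheme, seed = as.integer(seed)),
            class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, ...) {
  cat(sprintf("PLSR cross-validation (%s): selected %d LV\n", x$scheme,
              x$selected_lv))
  tab <- cbind(x$rmsecv, overall = x$overall)
  print(round(tab, 4))
  invisible(x)
}

#' Choose the latent-variable count from a cross-validation curve
#'
#' \code{"global_min"} returns the LV count minimising the pooled RMSECV
#' curve (smallest count on ties); \code{"one_se"} returns the smallest
#' count whose pooled RMSECV is within one standard error of the minimum.
#'
#' @param cv a \code{\link{plsr_cv}} result.
#' @param rule \code{"global_min"} or \code{"one_se"}.
#' @return integer LV count.
#' @export
select_lv <- function(cv, rule = c("global_min", "one_se")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cv, "plsr_cv"))
  i_min <- which.min(cv$overall)
  if (rule == "global_min") return(cv$lv_grid[i_min])
  thr <- cv$overall[i_min] + cv$se_overall[i_min]
  cv$lv_grid[which(cv$overall <= thr)[1]]
}
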
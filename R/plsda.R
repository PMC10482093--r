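#' Partial-least-squares discriminant fit on food-item indicators
#'
#' Runs NIPALS partial-least-squares regression of the centered 0/1 outcome
#' on the centered item-indicator matrix. The first weight direction is the
#' (normalized) cross-covariance `t(X) %*% (y - mean(y))`, i.e. the
#' direction maximizing covariance between the component scores and the
#' outcome; later components are extracted after deflation and their score
#' vectors are mutually orthogonal. Food groups play no role here -- every
#' item competes directly.
#'
#' @param g Binary item-indicator matrix (n x items).
#' @param y Binary 0/1 outcome.
#' @param n_components Number of PLS components to extract (default 1; only
#'   the first column of the coefficient matrix feeds the weighted score).
#' @param scale Scale columns to unit variance before fitting? Constant
#'   columns are an error when `TRUE`.
#' @return Object of class `plsda_fit`: `weights` (items x A weight matrix
#'   `W`), `loadings` (`P`), `y_loadings` (`q`), `scores` (`T`),
#'   `coefficients` (per-item regression coefficients
#'   `W (P'W)^{-1} q`; with one outcome this is the first and only column
#'   of the coefficient matrix, stored also as `coef_first`),
#'   `x_center`, `x_scale`, `y_center`, `n_components`.
#' @export
fit_plsda <- function(g, y, n_components = 1L, scale = FALSE) {
  X <- as.matrix(g) * 1.0
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("`y` not conformable with `g`")
  if (!all(y %in% c(0, 1))) stop("`y` must be binary encoded 0/1")
  if (n_components < 1 || n_components >= nrow(X))
    stop("`n_components` must be in [1, n-1]")
  x_center <- colMeans(X)
  X <- sweep(X, 2, x_center)
  x_scale <- rep(1, ncol(X))
  if (scale) {
    x_scale <- apply(X, 2, stats::sd)
    if (any(x_scale == 0))
      stop("constant (zero-variance) column(s); cannot scale: ",
           paste(colnames(g)[x_scale == 0], collapse = ", "))
    X <- sweep(X, 2, x_scale, "/")
  }
  y_center <- mean(y)
  yc <- y - y_center
  A <- as.integer(n_components)
  p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, nrow(X), A); q <- numeric(A)
  for (a in seq_len(A)) {
    wa <- drop(crossprod(X, yc))
    nrm <- sqrt(sum(wa^2))
    if (nrm < 1e-12)
      stop("residual covariance vanished before component ", a)
    wa <- wa / nrm
    ta <- drop(X %*% wa)
    tt <- sum(ta^2)
    pa <- drop(crossprod(X, ta)) / tt
    qa <- sum(yc * ta) / tt
    X <- X - tcrossprod(ta, pa)
    yc <- yc - qa * ta
    W[, a] <- wa; P[, a] <- pa; Tm[, a] <- ta; q[a] <- qa
  }
  coefs <- drop(W %*% solve(crossprod(P, W), q)) / x_scale
  names(coefs) <- colnames(g)
  structure(list(weights = W, loadings = P, y_loadings = q, scores = Tm,
                 coefficients = coefs, coef_first = coefs,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, n_components = A),
            class = "plsda_fit")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat("PLS-DA fit:", length(x$coefficients), "items,",
      x$n_components, "component(s)\n")
  invisible(x)
}

#' Weighted food score from a PLS-DA fit
#'
#' Multiplies each subject's item-indicator vector by the per-item
#' coefficient vector of the fit (the weight matrix combined with the first
#' column of the coefficient matrix), giving the PLS-weighted diet score.
#'
#' @param fit A [fit_plsda()] result.
#' @param g Binary indicator matrix with the same columns as the fit.
#' @return Numeric score vector.
#' @export
compute_plsda_rfs <- function(fit, g) {
  stopifnot(inherits(fit, "plsda_fit"))
  g <- as.matrix(g)
  if (ncol(g) != length(fit$coefficients))
    stop("`g` has ", ncol(g), " columns; fit expects ",
         length(fit$coefficients))
  as.numeric(g %*% fit$coefficients)
}
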
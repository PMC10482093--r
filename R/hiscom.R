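#' Fit the hierarchical structural component model for food scores
#'
#' Fits a two-level latent-component logistic model: within each food group
#' the binary item indicators are combined by item weights `w` into a group
#' component, and the components predict the case-control outcome through
#' group coefficients `beta`:
#' \deqn{logit(\pi_i) = \beta_0 + \sum_k \big[\sum_t g_{itk} w_{tk}\big] \beta_k.}
#' Estimation alternates least-squares updates of `beta` (weights fixed) and
#' of `w` (coefficients fixed) inside an iteratively reweighted
#' working-response loop for the logistic link. A ridge penalty `lambda1`
#' shrinks the item weights to control multicollinearity between food
#' items; no penalty is placed on the group coefficients (`lambda2 = 0`),
#' so the phenotype stays a linear combination of the items, not of
#' penalized group summaries.
#'
#' Identification: item columns are scaled by their sample standard
#' deviation (not centered, so the score formula remains exact at the
#' origin), each group component is renormalized to unit sample variance
#' after every sweep, and signs are fixed so each group's weights sum to a
#' nonnegative value. Flipping the sign of any (w-subvector, beta) pair
#' leaves the likelihood unchanged; the canonicalization makes output
#' deterministic.
#'
#' @param g Binary item-indicator matrix (n x items), columns in panel
#'   order, e.g. from [indicator_matrix()].
#' @param y Binary 0/1 outcome vector.
#' @param panel A [food_panel()] describing the column grouping.
#' @param lambda1 Nonnegative ridge penalty on the item weights.
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Maximum number of ALS sweeps.
#' @return An object of class `hiscom_fit` with elements `w` (named item
#'   weights), `beta` (named group coefficients), `beta0`, `lambda1`,
#'   `lambda2` (always 0), `scale` (per-item SDs used internally),
#'   `loading` (per-item coefficients on the raw indicator scale, so that
#'   the per-subject score is `g %*% loading`), `objective` (penalized
#'   deviance trace), `n_iter`, `converged`.
#' @seealso [compute_hiscom_rfs()], [hiscom_permutation_test()],
#'   [select_lambda1()]
#' @export
fit_hiscom <- function(g, y, panel = default_food_panel(), lambda1 = 0,
                       tol = 1e-6, max_iter = 500L) {
  g <- as.matrix(g)
  if (!all(g %in% c(0, 1))) stop("`g` must contain only 0/1 indicators")
  if (ncol(g) != nrow(panel))
    stop("`g` has ", ncol(g), " columns but the panel has ", nrow(panel),
         " items")
  y <- as.numeric(y)
  if (length(y) != nrow(g)) stop("`y` not conformable with `g`")
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1")
  if (length(unique(y)) < 2L) stop("`y` is constant; nothing to fit")
  if (lambda1 < 0) stop("`lambda1` must be nonnegative")
  n <- nrow(g); p <- ncol(g)
  idx <- panel_group_index(panel)
  K <- length(idx)

  s <- apply(g, 2, stats::sd)
  if (any(s == 0)) {
    if (lambda1 == 0)
      stop("constant item column(s) with lambda1 = 0 (singular update): ",
           paste(panel$item[s == 0], collapse = ", "))
    s[s == 0] <- 1 # ridge keeps the update well-posed; weight shrinks to 0
  }
  Gs <- sweep(g, 2, s, "/")

  # normalize a (w, beta) pair to unit component variance + sign convention
  canonicalize <- function(w, beta) {
    for (k in seq_len(K)) {
      jk <- idx[[k]]
      sc <- stats::sd(as.numeric(Gs[, jk, drop = FALSE] %*% w[jk]))
      if (is.finite(sc) && sc > 0) {
        w[jk] <- w[jk] / sc
        beta[k] <- beta[k] * sc
      }
      if (sum(w[jk]) < 0) {
        w[jk] <- -w[jk]
        beta[k] <- -beta[k]
      }
    }
    list(w = w, beta = beta)
  }
  components <- function(w) {
    F <- matrix(0, n, K)
    for (k in seq_len(K))
      F[, k] <- Gs[, idx[[k]], drop = FALSE] %*% w[idx[[k]]]
    F
  }
  objective <- function(beta0, beta, w) {
    eta <- beta0 + components(w) %*% beta
    pi <- stats::plogis(eta)
    pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
    -2 * sum(y * log(pi) + (1 - y) * log(1 - pi)) + lambda1 * sum(w^2)
  }

  w <- rep(1, p)
  cn <- canonicalize(w, rep(0, K)); w <- cn$w
  beta <- rep(0, K); beta0 <- stats::qlogis(mean(y))
  obj <- objective(beta0, beta, w)
  trace <- obj
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    w_old <- w; beta_old <- beta; beta0_old <- beta0; obj_old <- obj

    # Step 1: weights fixed, update intercept and group coefficients by
    # weighted least squares on the IRLS working response
    F <- components(w)
    eta <- as.numeric(beta0 + F %*% beta)
    pi <- stats::plogis(eta)
    v <- pmax(pi * (1 - pi), 1e-10)
    z <- eta + (y - pi) / v
    cf <- stats::lm.wfit(cbind(`(Intercept)` = 1, F), z, v)$coefficients
    cf[is.na(cf)] <- 0
    beta0_new <- cf[1]; beta_new <- cf[-1]

    # Step 2: coefficients fixed, ridge-penalized weight update (joint
    # across groups; the blocks are additive in the linear predictor)
    eta <- as.numeric(beta0_new + components(w) %*% beta_new)
    pi <- stats::plogis(eta)
    v <- pmax(pi * (1 - pi), 1e-10)
    z <- eta + (y - pi) / v
    active <- abs(beta_new) > 1e-10
    w_new <- w
    if (any(active)) {
      cols <- unlist(idx[active], use.names = FALSE)
      X <- Gs[, cols, drop = FALSE]
      mult <- rep(beta_new[active], lengths(idx[active]))
      X <- sweep(X, 2, mult, "*")
      XtV <- t(X * v)
      A <- XtV %*% X + diag(lambda1, length(cols))
      rhs <- XtV %*% (z - beta0_new)
      sol <- tryCatch(solve(A, rhs), error = function(e)
        stop("singular weight update; increase lambda1 (", conditionMessage(e),
             ")"))
      w_new[cols] <- as.numeric(sol)
    }
    cn <- canonicalize(w_new, beta_new)
    w_new <- cn$w; beta_new <- cn$beta

    # step-halving keeps the penalized deviance non-increasing
    alpha <- 1
    repeat {
      w_try <- (1 - alpha) * w_old + alpha * w_new
      beta_try <- (1 - alpha) * beta_old + alpha * beta_new
      beta0_try <- (1 - alpha) * beta0_old + alpha * beta0_new
      cn <- canonicalize(w_try, beta_try)
      obj_try <- objective(beta0_try, cn$beta, cn$w)
      if (obj_try <= obj_old + 1e-10 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    if (alpha < 1e-4 && obj_try > obj_old + 1e-10) {
      # objective stalled: keep previous iterate
      converged <- TRUE
      break
    }
    w <- cn$w; beta <- cn$beta; beta0 <- beta0_try; obj <- obj_try
    trace <- c(trace, obj)

    delta <- max(abs(c(w - w_old, beta - beta_old, beta0 - beta0_old)))
    scale_ref <- max(1, abs(c(w_old, beta_old, beta0_old)))
    if (delta / scale_ref < tol) {
      converged <- TRUE
      break
    }
  }
  names(w) <- panel$item
  names(beta) <- names(idx)
  loading <- w / s * rep(beta, lengths(idx))
  names(loading) <- panel$item
  structure(list(w = w, beta = beta, beta0 = unname(beta0),
                 lambda1 = lambda1, lambda2 = 0,
                 scale = stats::setNames(s, panel$item),
                 loading = loading, panel = panel,
                 objective = trace, n_iter = it, converged = converged,
                 n = n),
            class = "hiscom_fit")
}

#' @export
print.hiscom_fit <- function(x, ...) {
  cat("Hierarchical structural component fit\n")
  cat(sprintf("  n = %d subjects, %d items in %d groups\n",
              x$n, length(x$w), length(x$beta)))
  cat(sprintf("  lambda1 = %g (lambda2 = 0), %d iterations, %s\n",
              x$lambda1, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat("  group coefficients:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Weighted food score from a fitted hierarchical component model
#'
#' Evaluates the fitted linear combination
#' \eqn{\sum_k [\sum_t g_{itk} w_{tk}] \beta_k} per subject (the intercept
#' is excluded), using the item scaling stored in the fit.
#'
#' @param fit A [fit_hiscom()] result.
#' @param g Binary indicator matrix with the same columns as the fit.
#' @return Numeric score vector, one value per row of `g`.
#' @export
compute_hiscom_rfs <- function(fit, g) {
  stopifnot(inherits(fit, "hiscom_fit"))
  g <- as.matrix(g)
  if (ncol(g) != length(fit$loading))
    stop("`g` has ", ncol(g), " columns; fit expects ", length(fit$loading))
  as.numeric(g %*% fit$loading)
}

#' Permutation inference for the hierarchical component model
#'
#' Refits the model under `B` random permutations of the phenotype and
#' compares the magnitude of each group coefficient and item weight with its
#' permutation distribution, giving per-parameter p-values
#' `(1 + #{|perm| >= |obs|}) / (B + 1)`.
#'
#' @inheritParams fit_hiscom
#' @param B Number of permutations (at least 100 recommended for reporting;
#'   any positive count is accepted).
#' @param seed Integer seed controlling the permutations.
#' @return List of class `hiscom_perm`: `perm_p_beta` (named, per group),
#'   `perm_p_w` (named, per item), `observed` fit, `B`, `seed`.
#' @export
hiscom_permutation_test <- function(g, y, panel = default_food_panel(),
                                    lambda1 = 0, B = 999L, seed = 1L,
                                    tol = 1e-6, max_iter = 500L) {
  if (B < 1) stop("`B` must be a positive permutation count")
  obs <- fit_hiscom(g, y, panel, lambda1, tol = tol, max_iter = max_iter)
  count_beta <- rep(0L, length(obs$beta))
  count_w <- rep(0L, length(obs$w))
  set.seed(seed)
  for (b in seq_len(B)) {
    fp <- fit_hiscom(g, sample(y), panel, lambda1, tol = tol,
                     max_iter = max_iter)
    count_beta <- count_beta + (abs(fp$beta) >= abs(obs$beta))
    count_w <- count_w + (abs(fp$w) >= abs(obs$w))
  }
  structure(list(
    perm_p_beta = stats::setNames((1 + count_beta) / (B + 1),
                                  names(obs$beta)),
    perm_p_w = stats::setNames((1 + count_w) / (B + 1), names(obs$w)),
    observed = obs, B = as.integer(B), seed = as.integer(seed)),
    class = "hiscom_perm")
}

#' Choose the item ridge penalty by cross-validated deviance
#'
#' K-fold cross-validation over a penalty grid: each candidate `lambda1` is
#' scored by the mean held-out binomial deviance of the fitted model, and
#' the smallest penalty attaining the minimum is returned.
#'
#' @inheritParams fit_hiscom
#' @param grid Nonempty vector of candidate nonnegative penalties.
#' @param k_folds Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return The selected `lambda1`, with attribute `cv_deviance` (named mean
#'   held-out deviance per grid value).
#' @export
select_lambda1 <- function(g, y, panel = default_food_panel(),
                           grid = c(0.1, 1, 10, 100), k_folds = 5L,
                           seed = 1L, tol = 1e-6, max_iter = 500L) {
  if (!length(grid)) stop("`grid` must be nonempty")
  grid <- sort(as.numeric(grid))
  g <- as.matrix(g); y <- as.numeric(y)
  n <- nrow(g)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), n))
  for (f in seq_len(k_folds))
    if (length(unique(y[fold != f])) < 2L)
      stop("fold ", f, " leaves a constant training phenotype")
  cv <- vapply(grid, function(l1) {
    dev <- vapply(seq_len(k_folds), function(f) {
      tr <- fold != f
      fit <- fit_hiscom(g[tr, , drop = FALSE], y[tr], panel, l1,
                        tol = tol, max_iter = max_iter)
      eta <- fit$beta0 + compute_hiscom_rfs(fit, g[!tr, , drop = FALSE])
      pi <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
      -2 * mean(y[!tr] * log(pi) + (1 - y[!tr]) * log(1 - pi))
    }, numeric(1))
    mean(dev)
  }, numeric(1))
  best <- grid[which.min(cv)] # grid sorted: ties resolve to the smaller
  structure(best, cv_deviance = stats::setNames(cv, grid))
}

#' Serialize a hierarchical component fit to JSON
#'
#' Writes (or reads back) the fitted parameters -- items, groups, weights,
#' coefficients, intercept, penalty and convergence trace -- as a plain-text
#' JSON parameter file.
#'
#' @param fit A `hiscom_fit`.
#' @param path Output file path.
#' @return `write_hiscom_fit` returns `path` invisibly; `read_hiscom_fit`
#'   returns a list of the stored parameters.
#' @export
write_hiscom_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hiscom_fit"))
  obj <- list(items = names(fit$w), groups = fit$panel$group,
              w = unname(fit$w), beta = unname(fit$beta),
              group_names = names(fit$beta), beta0 = fit$beta0,
              lambda1 = fit$lambda1, lambda2 = fit$lambda2,
              scale = unname(fit$scale), loading = unname(fit$loading),
              objective = fit$objective, n_iter = fit$n_iter,
              converged = fit$converged, n = fit$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hiscom_fit
#' @export
read_hiscom_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
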
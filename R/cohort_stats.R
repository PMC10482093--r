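#' Summary-statistics group
#'
#' Container for a group summarized as mean, standard deviation and size,
#' as printed in baseline-characteristics tables.
#'
#' @param mean Group mean.
#' @param sd Nonnegative standard deviation.
#' @param n Group size (at least 2).
#' @return List of class `summary_group`.
#' @export
summary_group <- function(mean, sd, n) {
  if (sd < 0) stop("`sd` must be nonnegative")
  if (n < 2) stop("`n` must be at least 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_group")
}

#' Two-sample t-test from summary statistics
#'
#' Textbook two-sample t-test computed from (mean, SD, n) summaries, as
#' needed to recompute baseline-table p-values from printed numbers. Both
#' the Welch (unequal variances) and pooled-variance variants are
#' available; on summaries computed from raw vectors the result matches
#' `t.test()` on the raw data exactly.
#'
#' @param a,b [summary_group()] objects (plain lists with `mean`, `sd`,
#'   `n` are accepted).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List of class `htest` with `statistic`, `parameter` (df) and
#'   `p.value` (two-sided).
#' @examples
#' # diet-score row of a case-control baseline table
#' t_test_summary(summary_group(17.02, 7.53, 1090),
#'                summary_group(17.18, 7.56, 3202))$p.value
#' @export
t_test_summary <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (!is.list(a) || !is.list(b))
    stop("`a` and `b` must be summary_group lists")
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean)
    stop("both groups degenerate (sd = 0) with equal means")
  if (variant == "welch") {
    se2a <- a$sd^2 / a$n; se2b <- b$sd^2 / b$n
    stat <- (a$mean - b$mean) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    stat <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  p <- 2 * stats::pt(-abs(stat), df)
  structure(list(statistic = c(t = stat), parameter = c(df = df),
                 p.value = p,
                 method = paste0("Two-sample t-test from summaries (",
                                 variant, ")"),
                 data.name = "a vs b"),
            class = "htest")
}

#' Pearson chi-squared test on a contingency table
#'
#' Wrapper around [stats::chisq.test()] with an explicit Yates
#' continuity-correction policy: `"auto"` applies the correction exactly
#' for 2x2 tables (the convention behind printed baseline-table p-values),
#' `"on"`/`"off"` force it.
#'
#' @param tab Integer matrix of nonnegative counts, at least 2x2.
#' @param yates `"auto"`, `"on"` or `"off"`.
#' @return The `htest` from [stats::chisq.test()].
#' @export
chi2_test <- function(tab, yates = c("auto", "on", "off")) {
  yates <- match.arg(yates)
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative cell count")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal row/column")
  correct <- switch(yates, auto = all(dim(tab) == 2L), on = TRUE,
                    off = FALSE)
  suppressWarnings(stats::chisq.test(tab, correct = correct))
}

#' Nonparametric two-sample comparisons of score distributions
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) and two-sample Kolmogorov-Smirnov test, the pair used to
#' compare food-score distributions between cases and controls.
#'
#' @param x,y Nonempty numeric vectors.
#' @return List with `wilcoxon_statistic`, `wilcoxon_p`, `ks_statistic`,
#'   `ks_p`.
#' @export
rank_tests <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                           correct = TRUE))
  k <- suppressWarnings(stats::ks.test(x, y))
  list(wilcoxon_statistic = unname(w$statistic),
       wilcoxon_p = w$p.value,
       ks_statistic = unname(k$statistic),
       ks_p = k$p.value)
}

#' Baseline characteristics table
#'
#' Builds a case-vs-control descriptive table: continuous variables are
#' summarized as mean (SD) and compared by two-sample t-test; categorical
#' variables are summarized as n (%) per level and compared by chi-squared
#' test (Yates-corrected when 2x2).
#'
#' @param covariates Data.frame of baseline variables (a `subject_id`
#'   column is ignored).
#' @param scores Optional data.frame / named list of numeric scores to
#'   append as continuous rows.
#' @param phenotype Binary 0/1 case indicator.
#' @param variant t-test variant, `"welch"` or `"pooled"`.
#' @return Data.frame with columns `variable`, `level`, `case`, `control`,
#'   `p_value` (p only on the variable's header row).
#' @export
build_table1 <- function(covariates, scores = NULL, phenotype,
                         variant = "welch") {
  y <- as.numeric(phenotype)
  if (!all(y %in% c(0, 1))) stop("`phenotype` must be binary 0/1")
  vars <- covariates[setdiff(names(covariates), "subject_id")]
  if (!is.null(scores)) vars <- cbind(vars, as.data.frame(scores))
  if (nrow(vars) != length(y))
    stop("covariates not conformable with phenotype")
  rows <- list()
  fmt <- function(v) formatC(v, digits = 2, format = "f")
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (is.numeric(v)) {
      a <- summary_group(mean(v[y == 1]), stats::sd(v[y == 1]), sum(y == 1))
      b <- summary_group(mean(v[y == 0]), stats::sd(v[y == 0]), sum(y == 0))
      tt <- t_test_summary(a, b, variant)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = "",
        case = sprintf("%s (%s)", fmt(a$mean), fmt(a$sd)),
        control = sprintf("%s (%s)", fmt(b$mean), fmt(b$sd)),
        p_value = tt$p.value, stringsAsFactors = FALSE)
    } else if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      tab <- table(v, factor(y, levels = c(1, 0)))
      ct <- chi2_test(unclass(tab)[, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = "", case = "", control = "",
        p_value = ct$p.value, stringsAsFactors = FALSE)
      for (lev in levels(v)) {
        n1 <- sum(v == lev & y == 1); n0 <- sum(v == lev & y == 0)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = nm, level = lev,
          case = sprintf("%d (%s)", n1, fmt(100 * n1 / sum(y == 1))),
          control = sprintf("%d (%s)", n0, fmt(100 * n0 / sum(y == 0))),
          p_value = NA_real_, stringsAsFactors = FALSE)
      }
    } else {
      stop("variable `", nm, "` is neither numeric nor categorical")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
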
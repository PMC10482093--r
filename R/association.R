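#' Standardize a score vector
#'
#' Centers to mean 0 and scales to unit standard deviation; used so that
#' odds ratios for the different food scores are per-SD and comparable.
#'
#' @param x Numeric vector with positive standard deviation.
#' @return Standardized numeric vector.
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) stop("cannot standardize a constant score")
  (x - mean(x)) / s
}

# shared glm-with-guards fit; returns the glm object
.fit_logistic <- function(df, formula) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged)
    stop("perfect (or quasi-perfect) separation; odds ratio not estimable")
  if (anyNA(stats::coef(fit)))
    stop("collinear covariates: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  fit
}

# Wald OR rows for selected coefficients of a logistic fit
.or_rows <- function(fit, terms) {
  sm <- summary(fit)$coefficients
  zc <- stats::qnorm(0.975)
  out <- data.frame(term = terms,
                    or = exp(sm[terms, "Estimate"]),
                    l95 = exp(sm[terms, "Estimate"] - zc * sm[terms, "Std. Error"]),
                    u95 = exp(sm[terms, "Estimate"] + zc * sm[terms, "Std. Error"]),
                    p_value = sm[terms, "Pr(>|z|)"],
                    n = length(fit$y),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("or_result", "data.frame")
  out
}

#' Covariate-adjusted association between a food score and the outcome
#'
#' Logistic regression of the case-control outcome on the score, adjusted
#' for the supplied covariates (in the study design: age, sex, area, BMI,
#' smoking, alcohol, coffee, education, income and METs). Reports the
#' score term's odds ratio with Wald 95% CI and two-sided p-value.
#'
#' @param y Binary 0/1 outcome.
#' @param score Numeric score (standardize first for per-SD odds ratios).
#' @param covariates Optional data.frame of adjustment variables (a
#'   `subject_id` column is ignored).
#' @return One-row data.frame of class `or_result`: `term`, `or`, `l95`,
#'   `u95`, `p_value`, `n`.
#' @export
fit_association <- function(y, score, covariates = NULL) {
  df <- data.frame(.y = as.numeric(y), score = as.numeric(score))
  if (!all(df$.y %in% c(0, 1))) stop("`y` must be binary 0/1")
  if (!is.null(covariates))
    df <- cbind(df, covariates[setdiff(names(covariates), "subject_id")])
  fit <- .fit_logistic(df, .y ~ .)
  .or_rows(fit, "score")
}

#' Diet-quality (or genetic-risk) tertile groups
#'
#' Rank-based partition at the 33.33%/66.6% fractions (i.e. thirds;
#' reported cut percentages are the rounded thirds and the defaults use
#' the exact values so tie-free groups have size n/3 within one): subjects
#' whose score percentile-rank falls below the first cut are `low`, below
#' the second `intermediate`, and the rest `high`. Ties share an average
#' rank, so equal scores are never split across groups; the percentile
#' rank of rank r is (r - 0.5)/n.
#'
#' @param score Numeric vector, length at least 3.
#' @param fractions Increasing pair of cut fractions in (0,1).
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
tertile_groups <- function(score, fractions = c(1, 2) / 3) {
  n <- length(score)
  if (n < 3) stop("need at least 3 subjects to form tertiles")
  if (length(fractions) != 2 || fractions[1] >= fractions[2] ||
      fractions[1] <= 0 || fractions[2] >= 1)
    stop("`fractions` must be strictly increasing within (0, 1)")
  pr <- (rank(score, ties.method = "average") - 0.5) / n
  out <- factor(ifelse(pr < fractions[1], "low",
                       ifelse(pr < fractions[2], "intermediate", "high")),
                levels = c("low", "intermediate", "high"))
  if (length(unique(out)) < 3L)
    warning("ties collapse the tertile grouping to ",
            length(unique(out)), " group(s)")
  out
}

#' Odds ratios for diet-quality groups against a reference group
#'
#' Dummy-coded logistic regression of the outcome on the group factor
#' (plus covariates), reporting one odds-ratio row per non-reference
#' group. In the study design the `high` diet-quality group is the
#' reference.
#'
#' @inheritParams fit_association
#' @param groups Factor of group labels (e.g. from [tertile_groups()]).
#' @param reference Reference group label.
#' @return Data.frame of class `or_result`, one row per non-reference
#'   group.
#' @export
group_association <- function(y, groups, reference = "high",
                              covariates = NULL) {
  groups <- factor(groups)
  if (!reference %in% levels(groups))
    stop("reference level `", reference, "` not present")
  counts <- table(groups)
  if (any(counts == 0))
    stop("empty group(s): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  groups <- stats::relevel(droplevels(groups), ref = reference)
  df <- data.frame(.y = as.numeric(y), grp = groups)
  if (!is.null(covariates))
    df <- cbind(df, covariates[setdiff(names(covariates), "subject_id")])
  fit <- .fit_logistic(df, .y ~ .)
  terms <- paste0("grp", setdiff(levels(groups), reference))
  out <- .or_rows(fit, terms)
  out$term <- sub("^grp", "", out$term)
  out
}
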
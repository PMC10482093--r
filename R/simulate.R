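#' Configure a synthetic case-control cohort
#'
#' Bundles the ground truth of a simulated gene-diet cohort: sample size and
#' case fraction, FFQ category probabilities, per-item weights and per-group
#' coefficients of the planted diet model, SNP panel size and allele
#' frequencies, planted SNP-by-score interaction effects and covariate
#' effects. Defaults emulate a cohort of 4,292 subjects (1,090 cases, 3,202
#' controls) of 40-69 year olds with a mean unweighted diet score near 17 of
#' 46 points, matching the marginal structure the analysis assumes. Group
#' coefficients default to log-odds 0.3-0.6 per SD of the group component --
#' a deliberately well-powered planted-signal regime used to validate
#' parameter recovery.
#'
#' @param n_subjects Number of subjects.
#' @param case_fraction Target case proportion in (0,1); the phenotype
#'   intercept is tuned so the expected case fraction matches it.
#' @param n_snps Number of simulated SNPs.
#' @param maf_range Length-2 minor-allele-frequency range; the lower bound
#'   may not drop below 0.05 (upstream QC removes rarer variants).
#' @param true_item_weights Length-46 vector of planted item weights, in
#'   panel order.
#' @param true_group_coefs Length-10 vector of planted group coefficients
#'   (log-odds per SD of the group component), in canonical group order.
#' @param interaction_effects Named numeric vector: names are SNP ids (or
#'   indices) and values are planted interaction log-odds per unit
#'   dosage x standardized diet score.
#' @param covariate_effects Named numeric vector of covariate log-odds;
#'   numeric covariates (`age`, `bmi`, `mets`) act per centered unit, factor
#'   levels via `var_level` names (e.g. `sex_male`).
#' @param food_category_probs Length-9 probabilities over the food frequency
#'   categories (must sum to 1).
#' @param meal_category_probs Length-5 probabilities over the meal-frequency
#'   categories (must sum to 1).
#' @param seed Integer seed; every simulation operation derives its RNG
#'   stream from it, so equal configs reproduce equal cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_subjects = 4292L,
                              case_fraction = 1090 / 4292,
                              n_snps = 100L,
                              maf_range = c(0.05, 0.5),
                              true_item_weights = default_item_weights(),
                              true_group_coefs = default_group_coefs(),
                              interaction_effects = numeric(0),
                              covariate_effects = c(age = 0.05,
                                                    sex_male = 0.3,
                                                    bmi = 0.10),
                              food_category_probs = default_food_probs(),
                              meal_category_probs = default_meal_probs(),
                              seed = 1L) {
  stopifnot(n_subjects >= 1, n_snps >= 1)
  if (!(case_fraction > 0 && case_fraction < 1))
    stop("`case_fraction` must lie strictly in (0, 1)")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2])
    stop("`maf_range` must be an increasing pair")
  if (maf_range[1] < 0.05 || maf_range[2] > 0.5)
    stop("`maf_range` must stay within [0.05, 0.5] (post-QC frequencies)")
  if (length(true_item_weights) != 46)
    stop("`true_item_weights` must have length 46")
  if (length(true_group_coefs) != 10)
    stop("`true_group_coefs` must have length 10")
  .check_probs(food_category_probs, 9L, "food_category_probs")
  .check_probs(meal_category_probs, 5L, "meal_category_probs")
  if (length(interaction_effects) &&
      is.null(names(interaction_effects)))
    stop("`interaction_effects` must be a named vector (SNP ids or indices)")
  cfg <- list(n_subjects = as.integer(n_subjects),
              case_fraction = case_fraction,
              n_snps = as.integer(n_snps),
              maf_range = maf_range,
              true_item_weights = as.numeric(true_item_weights),
              true_group_coefs = as.numeric(true_group_coefs),
              interaction_effects = interaction_effects,
              covariate_effects = covariate_effects,
              food_category_probs = food_category_probs,
              meal_category_probs = meal_category_probs,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.check_probs <- function(p, len, what) {
  if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("`", what, "` must be ", len,
         " nonnegative probabilities summing to 1")
}

#' @rdname simulation_config
#' @details `default_item_weights()` spaces weights evenly from 0.4 to 1.6
#'   within each multi-item group (1.0 for single-item groups), so items
#'   within a group contribute unequally -- the heterogeneity the weighted
#'   scores are designed to recover. `default_group_coefs()` assigns each of
#'   the ten groups a log-odds between 0.3 and 0.6 per component SD.
#' @export
default_item_weights <- function() {
  panel <- default_food_panel()
  unlist(lapply(panel_group_index(panel), function(idx) {
    if (length(idx) == 1L) 1.0 else seq(0.4, 1.6, length.out = length(idx))
  }), use.names = FALSE)
}

#' @rdname simulation_config
#' @export
default_group_coefs <- function() seq(0.3, 0.6, length.out = 10)

#' @rdname simulation_config
#' @export
default_food_probs <- function() {
  # weekly-or-more mass 0.37: reproduces a mean RFS near the observed 17/46
  c(0.35, 0.28, 0.12, 0.08, 0.06, 0.04, 0.04, 0.02, 0.01)
}

#' @rdname simulation_config
#' @export
default_meal_probs <- function() c(0.08, 0.25, 0.50, 0.05, 0.12)

#' Simulate FFQ frequency categories
#'
#' Draws each food item's frequency category independently from the
#' configured category probabilities, and the daily-meal-frequency item from
#' its five categories. Items are independent by design: realistic food-item
#' correlation structure is out of scope.
#'
#' @param config A [simulation_config()].
#' @param panel A [food_panel()].
#' @return Data.frame with `subject_id` plus one category column per item.
#' @export
simulate_ffq <- function(config, panel = default_food_panel()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_subjects
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  food_cats <- ffq_food_categories()
  meal_cats <- ffq_meal_categories()
  for (j in seq_len(nrow(panel))) {
    if (panel$group[j] == "meals") {
      out[[panel$item[j]]] <- sample(meal_cats, n, replace = TRUE,
                                     prob = config$meal_category_probs)
    } else {
      out[[panel$item[j]]] <- sample(food_cats, n, replace = TRUE,
                                     prob = config$food_category_probs)
    }
  }
  out
}

#' Simulate baseline covariates
#'
#' Independent draws loosely matched to the cohort's marginal distributions:
#' age truncated normal on 40-69, BMI and METs normal, and categorical
#' lifestyle variables (sex, area, smoking, alcohol, coffee, education,
#' income) with plausible level frequencies. Joint dependence between
#' covariates is deliberately not modelled.
#'
#' @inheritParams simulate_ffq
#' @return Data.frame of the ten adjustment covariates plus `subject_id`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_subjects
  rtrunc_norm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  fac <- function(levels, probs)
    factor(sample(levels, n, replace = TRUE, prob = probs), levels = levels)
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = round(rtrunc_norm(n, 51, 8.5, 40, 69), 1),
    sex = fac(c("female", "male"), c(0.52, 0.48)),
    area = fac(c("ansan", "ansung"), c(0.60, 0.40)),
    bmi = round(rtrunc_norm(n, 24.5, 3.0, 14, 45), 2),
    smoking = fac(c("former", "occasional"), c(0.78, 0.22)),
    alcohol = fac(c("non_drinker", "former_drinker"), c(0.52, 0.48)),
    coffee = fac(c("never", "monthly", "weekly", "daily"),
                 c(0.23, 0.03, 0.20, 0.54)),
    education = fac(c("elementary", "middle", "high", "higher"),
                    c(0.29, 0.22, 0.34, 0.15)),
    income = fac(c("lt1", "1to2", "2to3", "3to4", "gt4"),
                 c(0.30, 0.29, 0.20, 0.12, 0.09)),
    mets = round(rtrunc_norm(n, 42.2, 24.2, 0, 200), 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP gets a minor-allele frequency drawn uniformly from the
#' configured range (or supplied directly) and additive dosages drawn as
#' Binomial(2, MAF), i.e. Hardy-Weinberg proportions. No linkage
#' disequilibrium is modelled.
#'
#' @inheritParams simulate_ffq
#' @param mafs Optional vector of per-SNP minor-allele frequencies
#'   (recycled); each must lie inside `config$maf_range`.
#' @return List with `dosage` (n x m integer matrix, columns named by SNP
#'   id; counted allele is the minor/effect allele `a1`) and `info`
#'   (data.frame: snp, chr, pos, a1, a2, maf).
#' @export
simulate_genotypes <- function(config, mafs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  m <- config$n_snps
  if (is.null(mafs)) {
    mafs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  } else {
    mafs <- rep_len(mafs, m)
    if (any(mafs < config$maf_range[1] - 1e-12 |
            mafs > config$maf_range[2] + 1e-12))
      stop("supplied MAF outside `maf_range`")
  }
  n <- config$n_subjects
  dosage <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), integer(n))
  if (n == 1L) dosage <- matrix(dosage, nrow = 1L)
  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, m, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1L), character(1))
  info <- data.frame(
    snp = sprintf("rs%06d", seq_len(m)),
    chr = as.integer(((seq_len(m) - 1L) %% 22L) + 1L),
    pos = as.integer(100000L + ((seq_len(m) - 1L) %/% 22L) * 50000L),
    a1 = a1, a2 = a2, maf = mafs,
    stringsAsFactors = FALSE
  )
  colnames(dosage) <- info$snp
  rownames(dosage) <- sprintf("S%05d", seq_len(n))
  list(dosage = dosage, info = info)
}

# planted linear predictor shared by simulate_phenotype and its tests:
# standardized group components weighted by the group coefficients
planted_diet_score <- function(g, config, panel = default_food_panel()) {
  idx <- panel_group_index(panel)
  eta <- numeric(nrow(g))
  for (k in seq_along(idx)) {
    comp <- as.numeric(g[, idx[[k]], drop = FALSE] %*%
                         config$true_item_weights[idx[[k]]])
    s <- stats::sd(comp)
    if (is.na(s) || s == 0) next
    eta <- eta + config$true_group_coefs[k] * (comp - mean(comp)) / s
  }
  eta
}

#' Simulate a binary phenotype from planted effects
#'
#' The linear predictor is the planted hierarchical diet model (standardized
#' group components times group coefficients) plus covariate effects plus
#' any planted SNP-by-score interaction terms; the intercept is tuned by
#' bisection so that the expected case fraction equals the configured one,
#' and the phenotype is drawn Bernoulli.
#'
#' @param ffq FFQ table from [simulate_ffq()].
#' @param genotypes List from [simulate_genotypes()] (or `NULL` if the
#'   config plants no interaction effects).
#' @param covariates Data.frame from [simulate_covariates()] (or `NULL`).
#' @inheritParams simulate_ffq
#' @return Integer 0/1 vector with attributes `true_score` (the
#'   standardized planted diet score entering the interaction terms),
#'   `intercept`, and `linear_predictor`.
#' @export
simulate_phenotype <- function(ffq, genotypes = NULL, covariates = NULL,
                               config, panel = default_food_panel()) {
  stopifnot(inherits(config, "sim_config"))
  g <- indicator_matrix(ffq, panel)
  n <- nrow(g)
  eta <- planted_diet_score(g, config, panel)
  s_eta <- stats::sd(eta)
  true_score <- if (is.na(s_eta) || s_eta == 0) rep(0, n)
                else (eta - mean(eta)) / s_eta
  if (!is.null(covariates)) {
    if (nrow(covariates) != n) stop("covariates not conformable with FFQ")
    for (nm in names(config$covariate_effects)) {
      b <- config$covariate_effects[[nm]]
      if (nm %in% names(covariates) && is.numeric(covariates[[nm]])) {
        x <- covariates[[nm]]
        eta <- eta + b * (x - mean(x))
      } else {
        hit <- vapply(names(covariates), function(v)
          is.factor(covariates[[v]]) && startsWith(nm, paste0(v, "_")),
          logical(1))
        if (!any(hit))
          stop("covariate effect `", nm, "` matches no covariate")
        v <- names(covariates)[which(hit)[1]]
        lev <- sub(paste0("^", v, "_"), "", nm)
        eta <- eta + b * as.numeric(covariates[[v]] == lev)
      }
    }
  }
  if (length(config$interaction_effects)) {
    if (is.null(genotypes)) stop("interaction effects need genotypes")
    if (nrow(genotypes$dosage) != n)
      stop("genotypes not conformable with FFQ")
    nm <- names(config$interaction_effects)
    j <- suppressWarnings(as.integer(nm))
    j <- ifelse(is.na(j), match(nm, colnames(genotypes$dosage)), j)
    if (anyNA(j)) stop("unknown SNP in `interaction_effects`")
    for (i in seq_along(j))
      eta <- eta + config$interaction_effects[[i]] *
        genotypes$dosage[, j[i]] * true_score
  }
  # bisection on the intercept so mean(expit(b0 + eta)) hits case_fraction
  f <- function(b0) mean(stats::plogis(b0 + eta)) - config$case_fraction
  b0 <- stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
  set.seed(config$seed + 4L)
  y <- stats::rbinom(n, 1L, stats::plogis(b0 + eta))
  structure(y, true_score = true_score, intercept = b0,
            linear_predictor = b0 + eta)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_ffq()], [simulate_covariates()],
#' [simulate_genotypes()] and [simulate_phenotype()] under one config.
#'
#' @inheritParams simulate_ffq
#' @param genotypes Logical: simulate genotypes too?
#' @return List of class `sim_cohort`: `config`, `panel`, `ffq`,
#'   `covariates`, `genotypes`, `phenotype` (with ground-truth attributes),
#'   and `g` (the indicator matrix).
#' @export
simulate_cohort <- function(config = simulation_config(),
                            panel = default_food_panel(),
                            genotypes = TRUE) {
  ffq <- simulate_ffq(config, panel)
  cov <- simulate_covariates(config)
  geno <- if (genotypes) simulate_genotypes(config) else NULL
  y <- simulate_phenotype(ffq, geno, cov, config, panel)
  structure(list(config = config, panel = panel, ffq = ffq,
                 covariates = cov, genotypes = geno, phenotype = y,
                 g = indicator_matrix(ffq, panel)),
            class = "sim_cohort")
}
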
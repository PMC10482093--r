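#' Polygenic risk score as a weighted allele sum
#'
#' Computes per-subject PRS as the sum over SNPs of the external effect
#' size times the effect-allele dosage. Effect alleles are harmonized
#' against the genotype panel: when the weight file's effect allele is the
#' panel's other allele the dosage is flipped to `2 - d`; SNPs whose
#' effect allele matches neither panel allele are excluded with a warning
#' count, as are weight-file SNPs absent from the panel.
#'
#' @param dosages Additive dosage matrix (n x m), columns named by SNP id;
#'   the counted allele is `snp_info$a1`.
#' @param snp_info Data.frame with columns `snp`, `a1`, `a2`.
#' @param weights Data.frame with columns `snp`, `effect_allele`, `beta`
#'   (log-odds scale), e.g. from [read_prs_weights()].
#' @return Numeric PRS vector with attributes `n_used` and `n_excluded`.
#' @export
compute_prs <- function(dosages, snp_info, weights) {
  dosages <- as.matrix(dosages)
  if (anyDuplicated(weights$snp)) stop("duplicated SNP ids in weights")
  if (!all(weights$effect_allele %in% c("A", "C", "G", "T")))
    stop("effect alleles must be A/C/G/T")
  prs <- numeric(nrow(dosages))
  n_used <- 0L; n_excluded <- 0L
  j <- match(weights$snp, snp_info$snp)
  for (i in seq_len(nrow(weights))) {
    if (is.na(j[i])) { n_excluded <- n_excluded + 1L; next }
    a1 <- snp_info$a1[j[i]]; a2 <- snp_info$a2[j[i]]
    d <- dosages[, snp_info$snp[j[i]]]
    ea <- weights$effect_allele[i]
    if (ea == a1) {
      prs <- prs + weights$beta[i] * d
    } else if (ea == a2) {
      prs <- prs + weights$beta[i] * (2 - d)
    } else {
      n_excluded <- n_excluded + 1L
      next
    }
    n_used <- n_used + 1L
  }
  if (n_excluded > 0L)
    warning(n_excluded, " weight-file SNP(s) excluded ",
            "(absent from panel or unresolvable allele)")
  structure(prs, n_used = n_used, n_excluded = n_excluded)
}

# Wald statistics for one column of a glm.fit design
.glmfit_wald <- function(X, y, col) {
  fit <- suppressWarnings(stats::glm.fit(X, y,
                                         family = stats::binomial()))
  r <- fit$rank
  piv <- fit$qr$pivot[seq_len(r)]
  if (!(col %in% piv) || !fit$converged) return(NULL)
  R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  V <- chol2inv(R)
  k <- match(col, piv)
  beta <- fit$coefficients[col]
  se <- sqrt(V[k, k])
  z <- beta / se
  list(beta = unname(beta), se = se, p = 2 * stats::pnorm(-abs(z)),
       deviance = fit$deviance, rank = r)
}

#' Per-SNP score-by-genotype interaction scan
#'
#' For each SNP fits the logistic model
#' `y ~ covariates + score + snp + snp:score` and records the interaction
#' term (the gene-diet "interaction effect", as opposed to the SNP or
#' score main effects). SNPs that are monomorphic in-sample or fall below
#' the minor-allele-frequency floor are skipped with a recorded reason,
#' mirroring upstream genotype QC.
#'
#' @param y Binary 0/1 outcome.
#' @param dosages Additive dosage matrix (n x m) with SNP-id column names.
#' @param score Numeric food score; standardize first so interaction
#'   log-odds are per SD of diet quality.
#' @param covariates Optional adjustment data.frame.
#' @param snp_info Optional data.frame (`snp`, `chr`, `pos`) used to
#'   annotate the records.
#' @param maf_min In-sample MAF floor below which a SNP is skipped.
#' @return Data.frame, one row per SNP: `snp`, `chr`, `pos`, `beta`,
#'   `se`, `p_value`, `status` (`"ok"` or a skip reason).
#' @export
interaction_scan <- function(y, dosages, score, covariates = NULL,
                             snp_info = NULL, maf_min = 0.05) {
  dosages <- as.matrix(dosages)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(dosages) != n) stop("`dosages` not conformable with `y`")
  base <- data.frame(score = as.numeric(score))
  if (!is.null(covariates))
    base <- cbind(base, covariates[setdiff(names(covariates), "subject_id")])
  X0 <- stats::model.matrix(~ ., data = base)
  m <- ncol(dosages)
  ids <- colnames(dosages)
  if (is.null(ids)) ids <- sprintf("snp%d", seq_len(m))
  chr <- pos <- rep(NA_integer_, m)
  if (!is.null(snp_info)) {
    k <- match(ids, snp_info$snp)
    chr <- snp_info$chr[k]; pos <- snp_info$pos[k]
  }
  beta <- se <- p <- rep(NA_real_, m)
  status <- rep("ok", m)
  sc <- base$score
  for (j in seq_len(m)) {
    d <- dosages[, j]
    if (stats::var(d) == 0) { status[j] <- "skipped_monomorphic"; next }
    maf <- min(mean(d) / 2, 1 - mean(d) / 2)
    if (maf < maf_min) { status[j] <- "skipped_maf"; next }
    X <- cbind(X0, snp = d, `snp:score` = d * sc)
    res <- .glmfit_wald(X, y, ncol(X))
    if (is.null(res)) { status[j] <- "skipped_collinear"; next }
    beta[j] <- res$beta; se[j] <- res$se; p[j] <- res$p
  }
  data.frame(snp = ids, chr = chr, pos = pos, beta = beta, se = se,
             p_value = p, status = status, stringsAsFactors = FALSE)
}

#' Filter interaction records by significance threshold
#'
#' @param records Data.frame from [interaction_scan()].
#' @param alpha Significance threshold; records with `p_value < alpha`
#'   (and status `"ok"`) are retained.
#' @return The retained subset, with attribute `n_hits`.
#' @export
filter_hits <- function(records, alpha = 0.05) {
  if (!(alpha >= 0 && alpha <= 1)) stop("`alpha` must be in [0, 1]")
  keep <- !is.na(records$p_value) & records$p_value < alpha &
    records$status == "ok"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_hits = nrow(out))
}

#' Map SNPs to genes by position
#'
#' Assigns each SNP to every gene whose interval (optionally widened by a
#' symmetric window) contains its position. Intervals are 1-based and
#' closed, matching GRCh37-style gene-location tables.
#'
#' @param records Data.frame with `snp`, `chr`, `pos`.
#' @param gene_locations Data.frame with `gene`, `chr`, `start`, `end`.
#' @param window_kb Window in kilobases added on both sides of the gene
#'   body (default 0: gene body only).
#' @return Data.frame with one row per (gene, snp) assignment.
#' @export
map_snps_to_genes <- function(records, gene_locations, window_kb = 0) {
  if (anyNA(records$chr) || anyNA(records$pos))
    stop("records carry unknown chromosome/position labels")
  w <- window_kb * 1000
  rc <- as.character(records$chr)
  gc <- as.character(gene_locations$chr)
  out <- lapply(seq_len(nrow(gene_locations)), function(i) {
    hit <- rc == gc[i] &
      records$pos >= gene_locations$start[i] - w &
      records$pos <= gene_locations$end[i] + w
    if (!any(hit)) return(NULL)
    data.frame(gene = gene_locations$gene[i], snp = records$snp[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene = character(0), snp = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Li & Ji (2005) effective number of independent tests
.n_eff_tests <- function(dos) {
  if (ncol(dos) == 1L) return(1)
  cm <- suppressWarnings(stats::cor(dos))
  cm[!is.finite(cm)] <- 0; diag(cm) <- 1
  lam <- abs(eigen(cm, symmetric = TRUE, only.values = TRUE)$values)
  sum(as.numeric(lam >= 1) + (lam - floor(lam)))
}

#' Gene-level interaction test
#'
#' Aggregates the SNPs mapped to one gene into a single gene-diet
#' interaction p-value. `pc_regression` replaces the SNPs by principal
#' components capturing at least `var_explained` of the genotype variance
#' and jointly tests all PC-by-score interaction terms with a
#' likelihood-ratio test (a simplified principal-components regression in
#' the spirit of gene-based GWAS aggregation tools). `p_aggregation`
#' combines the per-SNP interaction p-values by a Sidak correction with
#' the Li-Ji effective number of tests.
#'
#' @inheritParams interaction_scan
#' @param dosages_in_gene Dosage matrix restricted to the gene's SNPs
#'   (at least one column).
#' @param mode `"pc_regression"` or `"p_aggregation"`.
#' @param var_explained Variance fraction the retained PCs must reach.
#' @return One-row data.frame: `n_snps`, `df`, `p_value`, `mode`.
#' @export
gene_test <- function(y, dosages_in_gene, score, covariates = NULL,
                      mode = c("pc_regression", "p_aggregation"),
                      var_explained = 0.95) {
  mode <- match.arg(mode)
  dos <- as.matrix(dosages_in_gene)
  if (ncol(dos) < 1L) stop("gene must contain at least one SNP")
  y <- as.numeric(y)
  base <- data.frame(score = as.numeric(score))
  if (!is.null(covariates))
    base <- cbind(base, covariates[setdiff(names(covariates), "subject_id")])
  X0 <- stats::model.matrix(~ ., data = base)
  if (mode == "pc_regression") {
    pc <- stats::prcomp(dos, center = TRUE, scale. = FALSE)
    keep <- pc$sdev > 1e-8
    vr <- cumsum(pc$sdev[keep]^2) / sum(pc$sdev[keep]^2)
    npc <- which(vr >= var_explained)[1]
    if (is.na(npc)) npc <- sum(keep)
    if (length(y) <= npc + ncol(X0) + npc)
      stop("too few subjects for ", npc, " principal components")
    P <- pc$x[, seq_len(npc), drop = FALSE]
    sc <- base$score
    X_red <- cbind(X0, P)
    X_full <- cbind(X_red, P * sc)
    f_red <- suppressWarnings(stats::glm.fit(X_red, y,
                                             family = stats::binomial()))
    f_full <- suppressWarnings(stats::glm.fit(X_full, y,
                                              family = stats::binomial()))
    df <- f_red$df.residual - f_full$df.residual
    p <- stats::pchisq(f_red$deviance - f_full$deviance, df,
                       lower.tail = FALSE)
    data.frame(n_snps = ncol(dos), df = df, p_value = p, mode = mode,
               stringsAsFactors = FALSE)
  } else {
    scan <- interaction_scan(y, dos, base$score,
                             covariates = if (is.null(covariates)) NULL
                             else covariates,
                             maf_min = 0)
    ps <- scan$p_value[scan$status == "ok"]
    if (!length(ps)) stop("no testable SNP in gene")
    meff <- .n_eff_tests(dos[, scan$status == "ok", drop = FALSE])
    p <- 1 - (1 - min(ps))^meff
    data.frame(n_snps = ncol(dos), df = meff, p_value = p, mode = mode,
               stringsAsFactors = FALSE)
  }
}

#' Competitive gene-set test with Benjamini-Hochberg correction
#'
#' Converts gene p-values to z-statistics by the probit transform and, for
#' each set, regresses the gene z-statistics on set membership; the
#' one-sided p-value for a positive membership coefficient asks whether
#' genes in the set score higher than genes outside it (a competitive
#' test). Set p-values are adjusted across sets by Benjamini-Hochberg.
#'
#' @param gene_results Data.frame with columns `gene` and `p_value`
#'   (at least two scored genes).
#' @param sets Named list of character vectors (gene sets), e.g. from
#'   [read_gmt()].
#' @return Data.frame: `set`, `n_genes` (scored members), `p_value`,
#'   `q_value`. Sets without scored genes are dropped with a warning.
#' @export
gene_set_test <- function(gene_results, sets) {
  if (!length(sets)) stop("empty gene-set collection")
  ok <- !is.na(gene_results$p_value)
  genes <- gene_results$gene[ok]
  if (length(genes) < 2L) stop("need at least two scored genes")
  pv <- pmin(pmax(gene_results$p_value[ok], 1e-15), 1 - 1e-15)
  z <- stats::qnorm(pv, lower.tail = FALSE)
  res <- lapply(names(sets), function(nm) {
    member <- genes %in% sets[[nm]]
    if (!any(member)) return(NULL)
    if (all(member)) {
      warning("set `", nm, "` contains every scored gene; dropped")
      return(NULL)
    }
    fit <- stats::lm(z ~ member)
    sm <- summary(fit)$coefficients
    tval <- sm["memberTRUE", "t value"]
    p <- stats::pt(tval, df = fit$df.residual, lower.tail = FALSE)
    data.frame(set = nm, n_genes = sum(member), p_value = p,
               stringsAsFactors = FALSE)
  })
  dropped <- vapply(res, is.null, logical(1))
  if (any(dropped & !vapply(names(sets), function(nm)
    any(genes %in% sets[[nm]]), logical(1))))
    warning(sum(dropped), " set(s) without scored genes dropped")
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable gene set")
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Genetic-risk by diet-quality interaction grid
#'
#' Cross-classifies subjects into nine cells by PRS tertile (genetic risk:
#' low/intermediate/high) and diet-quality tertile, and fits one
#' dummy-coded logistic model against the reference cell (low genetic
#' risk, high diet quality), adjusting for covariates. PRS tertiles use
#' the same rank rule as the diet tertiles.
#'
#' @inheritParams fit_association
#' @param prs Numeric polygenic risk score vector.
#' @param diet_groups Factor from [tertile_groups()] on a food score.
#' @return Data.frame with one row per cell: `genetic_risk`,
#'   `diet_quality`, `n`, `or`, `l95`, `u95`, `p_value`, `note` (the
#'   reference row has OR 1; empty cells are flagged and their OR omitted).
#' @export
risk_by_diet_grid <- function(y, prs, diet_groups, covariates = NULL) {
  grc <- tertile_groups(prs)
  diet_groups <- factor(diet_groups,
                        levels = c("low", "intermediate", "high"))
  cells <- expand.grid(genetic_risk = levels(grc),
                       diet_quality = levels(diet_groups),
                       stringsAsFactors = FALSE)
  cell_of <- interaction(grc, diet_groups, sep = ":", drop = FALSE)
  ref <- "low:high"
  cell_of <- stats::relevel(cell_of, ref = ref)
  counts <- table(cell_of)
  present <- names(counts)[counts > 0]
  if (!(ref %in% present)) stop("reference cell (low risk, high diet) empty")
  df <- data.frame(.y = as.numeric(y),
                   cell = factor(as.character(cell_of), levels = present))
  df$cell <- stats::relevel(df$cell, ref = ref)
  if (!is.null(covariates))
    df <- cbind(df, covariates[setdiff(names(covariates), "subject_id")])
  fit <- .fit_logistic(df, .y ~ .)
  out <- cells
  out$n <- as.integer(counts[paste0(out$genetic_risk, ":",
                                    out$diet_quality)])
  out$or <- out$l95 <- out$u95 <- out$p_value <- NA_real_
  out$note <- ""
  for (i in seq_len(nrow(out))) {
    lbl <- paste0(out$genetic_risk[i], ":", out$diet_quality[i])
    if (lbl == ref) {
      out$or[i] <- 1; out$note[i] <- "reference"
    } else if (out$n[i] == 0L) {
      out$note[i] <- "empty cell; OR omitted"
    } else {
      row <- .or_rows(fit, paste0("cell", lbl))
      out$or[i] <- row$or; out$l95[i] <- row$l95; out$u95[i] <- row$u95
      out$p_value[i] <- row$p_value
    }
  }
  out
}
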
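#' Configure an end-to-end pipeline run
#'
#' Collects every tunable of the pipeline: the simulation (or input file
#' paths), the item-ridge policy, permutation count, tertile fractions and
#' significance thresholds. Defaults follow the analysis design:
#' tertile cuts at 33.33%/66.6%, interaction thresholds 0.05 and 0.001,
#' FDR threshold 0.1.
#'
#' @param sim A [simulation_config()] describing the cohort to simulate,
#'   or `NULL` when `inputs` supplies files.
#' @param inputs Optional named list of file paths (`ffq`, `covariates`,
#'   `genotypes`, `phenotype`) read instead of simulating.
#' @param lambda1 Item ridge penalty: a number, or `"auto"` for
#'   cross-validated selection over `lambda1_grid`.
#' @param lambda1_grid Grid used when `lambda1 = "auto"`.
#' @param permutations Permutation count for the component-model inference
#'   (0 skips permutation p-values).
#' @param scan_score Which score drives the interaction scan and grid:
#'   `"rfs"`, `"hiscom"` or `"plsda"`.
#' @param tertile_fractions Increasing pair of rank cut points in (0,1).
#' @param alpha,alpha_strict Interaction p-value thresholds.
#' @param fdr_q FDR threshold annotated in the gene-set output.
#' @param window_kb Gene-mapping window in kb.
#' @param seed Master seed (also used for the simulation config when
#'   `sim` is `NULL` and inputs are absent).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, inputs = NULL,
                            lambda1 = "auto",
                            lambda1_grid = c(0.1, 1, 10),
                            permutations = 0L,
                            scan_score = c("rfs", "hiscom", "plsda"),
                            tertile_fractions = c(1, 2) / 3,
                            alpha = 0.05, alpha_strict = 0.001,
                            fdr_q = 0.1, window_kb = 0, seed = 1L) {
  scan_score <- match.arg(scan_score)
  if (!(is.numeric(lambda1) || identical(lambda1, "auto")))
    stop("`lambda1` must be numeric or \"auto\"")
  stopifnot(tertile_fractions[1] < tertile_fractions[2],
            tertile_fractions[1] > 0, tertile_fractions[2] < 1)
  for (a in c(alpha, alpha_strict, fdr_q))
    if (!(a > 0 && a <= 1)) stop("thresholds must lie in (0, 1]")
  structure(list(sim = sim, inputs = inputs, lambda1 = lambda1,
                 lambda1_grid = lambda1_grid,
                 permutations = as.integer(permutations),
                 scan_score = scan_score,
                 tertile_fractions = tertile_fractions,
                 alpha = alpha, alpha_strict = alpha_strict,
                 fdr_q = fdr_q, window_kb = window_kb,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full gene-diet analysis pipeline
#'
#' Executes the stages in order -- scoring, weighted-score fits,
#' baseline table, covariate-adjusted association, diet tertiles, the
#' SNP-by-score interaction scan, gene and gene-set aggregation, PRS and
#' the risk-by-diet grid -- writing one TSV per stage plus a JSON run
#' manifest into `out_dir`. Outputs are deterministic given the same
#' configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- default_food_panel()

  data <- .stage("load", {
    if (!is.null(config$inputs)) {
      ins <- config$inputs
      for (p in unlist(ins)) if (!file.exists(p))
        stop("missing input path: ", p)
      ffq <- read_tsv(ins$ffq)
      covariates <- read_tsv(ins$covariates)
      for (v in c("sex", "area", "smoking", "alcohol", "coffee",
                  "education", "income"))
        if (v %in% names(covariates))
          covariates[[v]] <- factor(covariates[[v]])
      genotypes <- read_genotypes(ins$genotypes, format = "raw")
      phenotype <- read_tsv(ins$phenotype)$phenotype
      list(ffq = ffq, covariates = covariates, genotypes = genotypes,
           phenotype = phenotype)
    } else {
      sim <- config$sim
      if (is.null(sim)) sim <- simulation_config(seed = config$seed)
      cohort <- simulate_cohort(sim, panel)
      write_cohort(cohort, file.path(out_dir, "cohort"))
      cohort
    }
  })
  covs <- data$covariates[setdiff(names(data$covariates), "subject_id")]
  y <- as.numeric(data$phenotype)

  scores <- .stage("score", {
    g <- indicator_matrix(data$ffq, panel)
    rfs <- compute_rfs(data$ffq, panel)
    l1 <- if (identical(config$lambda1, "auto"))
      as.numeric(select_lambda1(g, y, panel, grid = config$lambda1_grid,
                                seed = config$seed))
    else config$lambda1
    hfit <- fit_hiscom(g, y, panel, lambda1 = l1)
    write_hiscom_fit(hfit, file.path(out_dir, "hiscom_fit.json"))
    pfit <- fit_plsda(g, y)
    tab <- data.frame(subject_id = data$ffq$subject_id, rfs = rfs,
                      hiscom_rfs = compute_hiscom_rfs(hfit, g),
                      plsda_rfs = compute_plsda_rfs(pfit, g))
    write_tsv(tab, file.path(out_dir, "scores.tsv"))
    if (config$permutations > 0) {
      perm <- hiscom_permutation_test(g, y, panel, lambda1 = l1,
                                      B = config$permutations,
                                      seed = config$seed)
      write_tsv(data.frame(group = names(perm$perm_p_beta),
                           perm_p = unname(perm$perm_p_beta)),
                file.path(out_dir, "hiscom_perm_beta.tsv"))
      write_tsv(data.frame(item = names(perm$perm_p_w),
                           perm_p = unname(perm$perm_p_w)),
                file.path(out_dir, "hiscom_perm_w.tsv"))
    }
    list(g = g, table = tab, hiscom = hfit, plsda = pfit, lambda1 = l1)
  })

  .stage("table1", {
    t1 <- build_table1(covs, scores$table[c("rfs", "hiscom_rfs",
                                            "plsda_rfs")], y)
    write_tsv(t1, file.path(out_dir, "table1.tsv"))
  })

  assoc <- .stage("associate", {
    rows <- do.call(rbind, lapply(c("rfs", "hiscom_rfs", "plsda_rfs"),
      function(nm) {
        r <- fit_association(y, standardize(scores$table[[nm]]), covs)
        r$term <- nm
        r
      }))
    write_tsv(rows, file.path(out_dir, "association.tsv"))
    diet <- tertile_groups(scores$table[[paste0(
      sub("plsda", "plsda_rfs", sub("hiscom", "hiscom_rfs",
                                    config$scan_score)), "")]],
      config$tertile_fractions)
    grp <- group_association(y, diet, reference = "high", covs)
    write_tsv(grp, file.path(out_dir, "diet_group_association.tsv"))
    list(rows = rows, diet = diet)
  })

  scan <- .stage("interact", {
    sc <- standardize(scores$table[[sub("plsda", "plsda_rfs",
                                        sub("hiscom", "hiscom_rfs",
                                            config$scan_score))]])
    rec <- interaction_scan(y, data$genotypes$dosage, sc, covs,
                            snp_info = data$genotypes$info)
    write_tsv(rec, file.path(out_dir, "interaction.tsv"))
    hits <- filter_hits(rec, config$alpha)
    write_tsv(hits, file.path(out_dir,
                              sprintf("interaction_hits_p%g.tsv",
                                      config$alpha)))
    list(records = rec, hits = hits, score = sc)
  })

  genes <- .stage("gene-set", {
    info <- data$genotypes$info
    loc <- .synthetic_gene_locations(info)
    mapping <- map_snps_to_genes(scan$records, loc, config$window_kb)
    gres <- do.call(rbind, lapply(split(mapping$snp, mapping$gene),
      function(snps) gene_test(y, data$genotypes$dosage[, snps,
                                                        drop = FALSE],
                               scan$score, covs)))
    gres <- cbind(gene = rownames(gres), gres)
    rownames(gres) <- NULL
    write_tsv(gres, file.path(out_dir, "gene_results.tsv"))
    sets <- .synthetic_gene_sets(gres$gene)
    sres <- gene_set_test(gres, sets)
    sres$significant <- sres$q_value < config$fdr_q
    write_tsv(sres, file.path(out_dir, "gene_set_results.tsv"))
    list(locations = loc, gene = gres, sets = sres)
  })

  prs <- .stage("prs", {
    info <- data$genotypes$info
    set.seed(config$seed + 7L)
    w <- data.frame(snp = info$snp, effect_allele = info$a1,
                    beta = stats::rnorm(nrow(info), 0, 0.05),
                    stringsAsFactors = FALSE)
    write_tsv(w, file.path(out_dir, "prs_weights.tsv"))
    p <- compute_prs(data$genotypes$dosage, info, w)
    write_tsv(data.frame(subject_id = scores$table$subject_id,
                         prs = as.numeric(p)),
              file.path(out_dir, "prs.tsv"))
    p
  })

  grid <- .stage("grid", {
    gr <- risk_by_diet_grid(y, as.numeric(prs), assoc$diet, covs)
    write_tsv(gr, file.path(out_dir, "risk_by_diet_grid.tsv"))
    gr
  })

  manifest <- list(
    package = "dietGxE",
    version = as.character(utils::packageVersion("dietGxE")),
    seed = config$seed,
    lambda1 = scores$lambda1,
    scan_score = config$scan_score,
    thresholds = list(alpha = config$alpha,
                      alpha_strict = config$alpha_strict,
                      fdr_q = config$fdr_q),
    tertile_fractions = config$tertile_fractions,
    n_subjects = length(y),
    n_snps = ncol(data$genotypes$dosage),
    n_interaction_hits = nrow(scan$hits),
    n_genes = nrow(genes$gene),
    n_sets = nrow(genes$sets))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(data = data, scores = scores, association = assoc,
                 scan = scan, genes = genes, prs = prs, grid = grid,
                 manifest = manifest))
}

# tile consecutive SNPs (3 per gene, per chromosome) into synthetic gene
# bodies so the aggregation stages are exercised without external annotation
.synthetic_gene_locations <- function(info) {
  out <- lapply(split(seq_len(nrow(info)), info$chr), function(ix) {
    ix <- ix[order(info$pos[ix])]
    grp <- (seq_along(ix) - 1L) %/% 3L
    do.call(rbind, lapply(split(ix, grp), function(g)
      data.frame(gene = sprintf("GENE_%s_%d", info$chr[g[1]],
                                min(info$pos[g])),
                 chr = info$chr[g[1]], start = min(info$pos[g]),
                 end = max(info$pos[g]), stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.synthetic_gene_sets <- function(genes, per_set = 4L) {
  genes <- sort(unique(genes))
  grp <- (seq_along(genes) - 1L) %/% per_set
  sets <- split(genes, grp)
  stats::setNames(sets, sprintf("SET_%02d", seq_along(sets)))
}
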
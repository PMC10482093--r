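make_panel_geno <- function(n = 200, m = 6, seed = 1) {
  cfg <- simulation_config(n_subjects = n, n_snps = m, seed = seed)
  simulate_genotypes(cfg)
}

test_that("PRS is a harmonized weighted allele sum", {
  geno <- make_panel_geno()
  info <- geno$info
  w <- data.frame(snp = info$snp, effect_allele = info$a1,
                  beta = seq(-0.3, 0.2, length.out = nrow(info)))
  prs <- compute_prs(geno$dosage, info, w)
  brute <- as.numeric(geno$dosage %*% w$beta)
  expect_equal(as.numeric(prs), brute, tolerance = 1e-12)
  expect_equal(attr(prs, "n_used"), nrow(info))
  # zero dosage, single SNP sanity
  expect_equal(as.numeric(compute_prs(matrix(0, 3, 1,
                                             dimnames = list(NULL, "s")),
                                      data.frame(snp = "s", a1 = "A",
                                                 a2 = "G"),
                                      data.frame(snp = "s",
                                                 effect_allele = "A",
                                                 beta = 0.5))),
               rep(0, 3))
  # SNP reordering leaves the score unchanged
  ord <- sample(nrow(w))
  expect_equal(as.numeric(compute_prs(geno$dosage, info, w[ord, ])),
               brute)
  # allele-flip round trip: swap panel alleles and flip dosages
  info2 <- info
  info2$a1 <- info$a2; info2$a2 <- info$a1
  prs2 <- compute_prs(2 - geno$dosage, info2, w)
  expect_equal(as.numeric(prs2), brute, tolerance = 1e-12)
  # unresolvable allele excluded with warning
  w_bad <- w
  w_bad$effect_allele[1] <- setdiff(c("A", "C", "G", "T"),
                                    c(info$a1[1], info$a2[1]))[1]
  expect_warning(prs3 <- compute_prs(geno$dosage, info, w_bad),
                 "excluded")
  expect_equal(attr(prs3, "n_excluded"), 1L)
})

test_that("interaction scan records the product term and skips bad SNPs", {
  set.seed(2)
  n <- 800
  d <- cbind(s1 = rbinom(n, 2, 0.3), s2 = rbinom(n, 2, 0.4),
             s3 = rep(0L, n), s4 = rbinom(n, 2, 0.01))
  sc <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * d[, 1] * sc))
  rec <- interaction_scan(y, d, sc)
  expect_equal(rec$status, c("ok", "ok", "skipped_monomorphic",
                             "skipped_maf"))
  # matches a direct glm fit of the same model
  ref <- glm(y ~ sc + d1 + d1:sc, data = data.frame(d1 = d[, 1]),
             family = binomial())
  expect_equal(rec$beta[1], unname(coef(ref)["sc:d1"]), tolerance = 1e-6)
  expect_equal(rec$p_value[1],
               summary(ref)$coefficients["sc:d1", 4], tolerance = 1e-6)
  # threshold filtering
  expect_equal(nrow(filter_hits(rec, 1)), 2)
  expect_equal(nrow(filter_hits(rec, 1e-300)), 0)
  expect_equal(nrow(filter_hits(rec, 0.05)),
               sum(rec$p_value < 0.05 & rec$status == "ok", na.rm = TRUE))
})

test_that("SNPs map to genes over closed windows", {
  rec <- data.frame(snp = c("r1", "r2", "r3"), chr = c(1, 1, 2),
                    pos = c(100500L, 95000L, 500L))
  loc <- data.frame(gene = c("G1", "G2"), chr = c(1, 2),
                    start = c(100000L, 400L), end = c(101000L, 450L))
  m0 <- map_snps_to_genes(rec, loc, window_kb = 0)
  expect_equal(m0$snp[m0$gene == "G1"], "r1")
  expect_false("r2" %in% m0$snp)
  m10 <- map_snps_to_genes(rec, loc, window_kb = 10)
  expect_true(all(c("r1", "r2") %in% m10$snp[m10$gene == "G1"]))
  # brute-force interval scan oracle on random positions
  set.seed(3)
  rec2 <- data.frame(snp = sprintf("s%d", 1:200),
                     chr = sample(1:3, 200, TRUE),
                     pos = sample.int(10000, 200))
  loc2 <- data.frame(gene = sprintf("g%d", 1:20),
                     chr = sample(1:3, 20, TRUE),
                     start = sample.int(9000, 20))
  loc2$end <- loc2$start + sample.int(1500, 20)
  got <- map_snps_to_genes(rec2, loc2, window_kb = 1)
  brute <- 0L
  for (i in 1:20) for (j in 1:200)
    if (loc2$chr[i] == rec2$chr[j] &&
        rec2$pos[j] >= loc2$start[i] - 1000 &&
        rec2$pos[j] <= loc2$end[i] + 1000) brute <- brute + 1L
  expect_equal(nrow(got), brute)
  expect_error(map_snps_to_genes(data.frame(snp = "x", chr = NA,
                                            pos = 1L), loc),
               "unknown chromosome")
})

test_that("single-SNP gene test equals the per-SNP likelihood-ratio test", {
  set.seed(4)
  n <- 500
  d <- matrix(rbinom(n, 2, 0.3), ncol = 1)
  sc <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.3 * d[, 1] * sc))
  gt <- gene_test(y, d, sc)
  full <- glm(y ~ sc + d + sc:d, family = binomial(),
              data = data.frame(d = d[, 1]))
  red <- glm(y ~ sc + d, family = binomial(),
             data = data.frame(d = d[, 1]))
  p_lrt <- pchisq(deviance(red) - deviance(full), 1, lower.tail = FALSE)
  expect_equal(gt$p_value, p_lrt, tolerance = 1e-8)
  expect_equal(gt$df, 1)
  # duplicated SNP columns collapse to a single principal component
  gt2 <- gene_test(y, cbind(d, d), sc)
  expect_equal(gt2$df, 1)
  expect_equal(gt2$p_value, p_lrt, tolerance = 1e-6)
  # aggregation mode gives a p-value in range and matching df bookkeeping
  ga <- gene_test(y, cbind(d, matrix(rbinom(n, 2, 0.4), ncol = 1)), sc,
                  mode = "p_aggregation")
  expect_true(ga$p_value >= 0 && ga$p_value <= 1)
  expect_error(gene_test(y[1:4], d[1:4, , drop = FALSE], sc[1:4]),
               "too few")
})

test_that("gene p-values are roughly uniform under the null", {
  set.seed(5)
  n <- 300
  sc <- rnorm(n)
  y <- rbinom(n, 1, 0.3)
  ps <- replicate(80, {
    d <- matrix(rbinom(n * 2, 2, runif(1, 0.2, 0.4)), n, 2)
    gene_test(y, d, sc)$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("competitive gene-set test and BH behave per the step-up rule", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:40)
  gr <- data.frame(gene = genes, p_value = runif(40))
  # plant enrichment: members get small p-values
  gr$p_value[1:8] <- gr$p_value[1:8] / 50
  sets <- list(hit = genes[1:8], null1 = genes[9:20], null2 = genes[21:33])
  res <- gene_set_test(gr, sets)
  expect_lt(res$p_value[res$set == "hit"], 0.05)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_true(all(res$q_value >= res$p_value))
  # sets without scored genes are dropped with a warning
  expect_warning(res2 <- gene_set_test(gr, c(sets, list(alien = "zz"))),
                 "dropped")
  expect_equal(nrow(res2), 3)
  expect_error(gene_set_test(gr, list()), "empty")
  expect_error(gene_set_test(gr[1, ], sets), "two scored genes")
})

test_that("the 3x3 risk-by-diet grid references low risk and high diet", {
  cfg <- simulation_config(n_subjects = 900, n_snps = 30, seed = 7)
  co <- simulate_cohort(cfg)
  y <- as.numeric(co$phenotype)
  set.seed(7)
  prs <- as.numeric(co$genotypes$dosage %*% rnorm(30, 0, 0.2))
  diet <- tertile_groups(compute_rfs(co$ffq))
  gr <- risk_by_diet_grid(y, prs, diet)
  expect_equal(nrow(gr), 9)
  expect_equal(sum(gr$n), 900)
  ref <- gr[gr$genetic_risk == "low" & gr$diet_quality == "high", ]
  expect_equal(ref$or, 1)
  expect_equal(ref$note, "reference")
  expect_true(all(is.finite(gr$or[gr$n > 0])))
})

test_that("a planted genetic gradient yields rising odds across risk rows", {
  set.seed(8)
  n <- 3000
  prs <- rnorm(n)
  diet <- tertile_groups(rnorm(n))
  y <- rbinom(n, 1, plogis(-1.2 + 0.8 * prs))
  gr <- risk_by_diet_grid(y, prs, diet)
  high_diet <- gr[gr$diet_quality == "high", ]
  or_of <- function(r) high_diet$or[high_diet$genetic_risk == r]
  expect_gt(or_of("intermediate"), or_of("low"))
  expect_gt(or_of("high"), or_of("intermediate"))
})
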
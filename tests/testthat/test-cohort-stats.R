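test_that("summary t-test equals the raw-data t-test", {
  set.seed(1)
  x <- rnorm(40, 1, 2); y <- rnorm(60, 0.4, 1.5)
  sx <- summary_group(mean(x), sd(x), 40)
  sy <- summary_group(mean(y), sd(y), 60)
  for (v in c("welch", "pooled")) {
    raw <- t.test(x, y, var.equal = (v == "pooled"))
    smr <- t_test_summary(sx, sy, v)
    expect_equal(unname(smr$statistic), unname(raw$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(smr$parameter), unname(raw$parameter),
                 tolerance = 1e-10)
    expect_equal(smr$p.value, raw$p.value, tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1
  same <- t_test_summary(sx, sx)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  # symmetric in group order
  expect_equal(t_test_summary(sy, sx)$p.value,
               t_test_summary(sx, sy)$p.value)
  expect_error(summary_group(1, -1, 10), "nonnegative")
  expect_error(summary_group(1, 1, 1), "at least 2")
  expect_error(t_test_summary(summary_group(1, 0, 5),
                              summary_group(1, 0, 5)), "degenerate")
})

test_that("chi-squared test matches the O/E oracle and Yates policy", {
  set.seed(2)
  tab <- matrix(rpois(12, 40) + 1, 3, 4)
  res <- chi2_test(tab, yates = "off")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(res$statistic), sum((tab - E)^2 / E),
               tolerance = 1e-12)
  expect_equal(unname(res$parameter), 6)
  t22 <- matrix(c(30, 20, 25, 35), 2)
  expect_equal(chi2_test(t22, "auto")$statistic,
               chisq.test(t22, correct = TRUE)$statistic)
  expect_equal(chi2_test(t22, "off")$statistic,
               chisq.test(t22, correct = FALSE)$statistic)
  # identical row distributions: statistic 0, p 1
  flat <- rbind(c(10, 20, 30), c(10, 20, 30))
  expect_equal(unname(chi2_test(flat, "off")$statistic), 0)
  expect_equal(chi2_test(flat, "off")$p.value, 1)
  expect_error(chi2_test(rbind(c(0, 0), c(1, 2))), "marginal")
  expect_error(chi2_test(matrix(1:3, 3, 1)), "2x2")
})

test_that("rank tests agree with enumeration on small tied samples", {
  x <- c(1, 1, 2, 3); y <- c(2, 2, 3, 4)
  res <- rank_tests(x, y)
  # exact permutation distribution of the rank-sum statistic
  pool <- c(x, y)
  r <- rank(pool)
  combs <- combn(8, 4)
  stats_all <- apply(combs, 2, function(ix) sum(r[ix]))
  obs <- sum(r[1:4])
  exact_p <- mean(abs(stats_all - mean(stats_all)) >=
                  abs(obs - mean(stats_all)) - 1e-9)
  expect_lt(abs(res$wilcoxon_p - exact_p), 0.1)
  # observed W equals the rank-sum shifted by n1(n1+1)/2
  expect_equal(res$wilcoxon_statistic, obs - 4 * 5 / 2)
  # same sample: KS statistic 0
  expect_equal(rank_tests(x, x)$ks_statistic, 0)
  # location shift is detected
  set.seed(3)
  a <- rnorm(500); b <- rnorm(500, 0.3)
  expect_lt(rank_tests(a, b)$wilcoxon_p, 0.01)
  expect_error(rank_tests(numeric(0), 1), "nonempty")
})

test_that("the baseline table dispatches tests and balances counts", {
  cfg <- simulation_config(n_subjects = 300, seed = 5)
  co <- simulate_cohort(cfg, genotypes = FALSE)
  y <- as.numeric(co$phenotype)
  t1 <- build_table1(co$covariates,
                     data.frame(rfs = compute_rfs(co$ffq)), y)
  expect_true(all(t1$p_value >= 0 & t1$p_value <= 1, na.rm = TRUE))
  # level counts add up to the group sizes
  lev <- t1[t1$variable == "coffee" & t1$level != "", ]
  n_case <- sum(as.integer(sub(" .*", "", lev$case)))
  expect_equal(n_case, sum(y == 1))
  # deterministic
  expect_identical(t1, build_table1(co$covariates,
                                    data.frame(rfs = compute_rfs(co$ffq)),
                                    y))
  expect_error(build_table1(data.frame(x = complex(3)), NULL,
                            rep(0:1, length.out = 3)), "neither")
})
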
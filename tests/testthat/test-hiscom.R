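test_that("single-item single-group fit reproduces univariate logistic", {
  set.seed(1)
  n <- 500
  g <- matrix(rbinom(n, 1, 0.5), ncol = 1, dimnames = list(NULL, "tea"))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * g[, 1]))
  panel <- food_panel("tea", "tea", validate_points = FALSE)
  fit <- fit_hiscom(g, y, panel, lambda1 = 0)
  expect_equal(abs(unname(fit$w)), 1, tolerance = 1e-8)
  slope <- unname(coef(glm(y ~ scale(g[, 1]), family = binomial()))[2])
  expect_equal(unname(fit$beta * fit$w), slope, tolerance = 1e-6)
})

test_that("penalized objective is non-increasing and components identified", {
  panel <- toy_panel()
  g <- random_g(300, panel, seed = 2)
  set.seed(2)
  y <- rbinom(300, 1, plogis(-1 + 0.8 * scale(g %*% rep(1, 8))))
  fit <- fit_hiscom(g, y, panel, lambda1 = 0.5)
  expect_true(fit$converged)
  expect_true(all(diff(fit$objective) <= 1e-8))
  # unit-variance identification and sign convention per group
  Gs <- sweep(g, 2, fit$scale, "/")
  for (grp in unique(panel$group)) {
    j <- which(panel$group == grp)
    comp <- as.numeric(Gs[, j, drop = FALSE] %*% fit$w[j])
    expect_equal(sd(comp), 1, tolerance = 1e-8)
    expect_gte(sum(fit$w[j]), 0)
  }
  # refitting the same data is deterministic
  fit2 <- fit_hiscom(g, y, panel, lambda1 = 0.5)
  expect_identical(fit$w, fit2$w)
})

test_that("the weighted score is the stated linear combination", {
  panel <- toy_panel()
  g <- random_g(120, panel, seed = 3)
  set.seed(3)
  y <- rbinom(120, 1, 0.3)
  fit <- fit_hiscom(g, y, panel, lambda1 = 1)
  gnew <- random_g(15, panel, seed = 4)
  # brute-force double loop over groups and items on the fit's scale
  idx <- split(seq_len(nrow(panel)),
               factor(panel$group, levels = unique(panel$group)))
  brute <- numeric(15)
  for (i in 1:15)
    for (k in seq_along(idx))
      for (t in idx[[k]])
        brute[i] <- brute[i] +
          fit$beta[k] * (gnew[i, t] / fit$scale[t]) * fit$w[t]
  expect_equal(compute_hiscom_rfs(fit, gnew), unname(brute),
               tolerance = 1e-10)
  # linear form vanishes at the origin
  expect_equal(compute_hiscom_rfs(fit, matrix(0, 3, 8)), rep(0, 3))
  expect_error(compute_hiscom_rfs(fit, gnew[, 1:5]), "columns")
})

test_that("degenerate inputs are rejected", {
  panel <- toy_panel()
  g <- random_g(100, panel, seed = 5)
  expect_error(fit_hiscom(g, rep(1, 100), panel), "constant")
  set.seed(5)
  y <- rbinom(100, 1, 0.4)
  expect_error(fit_hiscom(g * 2, y, panel), "0/1")
  gz <- g
  gz[, 2] <- 0L
  expect_error(fit_hiscom(gz, y, panel, lambda1 = 0), "constant item")
  # with ridge the constant column is tolerated and shrunk
  fitz <- fit_hiscom(gz, y, panel, lambda1 = 1)
  expect_lt(abs(fitz$w[2]), 1e-6)
})

test_that("heavy ridge drives within-group weights to equal magnitude", {
  # two exchangeable items in one group, equal planted effects
  set.seed(6)
  n <- 4000
  g <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * g[, 1] + 0.5 * g[, 2]))
  panel <- food_panel(c("a", "b"), c("g1", "g1"), validate_points = FALSE)
  fit_lo <- fit_hiscom(g, y, panel, lambda1 = 0)
  fit_hi <- fit_hiscom(g, y, panel, lambda1 = 1e5)
  log_ratio <- function(f) abs(log(abs(f$w[1]) / abs(f$w[2])))
  expect_lt(log_ratio(fit_hi), 0.01)
  expect_lte(log_ratio(fit_hi), log_ratio(fit_lo))
})

test_that("cross-validated penalty selection behaves", {
  panel <- toy_panel()
  g <- random_g(200, panel, seed = 7)
  set.seed(7)
  y <- rbinom(200, 1, plogis(-0.8 + 1.2 * scale(g %*% rep(1, 8))))
  expect_equal(as.numeric(select_lambda1(g, y, panel, grid = 3)), 3)
  # strong signal: the sanely small penalty beats an absurdly large one
  l <- select_lambda1(g, y, panel, grid = c(0.5, 1e6), seed = 1)
  expect_lt(as.numeric(l), 1e6)
  expect_identical(as.numeric(select_lambda1(g, y, panel,
                                             grid = c(0.5, 1e6), seed = 1)),
                   as.numeric(l))
  y1 <- c(1L, rep(0L, 199))
  expect_error(select_lambda1(g, y1, panel, grid = 1, seed = 1),
               "constant")
})

test_that("permutation p-values are reproducible and bounded by design", {
  panel <- food_panel(c("a1", "a2", "b1"), c("g1", "g1", "g2"),
                      validate_points = FALSE)
  set.seed(8)
  n <- 300
  g <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
  # overwhelming effect through group g1 only
  y <- rbinom(n, 1, plogis(-2 + 2.5 * (g[, 1] + g[, 2])))
  pt <- hiscom_permutation_test(g, y, panel, lambda1 = 0.1, B = 199,
                                seed = 11)
  expect_equal(unname(pt$perm_p_beta["g1"]), 1 / 200)
  pt2 <- hiscom_permutation_test(g, y, panel, lambda1 = 0.1, B = 199,
                                 seed = 11)
  expect_identical(pt$perm_p_beta, pt2$perm_p_beta)
  expect_identical(pt$perm_p_w, pt2$perm_p_w)
  expect_error(hiscom_permutation_test(g, y, panel, B = 0), "positive")
})

test_that("fit serialization round-trips through JSON", {
  panel <- toy_panel()
  g <- random_g(100, panel, seed = 9)
  set.seed(9)
  y <- rbinom(100, 1, 0.4)
  fit <- fit_hiscom(g, y, panel, lambda1 = 2)
  path <- tempfile(fileext = ".json")
  write_hiscom_fit(fit, path)
  back <- read_hiscom_fit(path)
  expect_equal(back$w, unname(fit$w), tolerance = 1e-12)
  expect_equal(back$beta, unname(fit$beta), tolerance = 1e-12)
  expect_equal(back$lambda1, 2)
  expect_equal(back$lambda2, 0)
})
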
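test_that("standardization matches the direct formula", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50, 3, 2)
  expect_equal(standardize(x), (x - mean(x)) / sd(x))
  expect_equal(standardize(standardize(x)), standardize(x),
               tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("score association equals a hand-built logistic model", {
  set.seed(2)
  n <- 400
  covs <- data.frame(age = rnorm(n, 50, 8),
                     sex = factor(sample(c("f", "m"), n, TRUE)))
  sc <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.3 * sc + 0.02 * (covs$age - 50)))
  res <- fit_association(y, sc, covs)
  ref <- glm(y ~ sc + age + sex, data = covs, family = binomial())
  b <- coef(ref)["sc"]; se <- sqrt(diag(vcov(ref)))["sc"]
  expect_equal(res$or, unname(exp(b)), tolerance = 1e-8)
  expect_equal(res$l95, unname(exp(b - qnorm(0.975) * se)),
               tolerance = 1e-8)
  expect_equal(res$u95, unname(exp(b + qnorm(0.975) * se)),
               tolerance = 1e-8)
  expect_equal(res$n, n)
  expect_true(res$l95 <= res$or && res$or <= res$u95)
})

test_that("unadjusted binary-exposure OR is the cross-product ratio", {
  set.seed(3)
  x <- rbinom(300, 1, 0.5)
  y <- rbinom(300, 1, plogis(-1 + 0.8 * x))
  a <- sum(y == 1 & x == 1); b <- sum(y == 1 & x == 0)
  c <- sum(y == 0 & x == 1); d <- sum(y == 0 & x == 0)
  expect_equal(fit_association(y, x)$or, (a * d) / (b * c),
               tolerance = 1e-8)
})

test_that("null Wald intervals achieve near-nominal coverage", {
  set.seed(4)
  cover <- replicate(200, {
    y <- rbinom(200, 1, 0.3)
    sc <- rnorm(200)
    r <- fit_association(y, sc)
    r$l95 <= 1 && 1 <= r$u95
  })
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("a planted per-SD effect is recovered within 3 SEs", {
  set.seed(5)
  n <- 4292
  sc <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1.1 + 0.1 * sc))
  r <- fit_association(y, sc)
  se <- (log(r$u95) - log(r$or)) / qnorm(0.975)
  expect_lt(abs(log(r$or) - 0.1), 3 * se)
})

test_that("separation and collinearity raise explicit errors", {
  y <- rep(0:1, each = 25)
  sc <- c(rnorm(25, -8), rnorm(25, 8))
  expect_error(fit_association(y, sc), "separation")
  set.seed(6)
  covs <- data.frame(a = rnorm(50))
  covs$b <- 2 * covs$a
  expect_error(fit_association(rbinom(50, 1, 0.5), rnorm(50), covs),
               "collinear")
})

test_that("tertile grouping follows the rank rule", {
  g <- tertile_groups(1:9)
  expect_equal(as.vector(table(g)), c(3L, 3L, 3L))
  expect_equal(as.character(g[1:3]), rep("low", 3))
  expect_equal(as.character(g[7:9]), rep("high", 3))
  # ties collapse rather than split, with a warning
  expect_warning(gt <- tertile_groups(rep(5, 9)), "ties")
  expect_equal(length(unique(gt)), 1L)
  # invariance to input order and to monotone transformation
  set.seed(7)
  x <- rnorm(100)
  perm <- sample(100)
  expect_identical(tertile_groups(x)[perm], tertile_groups(x[perm]))
  expect_identical(tertile_groups(x), tertile_groups(exp(x)))
  # tie-free group sizes within 1 of n/3
  for (n in c(10, 50, 101)) {
    sizes <- as.vector(table(tertile_groups(seq_len(n))))
    expect_true(all(abs(sizes - n / 3) <= 1))
  }
  expect_error(tertile_groups(1:2), "at least 3")
})

test_that("group odds ratios are reciprocal under reference swap", {
  set.seed(8)
  grp <- factor(sample(c("low", "high"), 200, TRUE),
                levels = c("low", "intermediate", "high"))
  grp <- droplevels(grp)
  y <- rbinom(200, 1, ifelse(grp == "low", 0.4, 0.25))
  a <- group_association(y, grp, reference = "high")
  b <- group_association(y, grp, reference = "low")
  expect_equal(a$or, 1 / b$or, tolerance = 1e-8)
  # matches a manual dummy-coded fit
  ref <- glm(y ~ I(grp == "low"), family = binomial())
  expect_equal(a$or[a$term == "low"], unname(exp(coef(ref)[2])),
               tolerance = 1e-8)
  empty <- factor(rep("low", 200), levels = c("low", "high"))
  expect_error(group_association(y, empty, reference = "high"),
               "empty|not present")
})
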
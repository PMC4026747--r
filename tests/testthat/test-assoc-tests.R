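test_that("score test reduces to the chi-squared quadratic form", {
  sc <- score_components(matrix(c(0, 1), 2, 1), c(0, 1))
  h <- score_test(sc)
  expect_equal(unname(h$statistic), 1.0)
  expect_equal(h$p.value, pchisq(1, 1, lower.tail = FALSE))

  sc0 <- score_components(rand_geno(8, 2, seed = 2), rep(1, 8))
  expect_equal(score_test(sc0)$p.value, 1)
})

test_that("SSU/SSUw/UminP agree with the score test in degenerate cases", {
  set.seed(3)
  x <- rand_geno(50, 1, seed = 3)
  y <- rnorm(50) + 0.3 * x[, 1]
  sc <- score_components(x, y)
  p_score <- score_test(sc)$p.value
  expect_equal(ssu_test(sc)$p.value, p_score, tolerance = 1e-5)
  expect_equal(ssuw_test(sc)$p.value, p_score, tolerance = 1e-5)
  expect_equal(uminp_test(sc)$p.value, p_score, tolerance = 1e-5)

  # duplicated variant: UminP must collapse the perfect correlation
  x2 <- cbind(x, x)
  sc2 <- score_components(x2, y)
  expect_equal(uminp_test(sc2)$p.value, p_score, tolerance = 1e-5)

  # balanced design with exactly diagonal V: SSUw equals the score test
  xd <- cbind(rep(c(0, 0, 1, 1), 10), rep(c(0, 1, 0, 1), 10))
  set.seed(4)
  y2 <- rnorm(40)
  sc3 <- score_components(xd, y2)
  expect_equal(unname(sc3$V[1, 2]), 0)
  expect_equal(ssuw_test(sc3)$p.value, score_test(sc3)$p.value,
               tolerance = 1e-6)
})

test_that("F test matches the RSS-ratio oracle and handles edge cases", {
  set.seed(7)
  x <- rand_geno(20, 3, seed = 7)
  y <- rnorm(20)
  h <- f_test(x, y)
  fit <- lm(y ~ x)
  fs <- summary(fit)$fstatistic
  expect_equal(unname(h$statistic), unname(fs[1]), tolerance = 1e-10)
  expect_equal(h$p.value,
               unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
               tolerance = 1e-10)

  # trait orthogonal to the centered design: F = 0
  y_orth <- residuals(lm(rnorm(20) ~ x))
  h0 <- f_test(x, y_orth)
  expect_equal(unname(h0$statistic), 0, tolerance = 1e-8)
  expect_equal(h0$p.value, 1, tolerance = 1e-8)

  # exact linear trait: unbounded statistic, p -> 0
  y_exact <- drop(1 + x %*% c(1, -2, 0.5))
  hx <- f_test(x, y_exact)
  expect_equal(hx$p.value, 0)
})

test_that("Sum test is the simple regression on the dosage sum", {
  set.seed(8)
  x <- rand_geno(40, 1, seed = 8)
  y <- rnorm(40) + 0.4 * x[, 1]
  h <- sum_test(x, y)
  ref <- summary(lm(y ~ x))$coefficients[2, ]
  expect_equal(unname(h$statistic), unname(ref["t value"]), tolerance = 1e-10)
  expect_equal(h$p.value, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)

  # perfectly opposing effects on anticorrelated columns cancel
  x1 <- rbinom(200, 1, 0.5)
  xa <- cbind(x1, 1 - x1)
  set.seed(9)
  ya <- drop(xa %*% c(2, -2)) + rnorm(200, sd = 0.1)
  expect_gt(sum_test(xa, ya)$p.value, 0.99)  # S is constant here
  expect_true(sum_test(xa, ya)$p.value <= 1)
})

test_that("column order does not change the Sum test", {
  set.seed(10)
  x <- rand_geno(60, 4, seed = 10)
  y <- rnorm(60)
  expect_equal(sum_test(x, y)$p.value, sum_test(x[, 4:1], y)$p.value)
})

test_that("aSum coding flips negative nominally-significant variants only", {
  set.seed(12)
  n <- 200
  x <- rand_geno(n, 3, seed = 12)
  # strong negative effect on variant 1, none elsewhere
  y <- drop(x %*% c(-1, 0, 0)) + rnorm(n)
  cod <- asum_coding(x, y, alpha0 = 0.1)
  expect_true(cod$flip_mask[1])
  expect_true(cod$marginal_p[1] <= 0.1 && cod$marginal_beta[1] < 0)
  # variants with positive marginal slope are never flipped
  expect_false(any(cod$flip_mask[cod$marginal_beta > 0]))

  # all-positive effects: observed statistic equals the plain Sum-model LRT
  y2 <- drop(x %*% c(0.8, 0.8, 0.8)) + rnorm(n)
  cod2 <- asum_coding(x, y2)
  expect_false(any(cod2$flip_mask))
  h <- asum_test(x, y2, B = 5, seed = 1)
  s <- rowSums(x)
  lrt <- n * log(sum(resid(lm(y2 ~ 1))^2) / sum(resid(lm(y2 ~ s))^2))
  expect_equal(unname(h$statistic), lrt, tolerance = 1e-8)
})

test_that("aSum recovers power over Sum under opposite-signed effects", {
  cfg <- make_case_config("rv_only", 2, 0, n = 400)
  pw <- estimate_power(cfg, c("ols/Sum", "ols/aSum"), n_replicates = 50,
                       B = 100, seed = 31)
  expect_gt(pw$power[pw$statistic == "aSum"],
            pw$power[pw$statistic == "Sum"])
})

test_that("flipping every variant coding leaves the global tests unchanged", {
  set.seed(14)
  for (case_seed in c(21, 22)) {
    d <- simulate_rv_data(make_case_config("rv_only", 3, 2), seed = case_seed)
    x <- unclass(d$geno); xf <- 2 - x
    sc <- suppressWarnings(score_components(x, d$trait))
    scf <- suppressWarnings(score_components(xf, d$trait))
    expect_equal(unname(scf$U), -unname(sc$U))
    expect_equal(ssu_test(scf)$p.value, ssu_test(sc)$p.value, tolerance = 1e-8)
    expect_equal(suppressWarnings(ssuw_test(scf)$p.value),
                 suppressWarnings(ssuw_test(sc)$p.value), tolerance = 1e-8)
    expect_equal(score_test(scf)$p.value, score_test(sc)$p.value,
                 tolerance = 1e-8)
    expect_equal(suppressWarnings(uminp_test(scf)$p.value),
                 suppressWarnings(uminp_test(sc)$p.value), tolerance = 1e-4)
  }
})

test_that("null p-values of the closed-form tests are uniform", {
  cfg <- make_case_config("rv_only", 1, 0, null = TRUE, n = 200)
  seeds <- local({set.seed(41); sample.int(2^31 - 2, 500)})
  P <- t(vapply(seeds, function(s) {
    d <- simulate_rv_data(cfg, seed = s)
    sc <- suppressWarnings(score_components(d$geno, d$trait))
    suppressWarnings(c(f_test(d$geno, d$trait)$p.value,
                       score_test(sc)$p.value,
                       ssu_test(sc)$p.value,
                       ssuw_test(sc)$p.value,
                       sum_test(d$geno, d$trait)$p.value))
  }, numeric(5)))
  for (j in 1:5) {
    expect_gt(stats::ks.test(P[, j], "punif")$p.value, 0.01)
  }
  expect_true(all(P >= 0 & P <= 1))
})
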
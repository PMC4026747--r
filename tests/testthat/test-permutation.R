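test_that("one-df statistic is the squared t of the collapsed regression", {
  set.seed(51)
  x <- rand_geno(50, 3, seed = 51)
  y <- rnorm(50) + drop(x %*% c(0.5, 0, 0.5))
  fit <- penreg(x, y, family = "lasso", lambda = 0.5)
  z <- drop(x %*% fit$beta)
  tt <- summary(lm(y ~ z))$coefficients[2, "t value"]
  expect_equal(one_df_statistic(x, y, fit), tt^2, tolerance = 1e-10)

  # beta = 0 gives a constant covariate and a zero statistic
  expect_equal(one_df_statistic(x, y, rep(0, 3)), 0)

  # k = 1: the fitted covariate is a rescaling of the variant itself
  x1 <- x[, 1, drop = FALSE]
  f1 <- summary(lm(y ~ x1))$fstatistic
  expect_equal(one_df_statistic(x1, y, c(2)), unname(f1[1]),
               tolerance = 1e-10)
})

test_that("post-selection statistics restrict U and V to selected variants", {
  set.seed(52)
  x <- rand_geno(60, 3, seed = 52)
  y <- rnorm(60)
  sc <- score_components(x, y)
  # only variant 2 exceeds the 0.001 threshold
  expect_equal(selected_score_statistic(sc, c(5e-4, 0.5, 0), "ssu"),
               unname(sc$U[2]^2))
  expect_equal(selected_score_statistic(sc, c(5e-4, 0.5, 0), "ssuw"),
               unname(sc$U[2]^2 / sc$diag_V[2]))
  # empty selection
  expect_equal(selected_score_statistic(sc, rep(0, 3), "ssu"), 0)
  # full selection equals the global statistics
  expect_equal(selected_score_statistic(sc, rep(1, 3), "ssu"),
               unname(ssu_test(sc)$statistic))
  expect_equal(selected_score_statistic(sc, rep(1, 3), "ssuw"),
               unname(ssuw_test(sc)$statistic))
})

test_that("permutation p-values follow the strict-inequality count", {
  d <- simulate_rv_data(make_case_config("rv_only", 1, 0, n = 120), seed = 53)
  res <- perm_assoc_test(d$geno, d$trait, family = "lasso",
                         grid = list(lambda = c(0.5, 2)), B = 19, seed = 7)
  expect_true(res$p_value %in% ((0:19) / 19))
  expect_equal(res$p_value[["one_df"]],
               mean(res$observed_T[["one_df"]] < res$null_T[, "one_df"]))
  # a strong signal beats every permutation: p = 0 as printed
  expect_equal(unname(res$p_value), 0)
  # the add-one estimator never returns 0
  res1 <- perm_assoc_test(d$geno, d$trait, family = "lasso",
                          grid = list(lambda = c(0.5, 2)), B = 19, seed = 7,
                          add_one = TRUE)
  expect_equal(unname(res1$p_value), 1 / 20)
  expect_error(perm_assoc_test(d$geno, d$trait, family = "lasso", B = 0),
               "B")
})

test_that("permutation results are deterministic given the seed", {
  d <- simulate_rv_data(make_case_config("rv_only", 2, 2, n = 100), seed = 54)
  a <- perm_assoc_test(d$geno, d$trait, family = "tlp_sg",
                       stats = c("one_df", "ssu", "ssuw"),
                       grid = list(lambda1 = c(0.2, 0.6), lambda2 = 0.1,
                                   tau = c(0.1, 0.3)),
                       B = 15, seed = 99)
  b <- perm_assoc_test(d$geno, d$trait, family = "tlp_sg",
                       stats = c("one_df", "ssu", "ssuw"),
                       grid = list(lambda1 = c(0.2, 0.6), lambda2 = 0.1,
                                   tau = c(0.1, 0.3)),
                       B = 15, seed = 99)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$null_T, b$null_T)
  expect_identical(a$per_perm_params, b$per_perm_params)
})

test_that("jointly reordering samples leaves the observed statistics unchanged", {
  d <- simulate_rv_data(make_case_config("rv_only", 1, 0, n = 100), seed = 55)
  x <- unclass(d$geno); y <- d$trait
  set.seed(1); ord <- sample(100)
  a <- perm_assoc_test(x, y, family = "lasso",
                       grid = list(lambda = c(0.5, 2)), B = 30, seed = 5)
  b <- perm_assoc_test(x[ord, ], y[ord], family = "lasso",
                       grid = list(lambda = c(0.5, 2)), B = 30, seed = 5)
  expect_equal(a$observed_T, b$observed_T, tolerance = 1e-8)
  # p-values agree up to Monte-Carlo error of the permutation draw
  expect_lt(abs(a$p_value - b$p_value), 0.25)
})

test_that("unpenalized SSU permutation p matches the asymptotic mixture p", {
  d <- simulate_rv_data(make_case_config("rv_only", 1, 0, null = TRUE),
                        seed = 56)
  x <- unclass(d$geno); y <- d$trait
  sc <- suppressWarnings(score_components(x, y))
  p_asy <- ssu_test(sc)$p.value
  # vectorized permutation oracle on the SSU statistic
  set.seed(57)
  xc <- sweep(x, 2, colMeans(x))
  Yp <- vapply(1:4000, function(b) sample(y), numeric(length(y)))
  Up <- crossprod(xc, sweep(Yp, 2, colMeans(Yp)))
  t0 <- colSums(Up^2)
  p_perm <- mean(sum(sc$U^2) < t0)
  expect_lt(abs(p_asy - p_perm), 0.03)
})
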
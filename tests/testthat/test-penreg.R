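test_that("tlp_value is the truncated L1 penalty", {
  expect_equal(tlp_value(0, 0.5), 0)
  expect_equal(tlp_value(0.25, 0.5), 0.5)
  expect_equal(tlp_value(c(1, 3, 100), 0.5), c(1, 1, 1))  # saturation
  expect_error(tlp_value(1, 0), "positive")
  expect_error(tlp_value(-1, 0.5), "nonnegative")
})

test_that("objective evaluator matches term-by-term summation", {
  set.seed(21)
  x <- rand_geno(8, 3, seed = 21)
  y <- rnorm(8)
  beta <- c(0.7, -0.3, 0.1)
  xc <- sweep(x, 2, colMeans(x)); yc <- y - mean(y)
  loss <- 0
  for (i in 1:8) loss <- loss + 0.5 * (yc[i] - sum(xc[i, ] * beta))^2
  # manual penalties
  man_lasso <- loss + 0.4 * sum(abs(beta))
  man_tlp <- loss + 0.4 * sum(pmin(abs(beta) / 0.2, 1))
  pen2 <- 0
  for (j in 1:2) for (l in (j + 1):3)
    pen2 <- pen2 + 0.1 * min(abs(abs(beta[j]) - abs(beta[l])) / 0.2, 1)
  man_tlpsg <- man_tlp + pen2
  expect_equal(penreg_objective(x, y, beta, "lasso", lambda = 0.4),
               man_lasso, tolerance = 1e-12)
  expect_equal(penreg_objective(x, y, beta, "tlp_s", lambda1 = 0.4,
                                tau = 0.2), man_tlp, tolerance = 1e-12)
  expect_equal(penreg_objective(x, y, beta, "tlp_sg", lambda1 = 0.4,
                                lambda2 = 0.1, tau = 0.2),
               man_tlpsg, tolerance = 1e-12)
  # all penalty weights zero: objective is half the RSS
  expect_equal(penreg_objective(x, y, beta, "lasso", lambda = 0),
               loss, tolerance = 1e-12)
  expect_equal(penreg_objective(x, y, rep(0, 3), "lasso", lambda = 2),
               0.5 * sum(yc^2), tolerance = 1e-12)
})

test_that("lasso reduces to OLS at lambda 0 and to zero at the KKT bound", {
  set.seed(22)
  x <- rand_geno(30, 3, seed = 22)
  y <- rnorm(30)
  f0 <- penreg(x, y, family = "lasso", lambda = 0)
  expect_equal(unname(f0$beta), unname(coef(lm(y ~ x))[-1]),
               tolerance = 1e-8)
  xc <- sweep(x, 2, colMeans(x))
  lam_max <- max(abs(crossprod(xc, y - mean(y))))
  fmax <- penreg(x, y, family = "lasso", lambda = lam_max * 1.0001)
  expect_equal(max(abs(fmax$beta)), 0)
})

test_that("orthonormal-design lasso is exact soft thresholding", {
  q <- orthonormal_design(40, 3, seed = 23)
  set.seed(23)
  y <- rnorm(40) + q %*% c(2, 0.5, -1)
  ols <- drop(crossprod(q, y - mean(y)))
  lam <- 0.8
  fit <- penreg(q, y, family = "lasso", lambda = lam)
  soft <- sign(ols) * pmax(abs(ols) - lam, 0)
  expect_equal(unname(fit$beta), soft, tolerance = 1e-8)
})

test_that("lasso agrees with glmnet on dosage data", {
  skip_if_not_installed("glmnet")
  set.seed(24)
  x <- rand_geno(60, 5, seed = 24)
  y <- rnorm(60) + drop(x %*% c(1, 0, -0.5, 0, 0))
  for (lam in c(0.5, 3)) {
    f1 <- penreg(x, y, family = "lasso", lambda = lam)
    f2 <- glmnet::glmnet(x, y, lambda = lam / 60, standardize = FALSE,
                         thresh = 1e-14)
    expect_equal(unname(f1$beta), as.numeric(f2$beta), tolerance = 1e-5)
  }
})

test_that("graph-fused lasso reduces, groups duplicates, and hits the grid optimum", {
  set.seed(25)
  x <- rand_geno(50, 2, seed = 25)
  y <- rnorm(50) + drop(x %*% c(0.8, 0.6))
  # lambda2 = 0 is the plain lasso
  f1 <- penreg(x, y, family = "gflasso_r1", lambda1 = 0.7, lambda2 = 0)
  f2 <- penreg(x, y, family = "lasso", lambda = 0.7)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)

  # duplicated columns under a large fusion weight share one estimate
  xd <- cbind(x[, 1], x[, 1])
  fd <- penreg(xd, y, family = "gflasso_r1", lambda1 = 0.2, lambda2 = 5)
  expect_lt(abs(fd$beta[1] - fd$beta[2]), 1e-4)
  gref <- grid_min(xd, y, pen_gfl(0.2, 5))
  expect_lt(fd$objective - gref$objective, 1e-4)

  # 2-D grid oracle, both r conventions
  for (fam in c("gflasso_r1", "gflasso_rcor")) {
    fit <- penreg(x, y, family = fam, lambda1 = 0.5, lambda2 = 0.3)
    r <- if (fam == "gflasso_r1") 1 else sign(cor(x[, 1], x[, 2]))
    ref <- grid_min(x, y, pen_gfl(0.5, 0.3, r))
    expect_lt(fit$objective - ref$objective, 1e-3)
  }

  # a very large selection weight empties the model
  fz <- penreg(x, y, family = "gflasso_r1", lambda1 = 1e4, lambda2 = 0.1)
  expect_equal(max(abs(fz$beta)), 0)
})

test_that("TLP-S matches 1-D dense grid, OLS and Lasso limits", {
  set.seed(26)
  x <- rand_geno(40, 1, seed = 26)
  y <- rnorm(40) + 0.9 * x[, 1]
  fit <- penreg(x, y, family = "tlp_s", lambda1 = 0.8, tau = 0.3)
  ref <- grid_min(x, y, pen_tlp_s(0.8, 0.3), lim = 5, step = 1e-4)
  expect_lt(fit$objective - ref$objective, 1e-6)

  x3 <- rand_geno(50, 3, seed = 27)
  set.seed(27)
  y3 <- rnorm(50) + drop(x3 %*% c(1, 0, -0.5))
  # lambda1 = 0: OLS
  f0 <- penreg(x3, y3, family = "tlp_s", lambda1 = 0, tau = 0.3)
  expect_equal(unname(f0$beta), unname(coef(lm(y3 ~ x3))[-1]),
               tolerance = 1e-6)
  # tau large: the penalty is linear, i.e. Lasso with lambda1 / tau
  ft <- penreg(x3, y3, family = "tlp_s", lambda1 = 50, tau = 100)
  fl <- penreg(x3, y3, family = "lasso", lambda = 0.5)
  expect_equal(ft$beta, fl$beta, tolerance = 1e-4)
})

test_that("large coefficients escape TLP-S shrinkage on an orthonormal design", {
  q <- orthonormal_design(60, 2, seed = 28)
  set.seed(28)
  b_true <- c(3, 0)
  y <- drop(q %*% b_true) + rnorm(60, sd = 0.3)
  ols <- drop(crossprod(q, y - mean(y)))
  lam <- 0.4; tau <- 0.2
  ftlp <- penreg(q, y, family = "tlp_s", lambda1 = lam * tau, tau = tau)
  flas <- penreg(q, y, family = "lasso", lambda = lam)
  # lasso shrinks the large coefficient by exactly lambda
  expect_equal(unname(flas$beta[1]), ols[1] - lam, tolerance = 1e-6)
  # the truncated penalty leaves it at the OLS value
  expect_equal(unname(ftlp$beta[1]), ols[1], tolerance = 1e-4)
})

test_that("TLP-SG reduces to TLP-S, groups magnitudes, and descends", {
  set.seed(29)
  x <- rand_geno(80, 2, seed = 29)
  y <- rnorm(80) + drop(x %*% c(1, -1))
  f0 <- penreg(x, y, family = "tlp_sg", lambda1 = 0.4, lambda2 = 0,
               tau = 0.25)
  fs <- penreg(x, y, family = "tlp_s", lambda1 = 0.4, tau = 0.25)
  expect_equal(f0$beta, fs$beta, tolerance = 1e-6)

  # opposite effects of equal size: magnitudes grouped, signs kept
  fg <- penreg(x, y, family = "tlp_sg", lambda1 = 0.05, lambda2 = 3,
               tau = 0.6)
  expect_lt(abs(abs(fg$beta[1]) - abs(fg$beta[2])), 1e-3)
  expect_true(fg$beta[1] > 0 && fg$beta[2] < 0)
  ref <- grid_min(x, y, pen_tlp_sg(0.05, 3, 0.6))
  expect_lt(fg$objective - ref$objective, 1e-3)

  # descent contract: never worse than the zero vector or the warm start
  for (s in 30:32) {
    xs <- rand_geno(40, 4, seed = s)
    set.seed(s); ys <- rnorm(40) + drop(xs %*% c(0.5, -0.5, 0, 0))
    fit <- penreg(xs, ys, family = "tlp_sg", lambda1 = 0.3, lambda2 = 0.2,
                  tau = 0.2)
    obj0 <- penreg_objective(xs, ys, rep(0, 4), "tlp_sg", lambda1 = 0.3,
                             lambda2 = 0.2, tau = 0.2)
    warm <- penreg(xs, ys, family = "tlp_s", lambda1 = 0.3, tau = 0.2)
    objw <- penreg_objective(xs, ys, warm$beta, "tlp_sg", lambda1 = 0.3,
                             lambda2 = 0.2, tau = 0.2)
    expect_lte(fit$objective, obj0 + 1e-10)
    expect_lte(fit$objective, objw + 1e-10)
  }
})

test_that("negating a column negates its coefficient; TLP-SG objective is sign-blind", {
  set.seed(33)
  x <- rand_geno(60, 3, seed = 33)
  y <- rnorm(60) + drop(x %*% c(0.8, -0.6, 0))
  xn <- x; xn[, 2] <- -xn[, 2]
  f1 <- penreg(x, y, family = "tlp_sg", lambda1 = 0.3, lambda2 = 0.15,
               tau = 0.25)
  f2 <- penreg(xn, y, family = "tlp_sg", lambda1 = 0.3, lambda2 = 0.15,
               tau = 0.25)
  b <- f1$beta; b[2] <- -b[2]
  expect_equal(penreg_objective(xn, y, b, "tlp_sg", lambda1 = 0.3,
                                lambda2 = 0.15, tau = 0.25),
               f1$objective, tolerance = 1e-10)
  expect_equal(unname(f2$beta), unname(b), tolerance = 1e-3)
})

test_that("fit methods behave like a classical model object", {
  set.seed(34)
  x <- rand_geno(50, 3, seed = 34)
  y <- rnorm(50) + drop(x %*% c(1, 0, 0))
  fit <- penreg(x, y, family = "lasso", lambda = 0.5)
  expect_length(coef(fit), 4)
  expect_equal(predict(fit, x), fitted(fit))
  expect_equal(unname(fitted(fit) + residuals(fit)), y)
  expect_equal(AIC(fit), -2 * as.numeric(logLik(fit)) +
                 2 * attr(logLik(fit), "df"))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(50L, 3L))
  expect_output(print(summary(fit)), "effective parameters")
})
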
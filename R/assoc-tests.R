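#' @useDynLib tlpassoc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq pf pt pnorm qnorm rnorm rbinom runif var sd
NULL

# evaluate code under a temporary RNG state (no-op when seed is NULL)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

new_htest <- function(method, statistic, p.value, parameter = NULL, ...) {
  structure(c(list(method = method,
                   statistic = c(statistic = statistic),
                   p.value = p.value,
                   parameter = parameter,
                   data.name = "genotype dosages and quantitative trait"),
              list(...)),
            class = "htest")
}

# indices of polymorphic variants (positive diagonal of V)
poly_idx <- function(sc, warn = TRUE) {
  keep <- which(sc$diag_V > 1e-12 * max(sc$diag_V, 1))
  if (warn && length(keep) < sc$k)
    warning(sc$k - length(keep),
            " monomorphic variant(s) dropped from score-based test",
            call. = FALSE)
  keep
}

#' Score test of global association
#'
#' `T = U' V^- U` with a generalized inverse of `V`; asymptotically
#' chi-squared with degrees of freedom equal to the rank of `V`
#' (eigenvalues below a 1e-10 relative tolerance are truncated).
#'
#' @param sc a [score_components()] object.
#' @return An object of class `htest`.
#' @export
score_test <- function(sc) {
  ev <- eigen(sc$V, symmetric = TRUE)
  keep <- ev$values > 1e-10 * max(ev$values, 0)
  r <- sum(keep)
  if (r == 0L || sc$degenerate)
    return(new_htest("Score test", 0, 1, c(df = 0)))
  z <- drop(crossprod(ev$vectors[, keep, drop = FALSE], sc$U))
  stat <- sum(z^2 / ev$values[keep])
  new_htest("Score test", stat, pchisq(stat, df = r, lower.tail = FALSE),
            c(df = r))
}

#' Sum of squared score (SSU) test
#'
#' `T = U'U`; the null distribution is the mixture
#' `sum_j lambda_j chi2_1` with `lambda_j` the eigenvalues of `V`.
#'
#' @inheritParams score_test
#' @return An object of class `htest` (with `weights` = eigenvalues).
#' @export
ssu_test <- function(sc) {
  stat <- sum(sc$U^2)
  ev <- eigen(sc$V, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  p <- if (sum(ev) == 0 || sc$degenerate) 1 else mixture_chisq_pvalue(ev, stat)
  new_htest("SSU test", stat, p, weights = ev)
}

#' Weighted sum of squared score (SSUw) test
#'
#' `T = U' Vd^-1 U` with `Vd = diag(V)`; null mixture weights are the
#' eigenvalues of `Vd^{-1/2} V Vd^{-1/2}`. Monomorphic variants (zero
#' diagonal) are excluded.
#'
#' @inheritParams score_test
#' @return An object of class `htest`.
#' @export
ssuw_test <- function(sc) {
  keep <- poly_idx(sc)
  if (length(keep) == 0L || sc$degenerate)
    return(new_htest("SSUw test", 0, 1))
  U <- sc$U[keep]
  V <- sc$V[keep, keep, drop = FALSE]
  d <- sc$diag_V[keep]
  stat <- sum(U^2 / d)
  W <- V / sqrt(outer(d, d))
  ev <- pmax(eigen(W, symmetric = TRUE, only.values = TRUE)$values, 0)
  new_htest("SSUw test", stat, mixture_chisq_pvalue(ev, stat), weights = ev)
}

#' Univariate minimum-p (UminP) test
#'
#' `T = max_j U_j^2 / v_j`; the p-value is the complement of the
#' equicoordinate rectangle probability `Pr(all |Z_j| <= sqrt(T))` for a
#' multivariate normal `Z` with the correlation matrix induced by `V`,
#' computed by quasi-Monte-Carlo integration (absolute tolerance 1e-4,
#' fixed sub-seed). Perfectly correlated duplicates are collapsed before
#' integration.
#'
#' @inheritParams score_test
#' @return An object of class `htest`.
#' @export
uminp_test <- function(sc) {
  keep <- poly_idx(sc)
  if (length(keep) == 0L || sc$degenerate)
    return(new_htest("UminP test", 0, 1))
  U <- sc$U[keep]
  V <- sc$V[keep, keep, drop = FALSE]
  d <- sc$diag_V[keep]
  stat <- max(U^2 / d)
  C <- V / sqrt(outer(d, d))
  # collapse variants that are numerically identical in correlation
  rep_idx <- integer(0)
  taken <- rep(FALSE, nrow(C))
  for (j in seq_len(nrow(C))) {
    if (taken[j]) next
    dup <- which(abs(C[j, ]) >= 1 - 1e-10)
    taken[dup] <- TRUE
    rep_idx <- c(rep_idx, j)
  }
  C <- C[rep_idx, rep_idx, drop = FALSE]
  m <- nrow(C)
  b <- sqrt(stat)
  p <- if (m == 1L) {
    pchisq(stat, 1, lower.tail = FALSE)
  } else {
    pr <- with_seed(104729, mvtnorm::pmvnorm(
      lower = rep(-b, m), upper = rep(b, m), corr = C,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-4, maxpts = 50000)))
    min(max(1 - as.numeric(pr), 0), 1)
  }
  new_htest("UminP test", stat, p, c(m = m))
}

#' Overall F-test of the joint linear model
#'
#' Classical F-test of `H0: beta = 0` in the multiple regression of the
#' trait on all variant dosages; rank-deficient designs are reduced to
#' their column rank.
#'
#' @param geno dosage matrix (n x k).
#' @param trait numeric trait vector.
#' @return An object of class `htest`.
#' @export
f_test <- function(geno, trait) {
  x <- geno_dosages(geno)
  y <- as.numeric(trait)
  n <- nrow(x)
  qd <- qr(cbind(1, x))
  df1 <- qd$rank - 1L
  df2 <- n - qd$rank
  if (df1 == 0L)
    return(new_htest("Overall F-test", 0, 1, c(df1 = 0, df2 = df2)))
  if (df2 <= 0L) stop("saturated fit: no residual degrees of freedom")
  rss1 <- sum(qr.resid(qd, y)^2)
  rss0 <- sum((y - mean(y))^2)
  if (rss1 <= 1e-12 * max(rss0, 1))
    return(new_htest("Overall F-test", Inf, 0, c(df1 = df1, df2 = df2)))
  stat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  new_htest("Overall F-test", stat,
            pf(stat, df1, df2, lower.tail = FALSE), c(df1 = df1, df2 = df2))
}

#' Sum (burden) test
#'
#' Collapses the variant group to the per-sample dosage sum
#' `S_i = sum_j X_ij` and tests the common slope `beta_c = 0` in the simple
#' regression of the trait on `S` (two-sided t-test, n - 2 df).
#'
#' @inheritParams f_test
#' @return An object of class `htest` (with `estimate` = common slope).
#' @export
sum_test <- function(geno, trait) {
  x <- geno_dosages(geno)
  y <- as.numeric(trait)
  n <- nrow(x)
  s <- rowSums(x)
  sc <- s - mean(s)
  sxx <- sum(sc^2)
  if (sxx == 0)
    return(new_htest("Sum test", 0, 1, c(df = n - 2)))
  yc <- y - mean(y)
  bhat <- sum(sc * yc) / sxx
  rss <- sum(yc^2) - bhat^2 * sxx
  if (rss <= 0)
    return(new_htest("Sum test", Inf, 0, c(df = n - 2),
                     estimate = c(beta_c = bhat)))
  tstat <- bhat / sqrt(rss / (n - 2) / sxx)
  new_htest("Sum test", tstat, 2 * pt(-abs(tstat), n - 2), c(df = n - 2),
            estimate = c(beta_c = bhat))
}

# marginal simple-regression slopes and p-values for every variant
marginal_fits <- function(x, y) {
  n <- nrow(x)
  yc <- y - mean(y)
  xc <- sweep(x, 2, colMeans(x))
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- sum(yc^2) - beta^2 * sxx
  se2 <- ifelse(sxx > 0, rss / (n - 2) / sxx, Inf)
  tstat <- ifelse(is.finite(se2) & se2 > 0, beta / sqrt(se2),
                  ifelse(sxx > 0 & beta != 0, Inf * sign(beta), 0))
  pval <- ifelse(is.infinite(tstat), 0, 2 * pt(-abs(tstat), n - 2))
  pval[sxx == 0] <- 1
  list(beta = beta, p = pval, sxx = sxx)
}

#' Adaptive-coding for the aSum test
#'
#' Fits the k marginal regressions and flips the coding of variant j
#' (`X -> 2 - X`) when its marginal slope is negative and nominally
#' significant (`p <= alpha0`, default 0.1).
#'
#' @inheritParams f_test
#' @param alpha0 marginal p-value threshold for flipping (default 0.1).
#' @return list with `flip_mask`, `marginal_beta`, `marginal_p`, `alpha0`.
#' @export
asum_coding <- function(geno, trait, alpha0 = 0.1) {
  x <- geno_dosages(geno)
  mf <- marginal_fits(x, as.numeric(trait))
  list(flip_mask = mf$beta < 0 & mf$p <= alpha0,
       marginal_beta = mf$beta, marginal_p = mf$p, alpha0 = alpha0)
}

# Gaussian LRT statistic of the Sum model on adaptively recoded dosages
asum_stat <- function(x, y, alpha0) {
  n <- nrow(x)
  mf <- marginal_fits(x, y)
  flip <- mf$beta < 0 & mf$p <= alpha0
  s <- rowSums(x) + 2 * sum(flip) - 2 * drop(x %*% flip)
  sc <- s - mean(s)
  sxx <- sum(sc^2)
  if (sxx == 0) return(0)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  rss1 <- rss0 - sum(sc * yc)^2 / sxx
  if (rss1 <= 0) return(Inf)
  n * log(rss0 / rss1)
}

#' Adaptive Sum (aSum) test
#'
#' Flips variants with nominally significant negative marginal effects
#' (see [asum_coding()]), runs the Sum-model likelihood-ratio statistic on
#' the recoded dosages, and calibrates it by permuting the trait; the whole
#' procedure, including re-flipping, is recomputed on every permutation.
#' The p-value is `sum_b I(T < T0_b) / B` (strict inequality, as for all
#' permutation tests in the package).
#'
#' @inheritParams f_test
#' @param alpha0 marginal flip threshold (default 0.1).
#' @param B number of permutations (default 100).
#' @param seed optional integer seed for the permutation stream.
#' @param add_one if `TRUE`, use the `(sum + 1)/(B + 1)` estimator instead
#'   of the plain fraction.
#' @return An object of class `htest` (with `null_T` = permuted statistics).
#' @export
asum_test <- function(geno, trait, alpha0 = 0.1, B = 100, seed = NULL,
                      add_one = FALSE) {
  stopifnot(B >= 1)
  x <- geno_dosages(geno)
  y <- as.numeric(trait)
  n <- nrow(x)
  obs <- asum_stat(x, y, alpha0)
  null_T <- with_seed(seed, {
    yc_all <- vapply(seq_len(B), function(b) sample(y), numeric(n))
    # vectorized recomputation across permutations
    xc <- sweep(x, 2, colMeans(x))
    sxx <- colSums(xc^2)
    ycm <- sweep(yc_all, 2, colMeans(yc_all))
    syy <- colSums(ycm^2)
    bm <- crossprod(xc, ycm) / ifelse(sxx > 0, sxx, Inf)       # k x B
    rssm <- rep(syy, each = nrow(bm)) ; dim(rssm) <- dim(bm)
    rssm <- rssm - bm^2 * sxx
    se2 <- rssm / (n - 2) / ifelse(sxx > 0, sxx, Inf)
    tm <- ifelse(se2 > 0, bm / sqrt(se2), 0)
    pm <- 2 * pt(-abs(tm), n - 2)
    pm[sxx == 0, ] <- 1
    flip <- (bm < 0) & (pm <= alpha0)                           # k x B
    s0 <- rowSums(x)
    smat <- matrix(s0, n, B) + 2 * matrix(colSums(flip), n, B, byrow = TRUE) -
      2 * (x %*% flip)
    scm <- sweep(smat, 2, colMeans(smat))
    sxx_s <- colSums(scm^2)
    sxy_s <- colSums(scm * ycm)
    rss1 <- syy - ifelse(sxx_s > 0, sxy_s^2 / sxx_s, 0)
    ifelse(sxx_s > 0 & rss1 > 0, n * log(syy / rss1),
           ifelse(sxx_s == 0, 0, Inf))
  })
  hits <- sum(obs < null_T)
  p <- if (add_one) (hits + 1) / (B + 1) else hits / B
  new_htest("aSum test (permutation LRT)", obs, p, c(B = B),
            alpha0 = alpha0, null_T = null_T)
}

#' Run a panel of global association tests
#'
#' Convenience wrapper running any subset of the seven OLS-based global
#' tests and returning one row per test.
#'
#' @inheritParams f_test
#' @param methods subset of `c("F", "Score", "SSU", "SSUw", "UminP", "Sum",
#'   "aSum")`.
#' @param B,seed,alpha0 passed to [asum_test()].
#' @return data.frame with columns `method`, `statistic`, `df_or_rank`,
#'   `p_value`.
#' @examples
#' d <- simulate_rv_data(make_case_config("rv_only", 1, 0, seed = 1))
#' assoc_tests(d$geno, d$trait, methods = c("SSU", "Sum"))
#' @export
assoc_tests <- function(geno, trait,
                        methods = c("F", "Score", "SSU", "SSUw", "UminP",
                                    "Sum", "aSum"),
                        B = 100, seed = NULL, alpha0 = 0.1) {
  methods <- match.arg(methods, several.ok = TRUE)
  sc <- NULL
  need_sc <- any(methods %in% c("Score", "SSU", "SSUw", "UminP"))
  if (need_sc) sc <- score_components(geno, trait)
  one <- function(m) {
    h <- switch(m,
      "F" = f_test(geno, trait),
      "Score" = score_test(sc),
      "SSU" = ssu_test(sc),
      "SSUw" = ssuw_test(sc),
      "UminP" = uminp_test(sc),
      "Sum" = sum_test(geno, trait),
      "aSum" = asum_test(geno, trait, alpha0 = alpha0, B = B, seed = seed))
    df <- if (!is.null(h$parameter)) h$parameter[[1]] else NA_real_
    data.frame(method = m, statistic = unname(h$statistic),
               df_or_rank = df, p_value = h$p.value)
  }
  do.call(rbind, lapply(methods, one))
}
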
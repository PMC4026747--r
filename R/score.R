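#' Score vector and null covariance for a quantitative trait
#'
#' Computes the shared building blocks of the score-based global tests for
#' the linear model `Y = b0 + X beta + e`: the score vector evaluated at the
#' null `beta = 0`,
#' `U = sum_i (Y_i - Ybar) X_i`, its null covariance
#' `V = sigma0^2 sum_i (X_i - Xbar)(X_i - Xbar)'`, and the null variance
#' estimate `sigma0^2 = sum_i (Y_i - Ybar)^2 / (n - 1)`.
#'
#' @param geno dosage matrix (n x k), a [genotype_matrix()] or plain matrix.
#' @param trait numeric trait vector of length n.
#' @return A list of class `score_components` with elements `U`, `V`,
#'   `sigma0_sq`, `diag_V`, `n`, `k` and `degenerate` (TRUE when the trait
#'   has zero variance).
#' @examples
#' x <- matrix(c(0, 1), 2, 1)
#' score_components(x, c(0, 1))
#' @export
score_components <- function(geno, trait) {
  x <- geno_dosages(geno)
  y <- as.numeric(trait)
  n <- nrow(x)
  if (length(y) != n) stop("trait length must match sample count")
  if (!all(is.finite(y))) stop("trait values must be finite")
  if (n < 2L) stop("need at least 2 samples")
  yc <- y - mean(y)
  sigma0_sq <- sum(yc^2) / (n - 1)
  U <- drop(crossprod(x, yc))
  xc <- sweep(x, 2, colMeans(x))
  V <- sigma0_sq * crossprod(xc)
  structure(list(U = U, V = V, sigma0_sq = sigma0_sq, diag_V = diag(V),
                 n = n, k = ncol(x), degenerate = sigma0_sq == 0),
            class = "score_components")
}

#' @export
print.score_components <- function(x, ...) {
  cat("score components: k =", x$k, ", n =", x$n,
      ", sigma0^2 =", format(x$sigma0_sq, digits = 4), "\n")
  invisible(x)
}

#' Upper-tail probability of a nonnegative mixture of 1-df chi-squares
#'
#' `Pr(sum_j w_j chi2_1 >= t)`, the null distribution of the SSU and SSUw
#' statistics with weights equal to eigenvalues of (a standardized) `V`.
#' Uses Imhof's exact numerical inversion of the characteristic function;
#' if the integral fails or falls outside `[0, 1]` beyond tolerance, falls
#' back to a moment-matching (Satterthwaite-type) scaled chi-squared
#' approximation.
#'
#' @param weights nonnegative eigenvalue weights; near-zero entries are
#'   dropped.
#' @param t observed statistic, `t >= 0`.
#' @return upper-tail probability in `[0, 1]`.
#' @examples
#' mixture_chisq_pvalue(1, qchisq(0.95, 1))   # ~0.05
#' mixture_chisq_pvalue(c(2, 2), 3)           # = pchisq(1.5, 2, lower = FALSE)
#' @export
mixture_chisq_pvalue <- function(weights, t) {
  w <- as.numeric(weights)
  if (any(w < -1e-8 * max(abs(w), 1))) stop("negative mixture weights")
  # weights this far below the dominant one shift the quantile negligibly
  w <- w[w > 1e-7 * max(w, 0)]
  if (length(w) == 0L) return(1)
  if (t <= 0) return(1)
  if (length(w) == 1L)
    return(stats::pchisq(t / w, df = 1, lower.tail = FALSE))
  if (diff(range(w)) < 1e-12 * max(w))   # equal weights: exact chi-squared
    return(stats::pchisq(t / mean(w), df = length(w), lower.tail = FALSE))
  p <- imhof_upper(w, t)
  if (is.na(p) || p < -1e-4 || p > 1 + 1e-4) p <- liu_upper(w, t)
  min(max(p, 0), 1)
}

# Imhof (1961) inversion for Q = sum w_j chi2_1:
#   P(Q >= t) = 1/2 + (1/pi) int_0^Inf sin(theta(u)) / (u rho(u)) du
# Truncated at U where the integrand envelope 1/(u rho(u)) falls below
# pi * 5e-7 * t: one integration by parts shows the discarded oscillatory
# tail is about envelope(U) * (2/t) / pi < 1e-6 in absolute value.
imhof_upper <- function(w, t) {
  f <- function(u) {
    theta <- 0.5 * colSums(atan(outer(w, u))) - 0.5 * t * u
    rho <- exp(0.25 * colSums(log1p(outer(w^2, u^2))))
    ifelse(u == 0, 0, sin(theta) / (u * rho))
  }
  log_env <- function(u) -(log(u) + 0.25 * sum(log1p(w^2 * u^2)))
  target <- log(pi * 5e-7 * max(t, 1e-3))
  U <- tryCatch(
    stats::uniroot(function(lu) log_env(exp(lu)) - target,
                   lower = log(1e-4), upper = log(1e12))$root,
    error = function(e) NA_real_)
  if (is.na(U)) return(NA_real_)
  val <- tryCatch(
    stats::integrate(f, 0, exp(U), rel.tol = 1e-7, abs.tol = 1e-9,
                     subdivisions = 50000L)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(NA_real_)
  0.5 + val / pi
}

# four-moment (Liu-Tang-Zhang) noncentral chi-squared approximation
liu_upper <- function(w, t) {
  c1 <- sum(w); c2 <- sum(w^2); c3 <- sum(w^3); c4 <- sum(w^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- a^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2 * (l + 2 * delta))
  stats::pchisq((t - mu_q) / sigma_q * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}
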
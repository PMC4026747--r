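#' Control parameters for penalized fits
#'
#' @param tol_inner convergence tolerance of the inner solvers (maximum
#'   coordinate change for coordinate descent; primal/dual residual for
#'   ADMM).
#' @param tol_outer tolerance on the decrease of the true objective in the
#'   difference-of-convex outer loop.
#' @param max_outer maximum outer (DC) iterations.
#' @param max_inner maximum inner iterations.
#' @param rho ADMM augmented-Lagrangian parameter.
#' @return list of class `penreg_control`.
#' @export
penreg_control <- function(tol_inner = 1e-8, tol_outer = 1e-6,
                           max_outer = 100L, max_inner = 10000L, rho = 1) {
  structure(list(tol_inner = tol_inner, tol_outer = tol_outer,
                 max_outer = as.integer(max_outer),
                 max_inner = as.integer(max_inner), rho = rho),
            class = "penreg_control")
}

# complete pair graph (0-based indices for the C++ side)
pair_graph <- function(k) {
  if (k < 2L) return(list(i = integer(0), j = integer(0)))
  idx <- utils::combn(k, 2L)
  list(i = idx[1, ] - 1L, j = idx[2, ] - 1L)
}

# pairwise sign matrix r(j, j') for the graph-fused penalty
r_sign_matrix <- function(x, mode = c("one", "cor")) {
  mode <- match.arg(mode)
  k <- ncol(x)
  if (mode == "one") return(matrix(1, k, k))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance column(s): r defaults to +1 for their pairs",
            call. = FALSE)
  r <- matrix(1, k, k)
  ok <- sds > 0
  if (sum(ok) >= 2) {
    cc <- stats::cor(x[, ok, drop = FALSE])
    r[ok, ok] <- ifelse(cc >= 0, 1, -1)
  }
  r
}

min_norm_ols <- function(A, b, rel_tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rel_tol * max(s$d, 0)
  if (!any(keep)) return(rep(0, length(b)))
  drop(s$v[, keep, drop = FALSE] %*%
         ((crossprod(s$u[, keep, drop = FALSE], b)) / s$d[keep]))
}

#' Penalized least-squares fit for a group of variants
#'
#' Fits the linear model of a quantitative trait on variant dosages under
#' one of five penalties (plus unpenalized OLS):
#' \describe{
#'   \item{`ols`}{no penalty; minimum-norm least squares.}
#'   \item{`lasso`}{`lambda * sum_j |beta_j|`.}
#'   \item{`gflasso_r1`, `gflasso_rcor`}{graph-fused Lasso
#'     `lambda1 * sum_j |beta_j| + lambda2 * sum_{j<j'} |beta_j - r(j,j') beta_j'|`
#'     over the complete pair graph, with `r = 1` or the sign of the
#'     inter-variant correlation.}
#'   \item{`tlp_s`}{truncated-L1 selection penalty
#'     `lambda1 * sum_j J_tau(|beta_j|)` with `J_tau(x) = min(x/tau, 1)`;
#'     solved by difference-of-convex iterations warm-started at the
#'     Lasso(`lambda1/tau`) solution.}
#'   \item{`tlp_sg`}{adds the grouping penalty
#'     `lambda2 * sum_{j<j'} J_tau(||beta_j| - |beta_j'||)`; warm-started at
#'     the TLP-S solution. Groups absolute effect sizes, so variants may
#'     share a magnitude with opposite directions.}
#' }
#' The intercept is left unpenalized: the trait and dosage columns are
#' centered, the penalized problem is solved for `beta`, and
#' `b0 = mean(y) - colMeans(x)' beta`.
#'
#' Non-convex fits (TLP families) converge to a local minimizer; the
#' returned objective never exceeds the warm start's.
#'
#' @param x dosage matrix (n x k) or [genotype_matrix()].
#' @param y numeric trait vector.
#' @param family penalty family.
#' @param lambda Lasso penalty weight.
#' @param lambda1,lambda2,tau penalty weights of the fused/truncated
#'   families (`tau > 0`).
#' @param control a [penreg_control()] list.
#' @return Object of class `penreg` with components `beta`, `intercept`,
#'   `objective`, `converged`, `iterations`, `fitted.values`, `residuals`.
#' @examples
#' d <- simulate_rv_data(make_case_config("rv_only", 1, 0, seed = 1))
#' fit <- penreg(d$geno, d$trait, family = "lasso", lambda = 0.5)
#' coef(fit)
#' @export
penreg <- function(x, y,
                   family = c("ols", "lasso", "gflasso_r1", "gflasso_rcor",
                              "tlp_s", "tlp_sg"),
                   lambda = NULL, lambda1 = NULL, lambda2 = NULL, tau = NULL,
                   control = penreg_control()) {
  family <- match.arg(family)
  x <- geno_dosages(x)
  y <- as.numeric(y)
  n <- nrow(x); k <- ncol(x)
  stopifnot(length(y) == n)
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  ym <- mean(y)
  yc <- y - ym
  A <- crossprod(xc)
  b <- drop(crossprod(xc, yc))
  yty <- sum(yc^2)
  ctl <- control
  chk <- function(v, nm) {
    if (is.null(v) || v < 0) stop("'", nm, "' must be a nonnegative number")
    v
  }
  res <- switch(family,
    ols = {
      list(beta = min_norm_ols(A, b), objective = NA_real_,
           iterations = 0L, converged = TRUE)
    },
    lasso = {
      lambda <- chk(lambda, "lambda")
      if (lambda == 0) {
        list(beta = min_norm_ols(A, b), iterations = 0L, converged = TRUE)
      } else {
        cpp_wlasso(A, b, rep(lambda, k), rep(0, k),
                   ctl$tol_inner, ctl$max_inner)
      }
    },
    gflasso_r1 = ,
    gflasso_rcor = {
      lambda1 <- chk(lambda1, "lambda1"); lambda2 <- chk(lambda2, "lambda2")
      mode <- if (family == "gflasso_rcor") "cor" else "one"
      if (lambda2 == 0 || k < 2L) {
        cpp_wlasso(A, b, rep(lambda1, k), rep(0, k),
                   ctl$tol_inner, ctl$max_inner)
      } else {
        pg <- pair_graph(k)
        r <- r_sign_matrix(x, mode)
        pr <- r[cbind(pg$i + 1L, pg$j + 1L)]
        cpp_gflasso(A, b, yty, lambda1, lambda2, pg$i, pg$j, pr,
                    rep(0, k), ctl$rho, ctl$tol_inner, ctl$max_inner)
      }
    },
    tlp_s = {
      lambda1 <- chk(lambda1, "lambda1")
      if (is.null(tau) || tau <= 0) stop("'tau' must be > 0")
      warm <- cpp_wlasso(A, b, rep(lambda1 / tau, k), rep(0, k),
                         ctl$tol_inner, ctl$max_inner)$beta
      cpp_tlp_s(A, b, yty, lambda1, tau, warm, ctl$tol_inner,
                ctl$tol_outer, ctl$max_outer, ctl$max_inner)
    },
    tlp_sg = {
      lambda1 <- chk(lambda1, "lambda1"); lambda2 <- chk(lambda2, "lambda2")
      if (is.null(tau) || tau <= 0) stop("'tau' must be > 0")
      warm <- cpp_wlasso(A, b, rep(lambda1 / tau, k), rep(0, k),
                         ctl$tol_inner, ctl$max_inner)$beta
      warm <- cpp_tlp_s(A, b, yty, lambda1, tau, warm, ctl$tol_inner,
                        ctl$tol_outer, ctl$max_outer, ctl$max_inner)$beta
      if (lambda2 == 0 || k < 2L) {
        cpp_tlp_s(A, b, yty, lambda1, tau, warm, ctl$tol_inner,
                  ctl$tol_outer, ctl$max_outer, ctl$max_inner)
      } else {
        pg <- pair_graph(k)
        cpp_tlp_sg(A, b, yty, lambda1, lambda2, tau, pg$i, pg$j, warm,
                   ctl$rho, ctl$tol_inner, ctl$tol_outer, ctl$max_outer,
                   ctl$max_inner)
      }
    })
  beta <- drop(res$beta)
  names(beta) <- colnames(x)
  intercept <- ym - sum(xm * beta)
  fitted <- drop(intercept + x %*% beta)
  params <- list(lambda = lambda, lambda1 = lambda1, lambda2 = lambda2,
                 tau = tau)
  obj <- penreg_objective(x, y, beta, family, lambda = lambda,
                          lambda1 = lambda1, lambda2 = lambda2, tau = tau)
  structure(list(beta = beta, intercept = intercept, family = family,
                 params = params[!vapply(params, is.null, logical(1))],
                 objective = obj,
                 converged = isTRUE(res$converged),
                 iterations = res$iterations %||% 0L,
                 n = n, k = k,
                 fitted.values = fitted, residuals = y - fitted,
                 call = match.call()),
            class = "penreg")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Penalized objective value
#'
#' Evaluates the exact objective `1/2 ||Yc - Xc beta||^2 + penalty` of a
#' penalty family at an arbitrary coefficient vector, on centered data.
#' Serves as the acceptance oracle for the solvers.
#'
#' @inheritParams penreg
#' @param beta coefficient vector of length k.
#' @return scalar objective value.
#' @export
penreg_objective <- function(x, y, beta,
                             family = c("ols", "lasso", "gflasso_r1",
                                        "gflasso_rcor", "tlp_s", "tlp_sg"),
                             lambda = NULL, lambda1 = NULL, lambda2 = NULL,
                             tau = NULL) {
  family <- match.arg(family)
  x <- geno_dosages(x)
  stopifnot(length(beta) == ncol(x))
  xc <- sweep(x, 2, colMeans(x))
  yc <- as.numeric(y) - mean(y)
  loss <- 0.5 * sum((yc - drop(xc %*% beta))^2)
  pen <- switch(family,
    ols = 0,
    lasso = lambda * sum(abs(beta)),
    gflasso_r1 = ,
    gflasso_rcor = {
      r <- r_sign_matrix(x, if (family == "gflasso_rcor") "cor" else "one")
      p2 <- 0
      k <- length(beta)
      if (k >= 2) {
        idx <- utils::combn(k, 2L)
        p2 <- sum(abs(beta[idx[1, ]] - r[t(idx)] * beta[idx[2, ]]))
      }
      lambda1 * sum(abs(beta)) + lambda2 * p2
    },
    tlp_s = lambda1 * sum(tlp_value(abs(beta), tau)),
    tlp_sg = {
      p2 <- 0
      k <- length(beta)
      if (k >= 2) {
        idx <- utils::combn(k, 2L)
        p2 <- sum(tlp_value(abs(abs(beta[idx[1, ]]) - abs(beta[idx[2, ]])),
                            tau))
      }
      lambda1 * sum(tlp_value(abs(beta), tau)) + lambda2 * p2
    })
  loss + pen
}

#' Truncated L1 penalty
#'
#' `J_tau(x) = min(x / tau, 1)` for `x >= 0`: linear below the truncation
#' point `tau`, constant above it, so coefficients larger than `tau` incur
#' no additional shrinkage. As `tau -> 0+` it approaches the L0 indicator.
#'
#' @param x nonnegative value(s).
#' @param tau truncation parameter, `> 0`.
#' @return penalty value(s) in `[0, 1]`.
#' @examples
#' tlp_value(c(0, 0.25, 1), 0.5)
#' @export
tlp_value <- function(x, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a positive scalar")
  if (any(x < 0)) stop("'x' must be nonnegative")
  pmin(x / tau, 1)
}

#' @export
print.penreg <- function(x, digits = 4, ...) {
  cat("Penalized fit (", x$family, "), n = ", x$n, ", k = ", x$k, "\n",
      sep = "")
  if (length(x$params))
    cat("tuning:", paste(names(x$params), signif(unlist(x$params), 4),
                         sep = " = ", collapse = ", "), "\n")
  nz <- sum(abs(x$beta) > 1e-3)
  cat("non-zero coefficients (|beta| > 1e-3):", nz, "of", x$k, "\n")
  if (!is.na(x$objective))
    cat("objective:", format(x$objective, digits = digits),
        if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' @export
coef.penreg <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
predict.penreg <- function(object, newx, ...) {
  if (missing(newx)) return(object$fitted.values)
  drop(object$intercept + geno_dosages(newx) %*% object$beta)
}

#' @export
fitted.penreg <- function(object, ...) object$fitted.values

#' @export
residuals.penreg <- function(object, ...) object$residuals

#' Log-likelihood of a penalized fit
#'
#' Gaussian log-likelihood evaluated with the plug-in variance
#' `sigma^2 = RSS / (n - p - 1)`:
#' `log L = (-n log(sigma^2) - n - p - 1) / 2`, where `p` is the
#' method-specific effective number of parameters (see
#' [effective_params()]). When `n - p - 1 <= 0` the value is `-Inf`, so
#' `AIC()` rejects the candidate with `+Inf`.
#'
#' @param object a `penreg` fit.
#' @param ... unused.
#' @return `logLik` object with `df` attribute equal to `p`.
#' @export
logLik.penreg <- function(object, ...) {
  p <- effective_params(object$beta, object$family)
  n <- object$n
  if (n - p - 1 <= 0) {
    ll <- -Inf
  } else {
    s2 <- sum(object$residuals^2) / (n - p - 1)
    ll <- if (s2 <= 0) Inf else (-n * log(s2) - n - p - 1) / 2
  }
  structure(ll, df = p, nobs = n, class = "logLik")
}

#' @export
summary.penreg <- function(object, ...) {
  p <- effective_params(object$beta, object$family)
  out <- list(fit = object, p_eff = p, aic = stats::AIC(object),
              rss = sum(object$residuals^2))
  class(out) <- "summary.penreg"
  out
}

#' @export
print.summary.penreg <- function(x, ...) {
  print(x$fit)
  cat("effective parameters:", x$p_eff, "  AIC:",
      format(x$aic, digits = 6), "  RSS:", format(x$rss, digits = 6), "\n")
  cat("coefficients:\n")
  print(signif(coef(x$fit), 4))
  invisible(x)
}

#' Simulate traits from a fitted penalized model
#'
#' Draws new trait vectors `y* = b0 + X beta + N(0, sigma^2)` with
#' `sigma^2 = RSS / (n - p - 1)` from the fit.
#'
#' @param object a `penreg` fit.
#' @param nsim number of simulated trait vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.penreg <- function(object, nsim = 1, seed = NULL, ...) {
  p <- effective_params(object$beta, object$family)
  df <- max(object$n - p - 1, 1)
  s <- sqrt(sum(object$residuals^2) / df)
  with_seed(seed, {
    as.data.frame(vapply(seq_len(nsim),
                         function(i) object$fitted.values +
                           rnorm(object$n, 0, s),
                         numeric(object$n)))
  })
}
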
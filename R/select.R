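#' Effective number of parameters of a penalized fit
#'
#' The count `p` entering the AIC, per penalty family:
#' \itemize{
#'   \item `ols`, `lasso`, `tlp_s`: number of non-zero coefficients;
#'   \item `gflasso_r1`: number of non-zero unique signed coefficient
#'     values;
#'   \item `gflasso_rcor`, `tlp_sg`: number of non-zero unique absolute
#'     coefficient values (grouping of magnitudes).
#' }
#' "Non-zero" means `|beta_j| > zero_tol` (default 1e-3, the same threshold
#' the post-selection tests use); "unique" means distinct after clustering
#' values whose successive gaps are within `unique_tol` (default 1e-4).
#'
#' @param beta coefficient vector (or a `penreg` fit).
#' @param family penalty family.
#' @param zero_tol threshold below which a coefficient counts as zero.
#' @param unique_tol absolute tolerance for merging equal values.
#' @return integer count `>= 0`.
#' @examples
#' effective_params(c(0.5, 0, -0.2), "lasso")          # 2
#' effective_params(c(0.5, 0.5, -0.5, 0), "gflasso_r1") # 2
#' effective_params(c(0.5, 0.5, -0.5, 0), "tlp_sg")     # 1
#' @export
effective_params <- function(beta, family, zero_tol = 1e-3,
                             unique_tol = 1e-4) {
  if (inherits(beta, "penreg")) {
    if (missing(family)) family <- beta$family
    beta <- beta$beta
  }
  nz <- beta[abs(beta) > zero_tol]
  if (length(nz) == 0L) return(0L)
  switch(family,
         ols = ,
         lasso = ,
         tlp_s = length(nz),
         gflasso_r1 = n_unique_tol(nz, unique_tol),
         gflasso_rcor = ,
         tlp_sg = n_unique_tol(abs(nz), unique_tol),
         stop("unknown family: ", family))
}

# number of clusters when sorted values are split at gaps > tol
n_unique_tol <- function(v, tol) {
  v <- sort(v)
  if (length(v) == 1L) return(1L)
  sum(diff(v) > tol) + 1L
}

#' Default tuning grids
#'
#' The grid-search defaults: 50 equally (linearly) spaced `lambda` values
#' on `[0.001, 10]` for the Lasso; five equally spaced points each for
#' `lambda1` on `[0.001, 1]`, `lambda2` on `[0.001, 0.5]` and `tau` on
#' `[0.001, 0.5]` for the fused/truncated families.
#'
#' @param family penalty family.
#' @return named list of numeric grids (a `grid_spec`).
#' @export
default_grid <- function(family = c("lasso", "gflasso_r1", "gflasso_rcor",
                                    "tlp_s", "tlp_sg", "ols")) {
  family <- match.arg(family)
  l1 <- seq(0.001, 1, length.out = 5)
  l2 <- seq(0.001, 0.5, length.out = 5)
  tg <- seq(0.001, 0.5, length.out = 5)
  g <- switch(family,
              ols = list(),
              lasso = list(lambda = seq(0.001, 10, length.out = 50)),
              gflasso_r1 = ,
              gflasso_rcor = list(lambda1 = l1, lambda2 = l2),
              tlp_s = list(lambda1 = l1, tau = tg),
              tlp_sg = list(lambda1 = l1, lambda2 = l2, tau = tg))
  structure(g, class = "grid_spec")
}

# Fast grid-search engine working on the precomputed Gram formulation.
# Returns the audit table of all candidates plus the best candidate's
# coefficients; ties in AIC go to the lexicographically smallest parameter
# tuple. Used by penreg_tune() and by the permutation loop, where the full
# penreg object per candidate would be wasteful.
tune_engine <- function(x, y, family, grid, control = penreg_control()) {
  n <- nrow(x); k <- ncol(x)
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  yc <- y - mean(y)
  A <- crossprod(xc)
  b <- drop(crossprod(xc, yc))
  yty <- sum(yc^2)
  ctl <- control
  aic_of <- function(beta) {
    p <- effective_params(beta, family)
    if (n - p - 1 <= 0) return(c(p, Inf))
    rss <- yty - 2 * sum(b * beta) + drop(crossprod(beta, A %*% beta))
    s2 <- rss / (n - p - 1)
    if (s2 <= 0) return(c(p, -Inf))
    c(p, n * log(s2) + n + p + 1 + 2 * p)   # -2 logL + 2p
  }
  betas <- list(); recs <- list()
  if (family == "ols") {
    beta <- min_norm_ols(A, b)
    return(list(beta = beta, tuning = list(), p_eff = aic_of(beta)[1],
                aic = aic_of(beta)[2],
                audit = data.frame(p_eff = aic_of(beta)[1],
                                   aic = aic_of(beta)[2])))
  }
  if (family == "lasso") {
    lam <- sort(grid$lambda)
    path <- cpp_lasso_path(A, b, lam, ctl$tol_inner, ctl$max_inner)
    for (i in seq_along(lam)) {
      betas[[i]] <- path[, i]
      recs[[i]] <- c(lambda = lam[i], aic_of(path[, i]))
    }
  } else if (family %in% c("gflasso_r1", "gflasso_rcor")) {
    pg <- pair_graph(k)
    r <- suppressWarnings(
      r_sign_matrix(x, if (family == "gflasso_rcor") "cor" else "one"))
    pr <- if (k >= 2) r[cbind(pg$i + 1L, pg$j + 1L)] else numeric(0)
    cand <- expand.grid(lambda1 = sort(grid$lambda1),
                        lambda2 = sort(grid$lambda2))
    init <- rep(0, k)
    for (i in seq_len(nrow(cand))) {
      l1 <- cand$lambda1[i]; l2 <- cand$lambda2[i]
      bi <- if (l2 == 0 || k < 2L)
        cpp_wlasso(A, b, rep(l1, k), rep(0, k), ctl$tol_inner,
                   ctl$max_inner)$beta
      else
        cpp_gflasso(A, b, yty, l1, l2, pg$i, pg$j, pr, init, ctl$rho,
                    ctl$tol_inner, ctl$max_inner)$beta
      init <- drop(bi)   # convex: warm start only speeds convergence
      betas[[i]] <- drop(bi)
      recs[[i]] <- c(lambda1 = l1, lambda2 = l2, aic_of(betas[[i]]))
    }
  } else if (family == "tlp_s") {
    cand <- expand.grid(lambda1 = sort(grid$lambda1), tau = sort(grid$tau))
    for (i in seq_len(nrow(cand))) {
      l1 <- cand$lambda1[i]; tau <- cand$tau[i]
      w <- cpp_wlasso(A, b, rep(l1 / tau, k), rep(0, k), ctl$tol_inner,
                      ctl$max_inner)$beta
      fit <- cpp_tlp_s(A, b, yty, l1, tau, w, ctl$tol_inner, ctl$tol_outer,
                       ctl$max_outer, ctl$max_inner)
      betas[[i]] <- drop(fit$beta)
      recs[[i]] <- c(lambda1 = l1, tau = tau, aic_of(betas[[i]]))
    }
  } else if (family == "tlp_sg") {
    pg <- pair_graph(k)
    outer_grid <- expand.grid(lambda1 = sort(grid$lambda1),
                              tau = sort(grid$tau))
    l2s <- sort(grid$lambda2)
    i <- 0L
    for (o in seq_len(nrow(outer_grid))) {
      l1 <- outer_grid$lambda1[o]; tau <- outer_grid$tau[o]
      w <- cpp_wlasso(A, b, rep(l1 / tau, k), rep(0, k), ctl$tol_inner,
                      ctl$max_inner)$beta
      warm <- drop(cpp_tlp_s(A, b, yty, l1, tau, w, ctl$tol_inner,
                             ctl$tol_outer, ctl$max_outer,
                             ctl$max_inner)$beta)
      for (l2 in l2s) {
        i <- i + 1L
        bi <- if (l2 == 0 || k < 2L) warm
        else drop(cpp_tlp_sg(A, b, yty, l1, l2, tau, pg$i, pg$j, warm,
                             ctl$rho, ctl$tol_inner, ctl$tol_outer,
                             ctl$max_outer, ctl$max_inner)$beta)
        betas[[i]] <- bi
        recs[[i]] <- c(lambda1 = l1, lambda2 = l2, tau = tau, aic_of(bi))
      }
    }
  } else stop("unknown family: ", family)
  tab <- as.data.frame(do.call(rbind, recs))
  np <- ncol(tab) - 2L
  names(tab)[np + 1:2] <- c("p_eff", "aic")
  ord <- do.call(order, c(list(tab$aic), as.list(tab[seq_len(np)])))
  best <- ord[1]
  list(beta = betas[[best]],
       tuning = as.list(tab[best, seq_len(np), drop = FALSE]),
       p_eff = tab$p_eff[best], aic = tab$aic[best], audit = tab)
}

# AIC bookkeeping for one candidate fit
aic_record <- function(fit) {
  p <- effective_params(fit$beta, fit$family)
  n <- fit$n
  if (n - p - 1 <= 0) {
    list(p_eff = p, sigma_sq_hat = NA_real_, log_lik = -Inf, aic = Inf)
  } else {
    s2 <- sum(fit$residuals^2) / (n - p - 1)
    ll <- if (s2 <= 0) Inf else (-n * log(s2) - n - p - 1) / 2
    list(p_eff = p, sigma_sq_hat = s2, log_lik = ll, aic = -2 * ll + 2 * p)
  }
}

#' AIC-tuned penalized fit over a parameter grid
#'
#' Fits every point of the tuning grid and returns the candidate with the
#' smallest `AIC = -2 log L + 2 p`, where `p` is the family's effective
#' parameter count (see [effective_params()]) and the log-likelihood uses
#' the plug-in variance `RSS / (n - p - 1)`. Candidates with
#' `n - p - 1 <= 0` get `AIC = +Inf`; ties are broken by the smallest
#' parameter tuple in lexicographic order. If every candidate is rejected,
#' the null fit (`beta = 0`) is returned with a warning.
#'
#' @inheritParams penreg
#' @param grid named list of per-parameter grids (default
#'   [default_grid()]).
#' @param audit if `TRUE`, attach a data.frame of all candidate AICs.
#' @return The selected `penreg` fit, augmented with `tuning` (selected
#'   parameters), `selection` (AIC record) and, optionally, `audit`.
#' @examples
#' d <- simulate_rv_data(make_case_config("rv_only", 1, 0, seed = 1))
#' fit <- penreg_tune(d$geno, d$trait, family = "lasso",
#'                    grid = list(lambda = c(0.01, 0.1, 1)))
#' fit$tuning
#' @export
penreg_tune <- function(x, y, family = c("lasso", "gflasso_r1",
                                         "gflasso_rcor", "tlp_s", "tlp_sg",
                                         "ols"),
                        grid = default_grid(family),
                        control = penreg_control(), audit = FALSE) {
  family <- match.arg(family)
  if (family == "ols" || length(grid) == 0L) {
    fit <- penreg(x, y, family = "ols", control = control)
    fit$tuning <- list()
    fit$selection <- aic_record(fit)
    return(fit)
  }
  stopifnot(all(lengths(grid) > 0))
  xd <- geno_dosages(x)
  yv <- as.numeric(y)
  eng <- tune_engine(xd, yv, family, grid, control)
  best <- NULL
  if (is.finite(eng$aic)) {
    best <- do.call(penreg, c(list(x = xd, y = yv, family = family,
                                   control = control), eng$tuning))
    best$tuning <- eng$tuning
    best$selection <- aic_record(best)
  }
  if (is.null(best)) {
    warning("all grid candidates rejected (n - p - 1 <= 0); ",
            "returning the null fit", call. = FALSE)
    beta <- stats::setNames(rep(0, ncol(xd)), colnames(xd))
    best <- structure(list(beta = beta, intercept = mean(yv),
                           family = family, params = list(),
                           objective = NA_real_, converged = TRUE,
                           iterations = 0L, n = nrow(xd), k = ncol(xd),
                           fitted.values = rep(mean(yv), nrow(xd)),
                           residuals = yv - mean(yv), call = match.call()),
                      class = "penreg")
    best$tuning <- list()
    best$selection <- aic_record(best)
  }
  if (audit) best$audit <- eng$audit
  best
}
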
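#' One-degree-of-freedom statistic on the fitted linear predictor
#'
#' Collapses a penalized fit to the single covariate `Z = X beta_hat` and
#' returns the F statistic (1, n-2 df) of the simple regression of the
#' trait on `Z`; a constant `Z` (e.g. `beta_hat = 0`) gives 0.
#'
#' @param geno dosage matrix used for the fit.
#' @param trait trait vector.
#' @param est a `penreg` fit (or plain coefficient vector).
#' @return scalar F statistic.
#' @export
one_df_statistic <- function(geno, trait, est) {
  beta <- if (inherits(est, "penreg")) est$beta else as.numeric(est)
  x <- geno_dosages(geno)
  y <- as.numeric(trait)
  z <- drop(x %*% beta)
  zc <- z - mean(z)
  szz <- sum(zc^2)
  if (szz <= 0) return(0)
  yc <- y - mean(y)
  b <- sum(zc * yc) / szz
  rss <- sum(yc^2) - b^2 * szz
  n <- length(y)
  if (rss <= 0) return(Inf)
  b^2 * szz / (rss / (n - 2))
}

#' Post-selection SSU / SSUw statistic
#'
#' Restricts the score vector and its covariance to the variants the
#' penalized fit selected (`|beta_hat_j| > 0.001`) and returns
#' `U*'U*` (`kind = "ssu"`) or `U*' diag(V*)^{-1} U*` (`kind = "ssuw"`).
#' The grouping structure of the fit is not used. An empty selection gives
#' 0; selected variants with a zero score variance are dropped from the
#' SSUw form.
#'
#' @param sc [score_components()] of the same dataset the fit used.
#' @param est a `penreg` fit (or coefficient vector).
#' @param kind `"ssu"` or `"ssuw"`.
#' @param threshold selection threshold on `|beta_hat|` (default 0.001).
#' @return scalar statistic.
#' @export
selected_score_statistic <- function(sc, est, kind = c("ssu", "ssuw"),
                                     threshold = 0.001) {
  kind <- match.arg(kind)
  beta <- if (inherits(est, "penreg")) est$beta else as.numeric(est)
  sel <- which(abs(beta) > threshold)
  if (length(sel) == 0L) return(0)
  U <- sc$U[sel]
  if (kind == "ssu") return(sum(U^2))
  d <- sc$diag_V[sel]
  ok <- d > 1e-12 * max(d, 1)
  if (!any(ok)) return(0)
  sum(U[ok]^2 / d[ok])
}

#' Permutation-calibrated test based on a penalized fit
#'
#' Implements the four-step permutation procedure: (1) tune and fit the
#' penalized model on the observed data by AIC grid search; (2) compute the
#' test statistic(s) `T`; (3) for each of `B` trait permutations repeat the
#' full pipeline — the tuning parameters are re-estimated on every permuted
#' dataset; (4) `p = sum_b I(T < T0_b) / B` (strict inequality; ties count
#' as non-rejection, and `p = 0` is possible at finite `B`; set
#' `add_one = TRUE` for the `(sum + 1)/(B + 1)` variant).
#'
#' The SSU/SSUw post-selection statistics are reported for the TLP-SG
#' family; pass `allow_any_stat = TRUE` to apply them to other families.
#'
#' @inheritParams penreg
#' @param geno dosage matrix (n x k).
#' @param trait numeric trait vector.
#' @param stats character vector among `"one_df"`, `"ssu"`, `"ssuw"`; all
#'   requested statistics share one set of fits.
#' @param grid tuning grid (default [default_grid()]).
#' @param B number of permutations (default 100).
#' @param seed optional integer seed; results are reproducible given the
#'   seed.
#' @param add_one use the `(sum + 1)/(B + 1)` p-value estimator.
#' @param allow_any_stat allow SSU/SSUw statistics for families other than
#'   `tlp_sg`.
#' @return Object of class `perm_test`: observed statistics, the `B` null
#'   statistics, p-values per statistic and the per-permutation selected
#'   tuning parameters.
#' @examples
#' d <- simulate_rv_data(make_case_config("rv_only", 1, 0, seed = 1))
#' pt <- perm_assoc_test(d$geno, d$trait, family = "lasso",
#'                       grid = list(lambda = c(0.1, 1)), B = 20, seed = 2)
#' pt$p_value
#' @export
perm_assoc_test <- function(geno, trait,
                            family = c("lasso", "gflasso_r1", "gflasso_rcor",
                                       "tlp_s", "tlp_sg", "ols"),
                            stats = "one_df",
                            grid = default_grid(family),
                            B = 100, seed = NULL, add_one = FALSE,
                            allow_any_stat = FALSE,
                            control = penreg_control()) {
  family <- match.arg(family)
  stats <- match.arg(stats, c("one_df", "ssu", "ssuw"), several.ok = TRUE)
  if (B < 1) stop("'B' must be >= 1")
  if (any(stats %in% c("ssu", "ssuw")) && family != "tlp_sg" &&
      family != "ols" && !allow_any_stat)
    stop("post-selection SSU/SSUw statistics are reported for 'tlp_sg'; ",
         "set allow_any_stat = TRUE to override")
  x <- geno_dosages(geno)
  y <- as.numeric(trait)
  need_sc <- any(stats %in% c("ssu", "ssuw"))
  stat_fun <- function(yv, fit, sc) {
    vapply(stats, function(s) {
      switch(s,
             one_df = one_df_statistic(x, yv, fit),
             ssu = selected_score_statistic(sc, fit, "ssu"),
             ssuw = selected_score_statistic(sc, fit, "ssuw"))
    }, numeric(1))
  }
  fit_obs <- penreg_tune(x, y, family = family, grid = grid,
                         control = control)
  sc_obs <- if (need_sc) score_components(x, y) else NULL
  obs <- stat_fun(y, fit_obs, sc_obs)
  null_T <- matrix(NA_real_, B, length(stats),
                   dimnames = list(NULL, stats))
  params <- vector("list", B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      yb <- sample(y)
      eng <- tune_engine(x, yb, family, grid, control)
      sc_b <- if (need_sc) score_components(x, yb) else NULL
      null_T[b, ] <- stat_fun(yb, eng$beta, sc_b)
      params[[b]] <- unlist(eng$tuning)
    }
  })
  hits <- colSums(sweep(null_T, 2, obs, FUN = function(t0, t) t < t0))
  p <- if (add_one) (hits + 1) / (B + 1) else hits / B
  per_perm <- if (length(params[[1]]))
    as.data.frame(do.call(rbind, params)) else NULL
  structure(list(observed_T = obs, null_T = null_T, B = B,
                 p_value = stats::setNames(p, stats), family = family,
                 tuning = fit_obs$tuning, per_perm_params = per_perm,
                 add_one = add_one),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$family, "), B = ", x$B, "\n", sep = "")
  if (length(x$tuning))
    cat("selected tuning:", paste(names(x$tuning),
                                  signif(unlist(x$tuning), 4),
                                  sep = " = ", collapse = ", "), "\n")
  out <- data.frame(statistic = names(x$observed_T),
                    T = unname(x$observed_T),
                    p_value = unname(x$p_value))
  print(out, row.names = FALSE)
  invisible(x)
}
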
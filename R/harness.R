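ols_stats <- c("F", "Score", "SSU", "SSUw", "UminP", "Sum", "aSum")

parse_methods <- function(methods) {
  parts <- strsplit(methods, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("method spec must be 'fitting/statistic': ",
                     paste(methods[bad], collapse = ", "))
  data.frame(fitting = vapply(parts, `[`, "", 1),
             statistic = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Empirical power / type-I error of association tests
#'
#' Replicate-level harness: for each replicate, simulates a dataset from
#' the configuration, runs every requested method, and records whether its
#' p-value falls below the nominal level. Methods are given as
#' `"fitting/statistic"` strings, e.g. `"ols/SSU"`, `"ols/Sum"`,
#' `"lasso/1df"`, `"tlp_sg/ssuw"`. OLS statistics use their asymptotic
#' p-values (aSum is permutation-based); penalized fits are calibrated by
#' [perm_assoc_test()] with per-permutation AIC retuning. A method failing
#' on a replicate is logged and counted as a non-rejection.
#'
#' @param config a [make_case_config()] configuration (use `null = TRUE`
#'   for type-I error).
#' @param methods character vector of `"fitting/statistic"` specs.
#' @param n_replicates number of simulation replicates (default 200).
#' @param alpha nominal level (default 0.05).
#' @param B permutation count for permutation-based methods (default 100).
#' @param seed integer seed; the full table is reproducible from
#'   `(config, seed)`.
#' @return data.frame of class `power_table`: one row per method with the
#'   rejection fraction (`power`), plus the design descriptors. A
#'   `failures` attribute tallies per-method failures.
#' @examples
#' cfg <- make_case_config("rv_only", 1, 0, n = 100)
#' estimate_power(cfg, c("ols/Sum", "ols/SSU"), n_replicates = 5, seed = 1)
#' @export
estimate_power <- function(config, methods, n_replicates = 200,
                           alpha = 0.05, B = 100, seed = 1) {
  stopifnot(n_replicates >= 1, alpha > 0, alpha < 1)
  ms <- parse_methods(methods)
  seeds <- with_seed(seed, matrix(sample.int(2^31 - 2, 2 * n_replicates),
                                  n_replicates, 2))
  rej <- matrix(0, n_replicates, nrow(ms))
  fail <- integer(nrow(ms))
  pen_fams <- unique(ms$fitting[ms$fitting != "ols"])
  for (r in seq_len(n_replicates)) {
    d <- simulate_rv_data(config, seed = seeds[r, 1])
    pvals <- rep(NA_real_, nrow(ms))
    sc <- NULL
    for (i in which(ms$fitting == "ols")) {
      st <- ms$statistic[i]
      pvals[i] <- tryCatch(suppressWarnings({
        if (st %in% c("Score", "SSU", "SSUw", "UminP") && is.null(sc))
          sc <- score_components(d$geno, d$trait)
        switch(st,
               "F" = f_test(d$geno, d$trait)$p.value,
               "Score" = score_test(sc)$p.value,
               "SSU" = ssu_test(sc)$p.value,
               "SSUw" = ssuw_test(sc)$p.value,
               "UminP" = uminp_test(sc)$p.value,
               "Sum" = sum_test(d$geno, d$trait)$p.value,
               "aSum" = asum_test(d$geno, d$trait, B = B,
                                  seed = seeds[r, 2])$p.value,
               stop("unknown OLS statistic: ", st))
      }), error = function(e) NA_real_)
    }
    for (fam in pen_fams) {
      idx <- which(ms$fitting == fam)
      sts <- sub("^1df$", "one_df", ms$statistic[idx])
      res <- tryCatch(suppressWarnings(
        perm_assoc_test(d$geno, d$trait, family = fam, stats = sts,
                        B = B, seed = seeds[r, 2], allow_any_stat = TRUE)),
        error = function(e) NULL)
      if (!is.null(res)) pvals[idx] <- res$p_value[sts]
    }
    bad <- is.na(pvals)
    fail <- fail + bad
    rej[r, ] <- !bad & pvals < alpha
  }
  out <- data.frame(fitting = ms$fitting, statistic = ms$statistic,
                    scheme = config$scheme, case = config$case,
                    n_noncausal = config$k - 6L,
                    power = colMeans(rej),
                    alpha = alpha, n_replicates = n_replicates)
  attr(out, "failures") <- stats::setNames(fail, methods)
  class(out) <- c("power_table", "data.frame")
  out
}

#' Count true/false positives of a coefficient estimate
#'
#' A coefficient with `|beta_hat_j| > threshold` (default 0.001) counts as
#' a positive; positives at causal positions are true positives.
#'
#' @param est a `penreg` fit or coefficient vector.
#' @param causal_mask logical vector marking causal positions.
#' @param threshold positivity threshold.
#' @return named vector `c(TP, FP)`.
#' @examples
#' count_tp_fp(c(0.5, 0.0005, -0.2), c(TRUE, TRUE, FALSE))
#' @export
count_tp_fp <- function(est, causal_mask, threshold = 0.001) {
  beta <- if (inherits(est, "penreg")) est$beta else as.numeric(est)
  stopifnot(length(beta) == length(causal_mask))
  pos <- abs(beta) > threshold
  c(TP = sum(pos & causal_mask), FP = sum(pos & !causal_mask))
}

# AIC-tuned fit of one family (ols passes through untuned)
tuned_fit <- function(x, y, family) {
  suppressWarnings(penreg_tune(x, y, family = family))
}

#' Variable-selection summary over replicates
#'
#' Mean (and sd) numbers of true and false positives of AIC-tuned fits
#' across simulation replicates, with `|beta_hat| > 0.001` counted as a
#' positive.
#'
#' @inheritParams estimate_power
#' @param families penalty families to fit (AIC-tuned; `"ols"` allowed).
#' @return data.frame with per-family TP/FP means and sds.
#' @export
selection_summary <- function(config, families, n_replicates = 200,
                              seed = 1) {
  seeds <- with_seed(seed, sample.int(2^31 - 2, n_replicates))
  res <- array(NA_real_, c(n_replicates, length(families), 2))
  for (r in seq_len(n_replicates)) {
    d <- simulate_rv_data(config, seed = seeds[r])
    mask <- attr(d$geno, "causal_mask")
    for (f in seq_along(families)) {
      fit <- tuned_fit(d$geno, d$trait, families[f])
      res[r, f, ] <- count_tp_fp(fit, mask)
    }
  }
  data.frame(family = families,
             tp_mean = apply(res[, , 1, drop = FALSE], 2, mean),
             tp_sd = apply(res[, , 1, drop = FALSE], 2, sd),
             fp_mean = apply(res[, , 2, drop = FALSE], 2, mean),
             fp_sd = apply(res[, , 2, drop = FALSE], 2, sd),
             n_replicates = n_replicates)
}

#' Coefficient-estimate summary over replicates
#'
#' Tracks, in each replicate, the first two causal positions carrying the
#' largest (unscaled) positive effect and the first non-causal position,
#' fits each family with AIC tuning, and reports the mean, sd and mean
#' squared error (about the truth) of the estimates across replicates.
#'
#' @inheritParams selection_summary
#' @return data.frame with one row per family and tracked slot
#'   (`causal_1`, `causal_2`, `noncausal`), giving `truth`, `mean`, `sd`
#'   and `mse`.
#' @export
estimate_coef_summary <- function(config, families, n_replicates = 200,
                                  seed = 1) {
  seeds <- with_seed(seed, sample.int(2^31 - 2, n_replicates))
  slots <- c("causal_1", "causal_2", "noncausal")
  est <- array(NA_real_, c(n_replicates, length(families), 3),
               dimnames = list(NULL, families, slots))
  tru <- matrix(NA_real_, n_replicates, 3)
  target <- max(config$causal_values)
  for (r in seq_len(n_replicates)) {
    d <- simulate_rv_data(config, seed = seeds[r])
    cpos <- sort(d$causal_positions[d$beta[d$causal_positions] == target])
    pad <- c(if (length(cpos) >= 1) cpos[1] else NA_integer_,
             if (length(cpos) >= 2) cpos[2] else NA_integer_,
             setdiff(seq_len(config$k), d$causal_positions)[1])
    tru[r, ] <- ifelse(is.na(pad), NA, d$beta[pad])
    for (f in seq_along(families)) {
      fit <- tuned_fit(d$geno, d$trait, families[f])
      est[r, f, ] <- ifelse(is.na(pad), NA, fit$beta[pad])
    }
  }
  rows <- list()
  for (f in seq_along(families)) for (s in 1:3) {
    e <- est[, f, s]; tr <- tru[, s]
    ok <- !is.na(e)
    rows[[length(rows) + 1]] <- data.frame(
      family = families[f], slot = slots[s],
      truth = mean(tr[ok]),
      mean = mean(e[ok]), sd = sd(e[ok]),
      mse = mean((e[ok] - tr[ok])^2),
      n_used = sum(ok))
  }
  out <- do.call(rbind, rows)
  out$n_replicates <- n_replicates
  out
}

#' Solution path of a penalized fit over one tuning parameter
#'
#' Recomputes the fit along a sequence of values of one tuning parameter,
#' holding the others fixed — the display on which the step-like character
#' of the truncated-L1 paths (versus the piecewise-linear Lasso path) is
#' visible.
#'
#' @inheritParams penreg
#' @param over name of the varied parameter (`"lambda"`, `"lambda1"`,
#'   `"lambda2"` or `"tau"`).
#' @param values numeric sequence of parameter values.
#' @param ... fixed values of the remaining tuning parameters.
#' @return matrix of class `penreg_path` (length(values) x k) of
#'   coefficient estimates, with the grid as the `values` attribute.
#' @export
penreg_path <- function(x, y, family, over, values, ...,
                        control = penreg_control()) {
  fixed <- list(...)
  k <- ncol(geno_dosages(x))
  out <- matrix(NA_real_, length(values), k)
  for (i in seq_along(values)) {
    args <- c(list(x = x, y = y, family = family, control = control),
              fixed, stats::setNames(list(values[i]), over))
    out[i, ] <- do.call(penreg, args)$beta
  }
  structure(out, values = values, over = over, family = family,
            class = c("penreg_path", "matrix", "array"))
}

#' @export
plot.penreg_path <- function(x, ...) {
  graphics::matplot(attr(x, "values"), abs(unclass(x)), type = "l",
                    xlab = attr(x, "over"), ylab = "|coefficient|",
                    main = paste("solution path:", attr(x, "family")), ...)
  invisible(x)
}
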
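#' Simulation configuration for rare/common-variant studies
#'
#' Builds the study configuration for the two generating schemes:
#' \describe{
#'   \item{`rv_only`}{`k = 6 + n_noncausal` rare variants, generated as the
#'     sum of two latent-Gaussian AR1 haplotypes with target MAF drawn
#'     uniformly on `[0.005, 0.01]`.}
#'   \item{`rv_cv`}{as above, but two of the `k` variants (at uniformly
#'     random positions) are common variants with coded-allele frequency
#'     uniform on `[0.2, 0.7]`; a common variant landing on a causal
#'     position has its effect divided by 10.}
#' }
#' The six causal effect vectors are, by case: for `rv_only`,
#' `(0.9 x6)`, `(1.2, 1.2, 1.2, -1.2, -1.2, -1.2)` and
#' `(1.4, 1.3, -1.2, 1.2, -1.3, 1.4)`; for `rv_cv`, `(1 x6)`,
#' `(1.5, 1.5, 1.5, -1.5, -1.5, -1.5)` and
#' `(1.1, 1.3, -1.2, 1.2, -1.3, 1.1)`. Causal positions are drawn
#' uniformly at random in each replicate. Traits follow
#' `Y = 0.3 + X beta + N(0, 2)`.
#'
#' @param scheme `"rv_only"` or `"rv_cv"`.
#' @param case effect-pattern case, 1, 2 or 3.
#' @param n_noncausal number of non-causal variants added to the six
#'   causal ones.
#' @param n sample size (default 400).
#' @param seed optional integer seed stored in the config.
#' @param null if `TRUE`, all causal effects are set to 0 (type-I error
#'   configuration).
#' @return list of class `sim_config`.
#' @examples
#' make_case_config("rv_only", 2, 8)$causal_values
#' @export
make_case_config <- function(scheme = c("rv_only", "rv_cv"), case,
                             n_noncausal = 0, n = 400, seed = NULL,
                             null = FALSE) {
  scheme <- match.arg(scheme)
  if (!case %in% 1:3) stop("'case' must be 1, 2 or 3")
  if (n_noncausal < 0) stop("'n_noncausal' must be >= 0")
  cv <- switch(as.character(case),
    "1" = if (scheme == "rv_only") rep(0.9, 6) else rep(1, 6),
    "2" = if (scheme == "rv_only") c(1.2, 1.2, 1.2, -1.2, -1.2, -1.2)
          else c(1.5, 1.5, 1.5, -1.5, -1.5, -1.5),
    "3" = if (scheme == "rv_only") c(1.4, 1.3, -1.2, 1.2, -1.3, 1.4)
          else c(1.1, 1.3, -1.2, 1.2, -1.3, 1.1))
  if (null) cv <- rep(0, 6)
  structure(list(scheme = scheme, case = case, n = n,
                 k = 6L + as.integer(n_noncausal), n_causal = 6L,
                 causal_values = cv, beta0 = 0.3, sigma_sq = 2, rho = 0.8,
                 rv_maf_range = c(0.005, 0.01),
                 cv_freq_range = c(0.2, 0.7),
                 n_cv = if (scheme == "rv_cv") 2L else 0L,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("simulation config: scheme =", x$scheme, ", case =", x$case,
      ", n =", x$n, ", k =", x$k, "\n")
  cat("causal effects:", paste(x$causal_values, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate haplotypes from a dichotomized latent AR1 Gaussian
#'
#' Draws latent vectors `z ~ MVN(0, R)` with `R[j, j'] = rho^|j - j'|` and
#' sets allele `j` present when `z_j > qnorm(1 - maf_j)`, so each variant
#' attains its target allele frequency while neighbouring variants are in
#' linkage disequilibrium that decays by a factor `rho` per lag.
#'
#' @param maf per-variant target allele frequencies, in `(0, 0.5]`.
#' @param rho AR1 latent correlation, `|rho| < 1`.
#' @param n number of haplotypes to draw.
#' @return `n x k` binary matrix (0/1 allele indicators).
#' @export
simulate_haplotype <- function(maf, rho = 0.8, n = 1) {
  stopifnot(all(maf > 0), all(maf <= 0.5), abs(rho) < 1)
  k <- length(maf)
  R <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
  z <- matrix(rnorm(n * k), n, k) %*% chol(R)
  out <- sweep(z, 2, qnorm(1 - maf), ">") * 1
  out
}

#' Simulate a genotype matrix under a configuration
#'
#' Rare-variant genotypes are the sum of two independent haplotypes from
#' [simulate_haplotype()] with per-replicate target MAFs drawn uniformly on
#' the configured range. Under the `rv_cv` scheme, `n_cv` columns at
#' uniformly random positions are replaced by common variants generated as
#' binomial(2, freq) dosages with `freq` uniform on the configured range
#' (independent of the rare-variant latent block). Monomorphic simulated
#' columns are kept, as in real data.
#'
#' @param config a [make_case_config()] configuration.
#' @return a [genotype_matrix()] with attributes `cv_positions` and
#'   `target_maf`.
#' @export
simulate_genotypes <- function(config) {
  k <- config$k; n <- config$n
  cv_pos <- integer(0)
  if (config$n_cv > 0) cv_pos <- sort(sample.int(k, config$n_cv))
  k_rv <- k - length(cv_pos)
  maf_rv <- runif(k_rv, config$rv_maf_range[1], config$rv_maf_range[2])
  h1 <- simulate_haplotype(maf_rv, config$rho, n)
  h2 <- simulate_haplotype(maf_rv, config$rho, n)
  g <- matrix(0, n, k)
  target <- numeric(k)
  rv_pos <- setdiff(seq_len(k), cv_pos)
  g[, rv_pos] <- h1 + h2
  target[rv_pos] <- maf_rv
  if (length(cv_pos)) {
    freq <- runif(length(cv_pos), config$cv_freq_range[1],
                  config$cv_freq_range[2])
    g[, cv_pos] <- vapply(freq, function(f) rbinom(n, 2L, f), numeric(n))
    target[cv_pos] <- freq
  }
  out <- genotype_matrix(g)
  attr(out, "cv_positions") <- cv_pos
  attr(out, "target_maf") <- target
  out
}

#' Simulate a quantitative trait from genotypes
#'
#' `Y_i = beta0 + X_i beta + e_i` with `e_i ~ N(0, sigma^2)` i.i.d.
#'
#' @param geno genotype matrix.
#' @param beta length-k coefficient vector.
#' @param config configuration providing `beta0` and `sigma_sq`.
#' @return numeric trait vector.
#' @export
simulate_trait <- function(geno, beta, config) {
  x <- geno_dosages(geno)
  stopifnot(length(beta) == ncol(x))
  drop(config$beta0 + x %*% beta +
         rnorm(nrow(x), 0, sqrt(config$sigma_sq)))
}

#' Simulate one replicate dataset
#'
#' Draws genotypes, places the six causal effects at uniformly random
#' positions (a causal common variant's effect is divided by 10), and
#' generates the trait.
#'
#' @param config a [make_case_config()] configuration.
#' @param seed optional seed overriding `config$seed`.
#' @return list with `geno` (causal mask attached), `trait`, `beta` (the
#'   realized k-vector), `causal_positions`, `cv_positions` and `config`.
#' @examples
#' d <- simulate_rv_data(make_case_config("rv_cv", 2, 24, seed = 7))
#' table(d$beta[d$causal_positions])
#' @export
simulate_rv_data <- function(config, seed = config$seed) {
  with_seed(seed, {
    geno <- simulate_genotypes(config)
    k <- config$k
    pos <- sample.int(k, config$n_causal)
    beta <- numeric(k)
    beta[pos] <- config$causal_values
    cv_pos <- attr(geno, "cv_positions")
    scaled <- intersect(pos, cv_pos)
    beta[scaled] <- beta[scaled] / 10
    trait <- simulate_trait(geno, beta, config)
    attr(geno, "causal_mask") <- seq_len(k) %in% pos
    list(geno = geno, trait = trait, beta = beta,
         causal_positions = pos, cv_positions = cv_pos, config = config)
  })
}
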
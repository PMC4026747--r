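# Shared fixtures and independent oracles used across the suite.

# small random dosage matrix with common-ish variants (always polymorphic)
rand_geno <- function(n, k, seed, maf = 0.3) {
  set.seed(seed)
  repeat {
    g <- matrix(rbinom(n * k, 2, maf), n, k)
    if (all(apply(g, 2, var) > 0)) return(g)
  }
}

# centered orthonormal design (columns orthonormal and mean-zero)
orthonormal_design <- function(n, k, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * k), n, k)
  m <- sweep(m, 2, colMeans(m))
  qr.Q(qr(m))[, seq_len(k), drop = FALSE]
}

# dense grid minimizer of 0.5||Yc - Xc b||^2 + penalty(b) for k = 1 or 2;
# penalty_fn maps a (points x k) matrix to a penalty vector
grid_min <- function(x, y, penalty_fn, lim = 3, step = 0.005) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  A <- crossprod(xc)
  b <- drop(crossprod(xc, yc))
  yty <- sum(yc^2)
  g <- seq(-lim, lim, by = step)
  if (ncol(x) == 1L) {
    pts <- matrix(g, ncol = 1)
    loss <- 0.5 * (yty - 2 * b[1] * g + A[1, 1] * g^2)
  } else {
    pts <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
    loss <- 0.5 * (yty - 2 * (pts %*% b) +
                     A[1, 1] * pts[, 1]^2 + 2 * A[1, 2] * pts[, 1] * pts[, 2] +
                     A[2, 2] * pts[, 2]^2)
  }
  obj <- drop(loss) + penalty_fn(pts)
  i <- which.min(obj)
  list(beta = pts[i, ], objective = obj[i])
}

# per-element penalties for grid_min
pen_lasso <- function(lambda) function(p) lambda * rowSums(abs(p))
pen_tlp_s <- function(l1, tau) function(p) l1 * rowSums(pmin(abs(p) / tau, 1))
pen_gfl <- function(l1, l2, r = 1) function(p) {
  l1 * rowSums(abs(p)) +
    if (ncol(p) == 2) l2 * abs(p[, 1] - r * p[, 2]) else 0
}
pen_tlp_sg <- function(l1, l2, tau) function(p) {
  l1 * rowSums(pmin(abs(p) / tau, 1)) +
    if (ncol(p) == 2)
      l2 * pmin(abs(abs(p[, 1]) - abs(p[, 2])) / tau, 1) else 0
}
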
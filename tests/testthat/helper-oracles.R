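# Independent oracles used to cross-check the package's own computations.
# They deliberately follow different code paths (or different algorithms)
# than the implementation under test.

# Textbook NIPALS with an explicit inner u-loop, no sign convention, no
# ledger bookkeeping. Returns weights/scores/loadings/coefficients.
oracle_nipals <- function(X, y, A, center = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- if (center) colMeans(X) else rep(0, ncol(X))
  ym <- if (center) mean(y) else 0
  E <- sweep(X, 2, xm); f <- y - ym
  n <- nrow(E); p <- ncol(E)
  W <- P <- matrix(0, p, A); Tm <- matrix(0, n, A); q <- numeric(A)
  ssy <- numeric(A)
  for (a in 1:A) {
    u <- f
    w_old <- rep(Inf, p)
    repeat {
      w <- drop(crossprod(E, u)); w <- w / sqrt(sum(w^2))
      t <- drop(E %*% w)
      qa <- sum(t * f) / sum(t^2)
      u <- f # univariate response
      if (sqrt(sum((w - w_old)^2)) < 1e-13) break
      w_old <- w
    }
    pa <- drop(crossprod(E, t)) / sum(t^2)
    ss_before <- sum(f^2)
    E <- E - tcrossprod(t, pa)
    f <- f - t * qa
    ssy[a] <- ss_before - sum(f^2)
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t; q[a] <- qa
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  list(W = W, P = P, T = Tm, q = q, b = b, intercept = ym - sum(xm * b),
       ssy = ssy)
}

# Helland's Krylov-subspace closed form for centered univariate PLS
# coefficients: an algebraically different route to the same regression
# vector (no deflation at all).
oracle_krylov_coef <- function(X, y, A) {
  X <- as.matrix(X); y <- as.numeric(y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  s <- drop(crossprod(Xc, yc))
  C <- crossprod(Xc)
  K <- matrix(0, ncol(X), A)
  v <- s
  for (a in 1:A) { K[, a] <- v; v <- drop(C %*% v) }
  b <- K %*% solve(crossprod(K, C %*% K), crossprod(K, s))
  drop(b)
}

# Wold VIP assembled by brute force from the oracle fit's per-component
# explained y sums of squares.
oracle_vip <- function(X, y, A, center = FALSE) {
  m <- oracle_nipals(X, y, A, center = center)
  p <- ncol(as.matrix(X))
  sqrt(p * drop((m$W^2) %*% m$ssy) / sum(m$ssy))
}

# sign-align oracle component matrices to the package's convention
# (largest-|weight| entry positive) for direct comparison
align_signs <- function(oracle, W_ref) {
  flips <- vapply(seq_len(ncol(W_ref)), function(a) {
    sign(oracle$W[which.max(abs(oracle$W[, a])), a])
  }, numeric(1))
  oracle$W <- sweep(oracle$W, 2, flips, "*")
  oracle$P <- sweep(oracle$P, 2, flips, "*")
  oracle$T <- sweep(oracle$T, 2, flips, "*")
  oracle$q <- oracle$q * flips
  oracle
}

# exact two-sided Mann-Whitney p for tie-free samples via the closed-form
# Wilcoxon null distribution (independent of the package's enumeration)
oracle_mw_exact_p <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  U <- sum(outer(x0, x1, ">"))
  lo <- min(U, n0 * n1 - U); hi <- n0 * n1 - lo
  min(1, stats::pwilcox(lo, n0, n1) + stats::pwilcox(hi - 1, n0, n1, lower.tail = FALSE))
}

# small random test matrices with percentage-like values
rand_pct_matrix <- function(n, p, seed, lo = 5, hi = 40, sd = 3) {
  set.seed(seed)
  base <- runif(p, lo, hi)
  pmin(pmax(matrix(rep(base, each = n), n, p) + matrix(rnorm(n * p, sd = sd), n, p), 0), 100)
}

small_cohort <- function(seed, ...) {
  generate_cohort(cohort_config(seed = seed, ...))
}

tiny_cohort <- function(seed, n_variables = 20L) {
  generate_cohort(cohort_config(seed = seed, n_variables = n_variables,
                                n_informative = 5L, n_latent_factors = 3L))
}
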
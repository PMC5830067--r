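test_that("a single column proportional to y is fitted perfectly in one LV", {
  y <- c(0, 1, 0, 1, 1, 0)
  X <- cbind(v = 2 * y + 1)
  m <- fit_pls(X, y, A = 1, center = TRUE)
  expect_equal(unname(predict(m, X)), y, tolerance = 1e-12)
  led <- explained_variance(m)
  expect_equal(led$y_total[1], 100, tolerance = 1e-9)
})

test_that("NIPALS matches the textbook oracle and the Krylov closed form", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(40), 8, 5)
    y <- rnorm(8)
    for (center in c(TRUE, FALSE)) {
      m <- fit_pls(X, y, A = 2, center = center)
      o <- align_signs(oracle_nipals(X, y, 2, center = center), m$weights)
      expect_lt(max(abs(m$weights - o$W)), 1e-8)
      expect_lt(max(abs(m$x_scores - o$T)), 1e-8)
      expect_lt(max(abs(m$x_loadings - o$P)), 1e-8)
      expect_lt(max(abs(m$y_loadings - o$q)), 1e-8)
      expect_lt(max(abs(unname(m$coefficients) - o$b)), 1e-8)
    }
    m <- fit_pls(X, y, A = 3, center = TRUE)
    expect_lt(max(abs(unname(m$coefficients) - oracle_krylov_coef(X, y, 3))), 1e-8)
    # held-out prediction against the oracle
    set.seed(seed + 100)
    Xnew <- matrix(rnorm(10), 2, 5)
    o <- oracle_nipals(X, y, 3, center = TRUE)
    expect_equal(predict(m, Xnew), drop(Xnew %*% o$b) + o$intercept,
                 tolerance = 1e-8)
  }
})

test_that("predictions agree with mixOmics on centered data", {
  skip_if_not_installed("mixOmics")
  set.seed(42)
  X <- matrix(rnorm(60), 10, 6); colnames(X) <- paste0("v", 1:6)
  y <- rnorm(10)
  Xnew <- matrix(rnorm(18), 3, 6); colnames(Xnew) <- paste0("v", 1:6)
  m <- fit_pls(X, y, A = 3, center = TRUE)
  mo <- mixOmics::pls(X, matrix(y, ncol = 1), ncomp = 3, scale = FALSE,
                      mode = "regression")
  expect_equal(unname(predict(m, Xnew)),
               unname(predict(mo, Xnew)$predict[, 1, 3]), tolerance = 1e-8)
})

test_that("scores are mutually orthogonal and fits are deterministic", {
  for (seed in c(3, 17, 29)) {
    X <- rand_pct_matrix(12, 8, seed)
    y <- rep(c(0, 1), each = 6)
    m <- fit_pls(X, y, A = 4)
    G <- crossprod(m$x_scores)
    norms <- sqrt(diag(G))
    off <- abs(G - diag(diag(G))) / outer(norms, norms)
    expect_lt(max(off), 1e-8)
    m2 <- fit_pls(X, y, A = 4)
    expect_identical(m, m2)
  }
})

test_that("T q reconstruction, linearity through origin, and shape checks hold", {
  X <- rand_pct_matrix(10, 6, 5)
  y <- rep(c(0, 1), 5)
  m <- fit_pls(X, y, A = 3)
  expect_equal(unname(predict(m, X)), drop(m$x_scores %*% m$y_loadings),
               tolerance = 1e-10)
  expect_equal(unname(predict(m, rep(0, 6))), 0, tolerance = 1e-12)
  expect_error(predict(m, matrix(1, 2, 5)), "expects")
  expect_error(fit_pls(X, y, A = 11), "min\\(n, p\\)")
  expect_error(fit_pls(X, rep(1, 10), A = 2), "constant")
  X0 <- X; X0[, 3] <- 0
  expect_error(fit_pls(X0, y, A = 2), "degenerate direction")
})

test_that("variance ledger conserves partials and matches brute-force residuals", {
  for (seed in 1:4) {
    X <- rand_pct_matrix(9, 7, seed + 40)
    y <- rep(c(0, 1, 0), 3)
    for (center in c(TRUE, FALSE)) {
      m <- fit_pls(X, y, A = 4, center = center)
      led <- explained_variance(m)
      expect_equal(led$x_total, cumsum(led$x_partial), tolerance = 1e-9)
      expect_equal(led$y_total, cumsum(led$y_partial), tolerance = 1e-9)
      expect_true(all(diff(led$x_total) >= -1e-9))
      expect_true(all(led$y_partial >= -1e-9))
      expect_true(all(led$x_total <= 100 + 1e-9))
      # brute force: deflate with the oracle, re-measure residual SS per step
      xm <- if (center) colMeans(X) else rep(0, ncol(X))
      ym <- if (center) mean(y) else 0
      E0 <- sweep(X, 2, xm); f0 <- y - ym
      o <- oracle_nipals(X, y, 4, center = center)
      E <- E0; f <- f0
      for (a in 1:4) {
        E <- E - tcrossprod(o$T[, a], o$P[, a])
        f <- f - o$T[, a] * o$q[a]
        expect_equal(led$x_total[a], 100 * (1 - sum(E^2) / sum(E0^2)),
                     tolerance = 1e-8)
        expect_equal(led$y_total[a], 100 * (1 - sum(f^2) / sum(f0^2)),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("full-rank centered fit explains all of X", {
  set.seed(8)
  X <- matrix(rnorm(30), 6, 5)
  y <- rnorm(6)
  m <- fit_pls(X, y, A = 5, center = TRUE)
  expect_equal(explained_variance(m)$x_total[5], 100, tolerance = 1e-6)
})

test_that("an uncentered common offset concentrates X variance in LV1", {
  cohort <- small_cohort(21)
  m <- fit_pls(cohort$phenotype, cohort$phenotype$class_labels, A = 3)
  expect_gt(explained_variance(m)$x_partial[1], 90)
})

test_that("knee rule reads the ledger as intended", {
  expect_identical(knee_components(c(38.1, 26.2, 16.9, 3.4)), 3L)
  expect_identical(knee_components(c(100)), 1L)
  expect_identical(knee_components(c(2, 1, 0.5)), 1L)
})

test_that("component selection recovers simple and planted dimensions", {
  # perfect 1-LV structure: both criteria say 1
  y <- c(0, 1, 0, 1, 1, 0, 1, 0)
  X <- cbind(2 * y + 1, 0.5 * y + 2)
  expect_identical(select_n_components(X, y, 2, "explained_variance_knee",
                                       center = TRUE), 1L)
  expect_identical(select_n_components(X, y, 2, "loo_cv", center = TRUE), 1L)
  expect_error(select_n_components(X, y, 0), "at least 1")

  # 3-factor structure: LOO CV recovers A = 3 in most replicates
  hits <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    n <- 40; p <- 20
    Z <- matrix(rnorm(n * 3), n, 3)
    L <- matrix(rnorm(3 * p), 3, p)
    X <- Z %*% L + matrix(rnorm(n * p, sd = 0.1), n, p)
    y <- Z %*% c(1, -0.8, 0.6) + rnorm(n, sd = 0.1)
    A <- select_n_components(X, y, 6, "loo_cv", center = TRUE)
    hits <- hits + (A == 3L)
  }
  expect_gte(hits / 50, 0.8)
})
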
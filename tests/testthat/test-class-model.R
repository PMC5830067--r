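test_that("degenerate and undersized classes are rejected", {
  y <- rep(c(0, 1), each = 5)
  expect_error(fit_class_densities(y, y), "zero variance")
  expect_error(fit_class_densities(rnorm(4), c(0, 0, 1, 1)), "at least 3")
  expect_error(class_density_model(0, 0, 1, 1), "positive")
})

test_that("density fitting recovers known parameters and flags non-normal data", {
  set.seed(31)
  g0 <- rnorm(200, mean = 0.1, sd = 0.2)
  g1 <- rnorm(200, mean = 0.8, sd = 0.15)
  # finite normal samples can trip the normality warning by chance; only the
  # recovered parameters are under test here
  m <- suppressWarnings(fit_class_densities(c(g0, g1), rep(c(0, 1), each = 200)))
  # within 3 standard errors of truth
  expect_lt(abs(m$mu0 - 0.1), 3 * 0.2 / sqrt(200))
  expect_lt(abs(m$mu1 - 0.8), 3 * 0.15 / sqrt(200))
  expect_lt(abs(m$sigma0 - 0.2), 3 * 0.2 / sqrt(2 * 199))
  expect_lt(abs(m$sigma1 - 0.15), 3 * 0.15 / sqrt(2 * 199))

  set.seed(32)
  heavy <- rt(100, df = 1) # far from normal
  expect_warning(fit_class_densities(c(heavy, g1[1:100]), rep(c(0, 1), each = 100)),
                 class = "plscm_normality_warning")
})

test_that("risk curve has the specified orientation, limits and monotonicity", {
  m <- class_density_model(0, 1, 3, 0.5)
  rc <- risk_curve(m, grid_size = 401)
  expect_gt(rc$alpha[1], 0.999)           # grid minimum: alpha near its upper limit
  expect_lt(rc$beta[1], 1e-4)
  expect_true(all(diff(rc$alpha) <= 0))   # mu0 < mu1: alpha falls, beta rises
  expect_true(all(diff(rc$beta) >= 0))
  expect_true(all(rc$alpha >= 0 & rc$alpha <= 1 & rc$beta >= 0 & rc$beta <= 1))
  expect_error(risk_curve(m, grid_size = 1), "at least 2")
  expect_error(risk_curve(class_density_model(1, 1, 1, 1)), "equal")

  # monotonicity holds for seeded models in both orientations
  set.seed(44)
  for (i in 1:10) {
    mu <- sort(runif(2, -2, 2), decreasing = (i %% 2 == 0))
    mi <- class_density_model(mu[1], runif(1, 0.05, 1), mu[2], runif(1, 0.05, 1))
    rci <- risk_curve(mi, grid_size = 101)
    s <- if (mi$mu0 < mi$mu1) 1 else -1
    expect_true(all(s * diff(rci$alpha) <= 1e-12))
    expect_true(all(s * diff(rci$beta) >= -1e-12))
  }
})

test_that("symmetric class model balances alpha and beta at the midpoint", {
  m <- class_density_model(0, 0.3, 1, 0.3)
  rc <- risk_curve(m, grid_size = 1001)
  at_mid <- which.min(abs(rc$threshold - 0.5))
  expect_equal(rc$alpha[at_mid], rc$beta[at_mid], tolerance = 1e-9)
  op <- equal_error_point(m)
  expect_equal(op$threshold, 0.5, tolerance = 1e-12)
  expect_equal(op$sensitivity, pnorm(1 / 0.6) * 100, tolerance = 1e-10)
})

test_that("numeric equal-error root on the grid matches the closed form", {
  set.seed(55)
  for (i in 1:8) {
    mus <- runif(2, -1, 2); while (abs(diff(mus)) < 0.2) mus <- runif(2, -1, 2)
    m <- class_density_model(mus[1], runif(1, 0.05, 0.5), mus[2], runif(1, 0.05, 0.5))
    rc <- risk_curve(m, grid_size = 4001)
    t_num <- rc$threshold[which.min(abs(rc$alpha - rc$beta))]
    op <- equal_error_point(m)
    grid_step <- diff(rc$threshold[1:2])
    expect_lt(abs(t_num - op$threshold), grid_step)
  }
})

test_that("equal-error point is invariant to swapping the class labels", {
  m <- class_density_model(0.12, 0.25, 0.91, 0.18)
  swapped <- class_density_model(0.91, 0.18, 0.12, 0.25)
  a <- equal_error_point(m); b <- equal_error_point(swapped)
  expect_equal(a$sensitivity, b$sensitivity, tolerance = 1e-12)
  expect_equal(a$threshold, b$threshold, tolerance = 1e-12)
  expect_false(a$orientation == b$orientation)
})

test_that("sample assignment honours orientation and the tie rule", {
  m <- class_density_model(0.1, 0.2, 0.9, 0.2)
  op <- equal_error_point(m)
  res <- assign_samples(c(m$mu0, m$mu1, op$threshold), op,
                        coding = class_coding("ctrl", "case"))
  expect_identical(res$assigned, c(0L, 1L, 1L)) # tie goes to class 1
  expect_identical(res$assigned_label, c("ctrl", "case", "case"))

  flipped <- equal_error_point(class_density_model(0.9, 0.2, 0.1, 0.2))
  res2 <- assign_samples(c(0.9, 0.1), flipped)
  expect_identical(res2$assigned, c(0L, 1L))
})

test_that("empirical assignment accuracy matches the model-implied sensitivity", {
  m <- class_density_model(0.075, 0.219, 0.810, 0.146)
  op <- equal_error_point(m)
  set.seed(66)
  n0 <- 3600; n1 <- 1400
  y_hat <- c(rnorm(n0, m$mu0, m$sigma0), rnorm(n1, m$mu1, m$sigma1))
  labels <- rep(c(0, 1), c(n0, n1))
  res <- assign_samples(y_hat, op, labels = labels)
  expect_lt(abs(res$accuracy * 100 - op$sensitivity), 5)
  expect_identical(sum(res$confusion), as.integer(n0 + n1))
})
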
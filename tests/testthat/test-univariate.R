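test_that("exact Mann-Whitney enumeration matches the known small example", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$method, "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 0.1, tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact p equals the closed-form Wilcoxon null for tie-free samples", {
  set.seed(14)
  for (rep in 1:25) {
    n0 <- sample(2:6, 1); n1 <- sample(2:6, 1)
    if (n0 + n1 > 10) next
    x <- sample(seq(1, 100), n0 + n1) + runif(n0 + n1, 0, 0.4) # tie-free
    x0 <- x[seq_len(n0)]; x1 <- x[-seq_len(n0)]
    r <- mann_whitney(x0, x1)
    expect_identical(r$method, "exact")
    expect_equal(r$p_two_sided, oracle_mw_exact_p(x0, x1), tolerance = 1e-12)
  }
})

test_that("U statistics of swapped groups are complementary", {
  set.seed(15)
  for (rep in 1:10) {
    x0 <- round(rnorm(7), 1); x1 <- round(rnorm(9), 1) # ties likely
    a <- mann_whitney(x0, x1); b <- mann_whitney(x1, x0)
    expect_equal(a$U + b$U, a$n0 * a$n1, tolerance = 1e-12)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
  }
})

test_that("identical samples give the central statistic and p near 1", {
  x <- c(3, 1, 4, 1, 5)
  r <- mann_whitney(x, x)
  expect_equal(r$U, length(x)^2 / 2)
  expect_gte(r$p_two_sided, 0.99)
})

test_that("normal approximation agrees with wilcox.test under ties", {
  set.seed(16)
  for (rep in 1:10) {
    x0 <- round(rnorm(20, sd = 2), 0); x1 <- round(rnorm(15, 0.8, 2), 0)
    r <- mann_whitney(x0, x1)
    w <- suppressWarnings(stats::wilcox.test(x0, x1, correct = TRUE, exact = FALSE))
    expect_identical(r$method, "normal_approx")
    expect_equal(r$p_two_sided, w$p.value, tolerance = 1e-10)
  }
})

test_that("the screen has power at a 1.5 SD shift with 22 vs 14 subjects", {
  set.seed(17)
  hits <- 0L
  for (rep in 1:200) {
    p <- mann_whitney(rnorm(22), rnorm(14, mean = 1.5))$p_two_sided
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 200, 0.8)
})

test_that("screen flags planted variables and nothing else systematically", {
  cohort <- small_cohort(18)
  screen <- screen_variables(cohort$phenotype)
  expect_identical(nrow(screen), 350L)
  planted <- cohort$truth$informative_indices
  expect_gte(mean(screen$significant[planted]), 0.8)
  # a variable identical across classes is never significant
  vals <- cbind(same = rep(50, 20), rand = runif(20, 10, 20))
  sc <- screen_variables(vals, labels = rep(c(0, 1), 10))
  expect_false(sc$significant[1])
})

test_that("null screen keeps the type-I rate near alpha on independent variables", {
  fracs <- vapply(1:30, function(seed) {
    cohort <- generate_cohort(cohort_config(seed = seed, effect_size = 0,
                                            factor_strength = 0,
                                            n_latent_factors = 0L))
    mean(screen_variables(cohort$phenotype)$significant)
  }, numeric(1))
  # binomial SE at p = 0.05 over 350 variables x 30 seeds, doubled for slack
  expect_lt(abs(mean(fracs) - 0.05), 2 * sqrt(0.05 * 0.95 / (350 * 30)) + 0.01)
})

test_that("model importance anti-correlates with univariate p on planted signal", {
  neg <- 0L
  for (seed in 1:10) {
    cohort <- small_cohort(seed + 500)
    pheno <- cohort$phenotype
    res <- two_stage_fit(pheno$values, pheno$class_labels, A_stage1 = 3)
    screen <- screen_variables(pheno)
    assoc <- loading_pvalue_association(res$stage2_model,
                                        screen[res$selected_indices, ])
    neg <- neg + (assoc$rho < 0 && assoc$p_value < 0.05)
  }
  expect_gte(neg / 10, 0.8)
})

test_that("association degenerates cleanly and validates its inputs", {
  y <- rep(c(0, 1), each = 5)
  X <- rand_pct_matrix(10, 6, 19)
  m <- fit_pls(X, y, 2)
  screen <- screen_variables(X, labels = y)
  expect_error(loading_pvalue_association(m, screen[1:3, ]), "exactly")
  const_p <- screen; const_p$p <- 0.5
  expect_error(loading_pvalue_association(m, const_p), "degenerate ranks")
  m3 <- fit_pls(X[, 1:3], y, 2)
  expect_error(loading_pvalue_association(m3, screen[1:3, ]), "at least 4")
})

test_that("partition cross-tabulates selection and significance exhaustively", {
  screen <- data.frame(variable = paste0("v", 1:10),
                       U = 0, p = c(rep(0.01, 5), rep(0.5, 5)),
                       method = "exact")
  # selected: 3 significant-only overlap cases -> counts (0,3,2,5) pattern
  part <- partition_by_selection(c(6, 7, 8), screen, alpha = 0.05)
  expect_identical(part$n_selected_significant, 0L)
  expect_identical(part$n_selected_nonsignificant, 3L)
  expect_identical(part$n_unselected_significant, 5L)
  expect_identical(part$n_unselected_nonsignificant, 2L)
  total <- part$n_selected_significant + part$n_selected_nonsignificant +
    part$n_unselected_significant + part$n_unselected_nonsignificant
  expect_identical(total, 10L)
  all_sel <- partition_by_selection(1:5, screen[1:5, ], alpha = 0.05)
  expect_identical(all_sel$n_selected_significant, 5L)
  expect_error(partition_by_selection(11, screen), "out of range")
})

test_that("CD4 slope classification follows the signed-significance rule", {
  flat <- cd4_trajectory("flat", 0:4, rep(700, 5))
  expect_identical(classify_cd4_slope(flat)$category, "control")
  expect_equal(classify_cd4_slope(flat)$slope, 0)

  set.seed(20)
  decl <- cd4_trajectory("decl", 0:9, 1000 - 80 * (0:9) + rnorm(10, sd = 20))
  r <- classify_cd4_slope(decl)
  expect_identical(r$category, "case")
  expect_lt(abs(r$slope + 80), 20)

  incr <- cd4_trajectory("incr", 0:9, 500 + 50 * (0:9) + c(rep(c(-5, 5), 5)))
  expect_identical(classify_cd4_slope(incr)$category, "control")
})

test_that("slope classification is invariant to time origin and count units", {
  set.seed(21)
  counts <- 900 - 60 * (0:7) + rnorm(8, sd = 30)
  a <- classify_cd4_slope(cd4_trajectory("a", 0:7, counts))
  b <- classify_cd4_slope(cd4_trajectory("b", 0:7 + 3, counts))
  c3 <- classify_cd4_slope(cd4_trajectory("c", 0:7, counts * 10))
  expect_identical(a$category, b$category)
  expect_identical(a$category, c3$category)
  expect_equal(a$slope_p, b$slope_p, tolerance = 1e-9)
  expect_equal(a$slope_p, c3$slope_p, tolerance = 1e-9)
})
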
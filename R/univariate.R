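#' Mann-Whitney U test for two independent samples
#'
#' Two-sided rank-sum test. For small samples (`n0 + n1 <= 12`) without ties
#' the p-value is exact, obtained by enumerating all label arrangements of
#' the pooled sample; otherwise a midrank, tie-corrected normal
#' approximation with continuity correction is used. The statistic `U` is
#' the number of pairs in which a class-0 value exceeds a class-1 value
#' (ties counted 1/2), so `0 <= U <= n0 * n1` and swapping the groups maps
#' `U` to `n0 * n1 - U`.
#'
#' @param x0,x1 Numeric sample values for the two groups (non-empty).
#' @return An object of class `mann_whitney_result`: list with `U`,
#'   `p_two_sided`, `method` (`"exact"` or `"normal_approx"`), `n0`, `n1`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney <- function(x0, x1) {
  x0 <- as.numeric(x0); x1 <- as.numeric(x1)
  if (length(x0) == 0L || length(x1) == 0L) stop("both samples must be non-empty")
  if (anyNA(x0) || anyNA(x1)) stop("missing values are not allowed")
  n0 <- length(x0); n1 <- length(x1); N <- n0 + n1
  pooled <- c(x0, x1)
  r <- rank(pooled)                     # midranks
  U <- sum(r[seq_len(n0)]) - n0 * (n0 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && N <= 12L) {
    # exact null distribution by enumerating all choose(N, n0) arrangements
    combs <- utils::combn(N, n0)
    Us <- colSums(matrix(r[combs], nrow = n0)) - n0 * (n0 + 1) / 2
    lo <- min(U, n0 * n1 - U); hi <- n0 * n1 - lo
    p <- (sum(Us <= lo) + sum(Us >= hi)) / ncol(combs)
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n0 * n1 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n0 * n1 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- sign(U - mu) * 0.5          # continuity correction toward the mean
      z <- (U - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(U = U, p_two_sided = p, method = method, n0 = n0, n1 = n1),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n0 = %d, n1 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n0, x$n1, x$p_two_sided, x$method))
  invisible(x)
}

#' Univariate Mann-Whitney screen of all variables
#'
#' Tests each variable for a between-class location difference, one test per
#' column with no multiple-testing correction (raw two-sided p-values are
#' compared against `alpha`; with hundreds of variables the expected number
#' of false positives under the null is `alpha` times the variable count —
#' interpret the significant set accordingly).
#'
#' @param x A [phenotype_matrix()], or a plain matrix with `labels` given.
#' @param alpha Significance level on the raw p-values (default 0.05).
#' @param labels 0/1 labels when `x` is a plain matrix.
#' @return A data frame with one row per variable: `variable`, `U`, `p`,
#'   `method`, `significant`.
#' @export
screen_variables <- function(x, alpha = 0.05, labels = NULL) {
  if (inherits(x, "phenotype_matrix")) {
    labels <- x$class_labels
    vals <- x$values
  } else {
    vals <- as.matrix(x)
    if (is.null(labels)) stop("labels are required when x is a plain matrix")
    labels <- as.integer(labels)
  }
  stopifnot(all(labels %in% c(0L, 1L)), any(labels == 0L), any(labels == 1L))
  vn <- colnames(vals)
  if (is.null(vn)) vn <- paste0("V", seq_len(ncol(vals)))
  res <- lapply(seq_len(ncol(vals)), function(j) {
    mw <- mann_whitney(vals[labels == 0L, j], vals[labels == 1L, j])
    data.frame(variable = vn[j], U = mw$U, p = mw$p_two_sided,
               method = mw$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  out
}

#' Association between model importance and univariate p-values
#'
#' Spearman rank correlation between a per-variable magnitude taken from the
#' stage-2 PLS model and the Mann-Whitney p-value of the same variable. On
#' discriminative data the correlation is expected to be negative: variables
#' the model leans on tend to have small univariate p-values. The default
#' magnitude is the absolute composite regression coefficient; the PLS
#' weights or X-loadings (summed in absolute value across components) can be
#' chosen instead.
#'
#' @param stage2_model A fitted `pls_model` on the selected variables.
#' @param screen A data frame from [screen_variables()] covering exactly the
#'   stage-2 variables (matched by position).
#' @param measure `"coefficients"` (default), `"weights"` or `"loadings"`.
#' @return A list with `rho`, `p_value`, `measure`, `n`.
#' @export
loading_pvalue_association <- function(stage2_model, screen,
                                       measure = c("coefficients", "weights", "loadings")) {
  measure <- match.arg(measure)
  stopifnot(inherits(stage2_model, "pls_model"), is.data.frame(screen))
  p <- length(stage2_model$coefficients)
  if (nrow(screen) != p) {
    stop("screen must cover exactly the stage-2 variables (", p, " expected, got ",
         nrow(screen), ")")
  }
  if (p < 4L) stop("insufficient data: at least 4 variables are needed")
  mag <- switch(measure,
                coefficients = abs(stage2_model$coefficients),
                weights = rowSums(abs(stage2_model$weights)),
                loadings = rowSums(abs(stage2_model$x_loadings)))
  pv <- screen$p
  if (length(unique(pv)) < 2L || length(unique(mag)) < 2L) {
    stop("degenerate ranks: correlation undefined when p-values or magnitudes are constant")
  }
  ct <- suppressWarnings(stats::cor.test(mag, pv, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, measure = measure, n = p)
}

#' Cross-tabulate VIP selection against univariate significance
#'
#' Partitions the variables into the four selected-by-significant cells;
#' the counts always sum to the total variable count. Variables that are
#' univariately significant yet unselected typically lost out numerically —
#' without normalisation a variable's influence scales with its magnitude.
#'
#' @param selected Integer indices of the selected variables.
#' @param screen Data frame from [screen_variables()] over all variables.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `significance_partition`: list of four counts
#'   `n_selected_significant`, `n_selected_nonsignificant`,
#'   `n_unselected_significant`, `n_unselected_nonsignificant`.
#' @export
partition_by_selection <- function(selected, screen, alpha = 0.05) {
  stopifnot(is.data.frame(screen))
  p <- nrow(screen)
  selected <- as.integer(selected)
  if (length(selected) && (min(selected) < 1L || max(selected) > p)) {
    stop("selected indices out of range")
  }
  sel <- seq_len(p) %in% selected
  sig <- screen$p < alpha
  structure(list(n_selected_significant = sum(sel & sig),
                 n_selected_nonsignificant = sum(sel & !sig),
                 n_unselected_significant = sum(!sel & sig),
                 n_unselected_nonsignificant = sum(!sel & !sig)),
            class = "significance_partition")
}

#' @export
print.significance_partition <- function(x, ...) {
  m <- matrix(c(x$n_selected_significant, x$n_selected_nonsignificant,
                x$n_unselected_significant, x$n_unselected_nonsignificant),
              2L, 2L, byrow = TRUE,
              dimnames = list(c("selected", "unselected"),
                              c("significant", "nonsignificant")))
  print(m)
  invisible(x)
}

#' Classify a subject by CD4 slope
#'
#' Ordinary least-squares regression of CD4 count on time; the subject is a
#' "case" (immunological progressor) when the slope is statistically
#' significantly negative (t-test p below `alpha` and slope < 0), and a
#' "control" otherwise — including subjects with significantly increasing
#' counts: the rule is one-sided on the sign.
#'
#' @param traj A [cd4_trajectory()].
#' @param alpha Significance level for the slope t-test (default 0.05).
#' @return An object of class `slope_classification`: list with `slope`
#'   (cells/uL per year), `slope_p`, `category` (`"case"` or `"control"`),
#'   `subject_id`.
#' @export
classify_cd4_slope <- function(traj, alpha = 0.05) {
  stopifnot(inherits(traj, "cd4_trajectory"))
  t <- traj$times; y <- traj$counts
  if (stats::var(t) == 0) stop("degenerate: zero variance in times")
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2L])
  # summary.lm warns on perfect fits; that case is handled explicitly below
  coefs <- suppressWarnings(summary(fit)$coefficients)
  se <- coefs[2L, 2L]
  if (!is.finite(se) || se == 0) {
    # perfect fit: a nonzero slope is unambiguous, a zero slope is flat
    p <- if (slope == 0) 1 else 0
  } else {
    p <- coefs[2L, 4L]
  }
  category <- if (p < alpha && slope < 0) "case" else "control"
  structure(list(slope = slope, slope_p = p, category = category,
                 subject_id = traj$subject_id),
            class = "slope_classification")
}

#' @export
print.slope_classification <- function(x, ...) {
  cat(sprintf("subject %s: slope %.1f cells/uL/yr (p = %.3g) -> %s\n",
              x$subject_id, x$slope, x$slope_p, x$category))
  invisible(x)
}
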
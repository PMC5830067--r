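#' Per-class normal density model of the calculated response
#'
#' Container for the class-modeling layer: a normal distribution per class
#' fitted to the response values calculated by a PLS model, together with the
#' evidence (normality-test p-values) backing the normal assumption.
#' Construct directly from known parameters, or fit from data with
#' [fit_class_densities()].
#'
#' @param mu0,sigma0 Mean and standard deviation of the calculated response
#'   for class 0 (`sigma0 > 0`).
#' @param mu1,sigma1 Same for class 1.
#' @param normality_p0,normality_p1 Optional normality-test p-values.
#' @param n0,n1 Optional per-class sample sizes.
#' @return An object of class `class_density_model`.
#' @export
#' @examples
#' class_density_model(0.075, 0.219, 0.810, 0.146)
class_density_model <- function(mu0, sigma0, mu1, sigma1,
                                normality_p0 = NA_real_, normality_p1 = NA_real_,
                                n0 = NA_integer_, n1 = NA_integer_) {
  stopifnot(is.finite(mu0), is.finite(mu1))
  if (!is.finite(sigma0) || sigma0 <= 0 || !is.finite(sigma1) || sigma1 <= 0) {
    stop("degenerate density: class standard deviations must be positive")
  }
  for (p in c(normality_p0, normality_p1)) {
    if (!is.na(p) && (p < 0 || p > 1)) stop("normality p-values must be in [0, 1]")
  }
  structure(list(mu0 = mu0, sigma0 = sigma0, mu1 = mu1, sigma1 = sigma1,
                 normality_p0 = normality_p0, normality_p1 = normality_p1,
                 n0 = n0, n1 = n1),
            class = "class_density_model")
}

#' @export
print.class_density_model <- function(x, ...) {
  cat(sprintf("class densities: class 0 ~ N(%.3f, %.3f), class 1 ~ N(%.3f, %.3f)\n",
              x$mu0, x$sigma0, x$mu1, x$sigma1))
  if (!is.na(x$normality_p0)) {
    cat(sprintf("  normality p: %.3f (class 0), %.3f (class 1)\n",
                x$normality_p0, x$normality_p1))
  }
  invisible(x)
}

#' Fit per-class normal densities to calculated responses
#'
#' Computes the sample mean and standard deviation (n-1 denominator) of the
#' calculated response within each class and attaches Shapiro-Wilk normality
#' p-values. A p-value at or below `normality_alpha` raises a warning (class
#' `plscm_normality_warning`), not an error: the normal model remains
#' computable and the caller decides whether to trust it.
#'
#' @param y_hat Numeric vector of calculated (predicted) response values.
#' @param labels Binary 0/1 class labels, same length as `y_hat`.
#' @param normality_alpha Warning threshold for the normality p-values
#'   (default 0.10).
#' @return A [class_density_model()].
#' @export
fit_class_densities <- function(y_hat, labels, normality_alpha = 0.10) {
  y_hat <- as.numeric(y_hat)
  labels <- as.integer(labels)
  stopifnot(length(y_hat) == length(labels), all(labels %in% c(0L, 1L)))
  g0 <- y_hat[labels == 0L]; g1 <- y_hat[labels == 1L]
  if (length(g0) < 3L || length(g1) < 3L) {
    stop("each class needs at least 3 samples to fit a density")
  }
  s0 <- stats::sd(g0); s1 <- stats::sd(g1)
  if (s0 == 0 || s1 == 0) {
    stop("degenerate density: a class has zero variance in the calculated response")
  }
  p0 <- stats::shapiro.test(g0)$p.value
  p1 <- stats::shapiro.test(g1)$p.value
  if (p0 <= normality_alpha || p1 <= normality_alpha) {
    warning(warningCondition(
      sprintf("normality test p-value at or below %.2f (class 0: %.3g, class 1: %.3g); the normal class model may be inadequate",
              normality_alpha, p0, p1),
      class = "plscm_normality_warning"))
  }
  class_density_model(mean(g0), s0, mean(g1), s1,
                      normality_p0 = p0, normality_p1 = p1,
                      n0 = length(g0), n1 = length(g1))
}

#' Type I / type II risk curve
#'
#' Sweeps a classification threshold over the calculated-response axis and
#' records, at each threshold t, the probability alpha of rejecting the null
#' hypothesis "the sample belongs to class 0" when it is true, and the
#' probability beta of accepting it when it is false, both under the fitted
#' normal class densities. Orientation follows the class means: when
#' `mu0 < mu1`, alpha is the upper tail of the class-0 density and beta the
#' lower tail of the class-1 density (mirrored otherwise).
#'
#' @param model A [class_density_model()] with `mu0 != mu1`.
#' @param grid_size Number of thresholds (default 512); the grid spans
#'   `[min(mu) - 4 max(sigma), max(mu) + 4 max(sigma)]`.
#' @return A data frame of class `risk_curve` with columns `threshold`,
#'   `alpha`, `beta`.
#' @export
risk_curve <- function(model, grid_size = 512L) {
  stopifnot(inherits(model, "class_density_model"))
  if (model$mu0 == model$mu1) stop("class means are equal; risk curve undefined")
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L) stop("grid_size must be at least 2")
  smax <- max(model$sigma0, model$sigma1)
  lo <- min(model$mu0, model$mu1) - 4 * smax
  hi <- max(model$mu0, model$mu1) + 4 * smax
  t <- seq(lo, hi, length.out = grid_size)
  if (model$mu0 < model$mu1) {
    alpha <- stats::pnorm(t, model$mu0, model$sigma0, lower.tail = FALSE)
    beta <- stats::pnorm(t, model$mu1, model$sigma1)
  } else {
    alpha <- stats::pnorm(t, model$mu0, model$sigma0)
    beta <- stats::pnorm(t, model$mu1, model$sigma1, lower.tail = FALSE)
  }
  structure(data.frame(threshold = t, alpha = alpha, beta = beta),
            class = c("risk_curve", "data.frame"))
}

#' Equal-error operating point
#'
#' The threshold where the type I and type II error probabilities of the
#' normal class model coincide. In closed form this is
#' `t* = (mu0 sigma1 + mu1 sigma0) / (sigma0 + sigma1)`, the point where the
#' standardized distances to the two class means match; there
#' `alpha = beta = Phi(-|mu1 - mu0| / (sigma0 + sigma1))` and sensitivity
#' equals specificity at `(1 - alpha) x 100` percent. Raw probabilities are
#' carried everywhere; integer-percent rounding is provided separately for
#' reporting.
#'
#' @param model A [class_density_model()] with `mu0 != mu1`.
#' @return An object of class `operating_point`: list with `threshold`,
#'   `alpha`, `beta`, `sensitivity`, `specificity` (percent),
#'   `sensitivity_rounded`, `specificity_rounded` (integer percent), and
#'   `orientation` (`"class1_high"` if `mu1 > mu0`, else `"class1_low"`).
#' @export
#' @examples
#' equal_error_point(class_density_model(0.075, 0.219, 0.810, 0.146))
equal_error_point <- function(model) {
  stopifnot(inherits(model, "class_density_model"))
  if (model$mu0 == model$mu1) stop("class means are equal; equal-error point undefined")
  ssum <- model$sigma0 + model$sigma1
  if (ssum <= 0) stop("degenerate: sigma0 + sigma1 must be positive")
  t_star <- (model$mu0 * model$sigma1 + model$mu1 * model$sigma0) / ssum
  z <- abs(model$mu1 - model$mu0) / ssum
  alpha <- stats::pnorm(-z)
  sens <- (1 - alpha) * 100
  structure(list(threshold = t_star,
                 alpha = alpha,
                 beta = alpha,
                 sensitivity = sens,
                 specificity = sens,
                 sensitivity_rounded = as.integer(round(sens)),
                 specificity_rounded = as.integer(round(sens)),
                 orientation = if (model$mu1 > model$mu0) "class1_high" else "class1_low"),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("equal-error point: threshold %.4f, alpha = beta = %.4f\n",
              x$threshold, x$alpha))
  cat(sprintf("  sensitivity = specificity = %.2f%% (%d%%)\n",
              x$sensitivity, x$sensitivity_rounded))
  invisible(x)
}

#' Assign samples at an operating point
#'
#' Classifies each calculated response against the operating-point threshold,
#' orientation-aware: with `mu0 < mu1`, values at or above the threshold go
#' to class 1 (a value exactly at the threshold is assigned to class 1 by
#' convention); mirrored when class 1 lies low. When true labels are
#' supplied, a 2x2 confusion matrix is returned alongside.
#'
#' @param y_hat Numeric vector of calculated responses.
#' @param point An [equal_error_point()] (or any `operating_point`).
#' @param labels Optional true 0/1 labels for a confusion matrix.
#' @param coding Optional [class_coding()] used to name the assignments.
#' @return A list with `assigned` (0/1 vector), `assigned_label` (character,
#'   if `coding` given), and `confusion` (table, if `labels` given).
#' @export
assign_samples <- function(y_hat, point, labels = NULL, coding = NULL) {
  stopifnot(inherits(point, "operating_point"))
  y_hat <- as.numeric(y_hat)
  assigned <- if (point$orientation == "class1_high") {
    as.integer(y_hat >= point$threshold)
  } else {
    as.integer(y_hat <= point$threshold)
  }
  out <- list(assigned = assigned)
  if (!is.null(coding)) {
    stopifnot(inherits(coding, "class_coding"))
    out$assigned_label <- ifelse(assigned == 1L, coding$label_for_one,
                                 coding$label_for_zero)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    out$confusion <- table(truth = factor(labels, levels = 0:1),
                           assigned = factor(assigned, levels = 0:1))
    out$accuracy <- mean(assigned == labels)
  }
  out
}
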
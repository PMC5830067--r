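#' Fit a univariate-response PLS model by NIPALS
#'
#' Partial least squares regression of a single response on a
#' subjects-by-variables matrix, computed by the NIPALS algorithm with
#' sequential deflation of both blocks. By default no preprocessing is
#' applied: the data are neither centered nor scaled, so all sums of squares
#' are taken about the origin and the first latent variable (LV) tracks the
#' distance between the vector of variable means and the origin of
#' coordinates. This is the appropriate setting when all variables share one
#' scale (percentages) and normalisation would inflate noise variables to the
#' magnitude of the discriminative ones. Centering remains available via
#' `center = TRUE` for comparison with conventional PLS software.
#'
#' Each component's weight vector is initialised from the cross-product of
#' the current X residual with the current y residual, normalised to unit
#' length; X and y are deflated after each component. For a univariate
#' response the inner loop converges in a single pass; the iteration and
#' tolerance are retained for safety. The sign of each component is fixed so
#' that its largest-magnitude weight entry is positive, which resolves the
#' NIPALS sign indeterminacy and makes fits bitwise reproducible.
#'
#' @param X Numeric matrix (subjects x variables) or a [phenotype_matrix()].
#' @param y Numeric response vector; for class modeling a 0/1 class code.
#' @param A Number of latent variables, `1 <= A <= min(n, p)`.
#' @param center Logical; center columns of X and y before fitting
#'   (default `FALSE`).
#' @param tol Convergence tolerance on the change of the weight vector.
#' @param max_iter Maximum NIPALS iterations per component.
#' @return An object of class `pls_model` with fields `weights` (p x A, unit
#'   columns), `x_scores` (n x A), `x_loadings` (p x A), `y_loadings`
#'   (length A), `coefficients` (length p, mapping raw X to predicted y),
#'   `intercept`, `centering_enabled`, `column_means`, `y_mean`,
#'   `variance_ledger` (see [explained_variance()]), `n_components`,
#'   `variable_names`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(runif(40, 10, 30), 8, 5)
#' y <- rep(c(0, 1), each = 4)
#' m <- fit_pls(X, y, A = 2)
#' m$variance_ledger
fit_pls <- function(X, y, A, center = FALSE, tol = 1e-12, max_iter = 500L) {
  if (inherits(X, "phenotype_matrix")) X <- X$values
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length of y must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  A <- as.integer(A)
  if (A < 1L || A > min(n, p)) stop("A must satisfy 1 <= A <= min(n, p) = ", min(n, p))
  if (stats::var(y) == 0) stop("y is constant; both classes must be present")
  if (!center) {
    zero_col <- which(colSums(X^2) == 0)
    if (length(zero_col)) {
      stop("degenerate direction: column(s) with zero norm under center = FALSE: ",
           paste(utils::head(zero_col, 5L), collapse = ", "))
    }
  }
  column_means <- if (center) colMeans(X) else rep(0, p)
  y_mean <- if (center) mean(y) else 0
  E <- sweep(X, 2L, column_means)
  f <- y - y_mean
  ssx_total <- sum(E^2)
  ssy_total <- sum(f^2)
  if (ssx_total == 0 || ssy_total == 0) stop("zero total sum of squares; variance undefined")

  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  ssx_part <- ssy_part <- numeric(A)

  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      stop("degenerate direction: zero weight vector at component ", a)
    }
    w <- w / nw
    iter <- 0L
    repeat {
      iter <- iter + 1L
      t_a <- drop(E %*% w)
      tt <- sum(t_a^2)
      if (tt < .Machine$double.eps) {
        stop("degenerate direction: zero score vector at component ", a)
      }
      # univariate y: u = f, so the updated weight is E'f regardless of t
      w_new <- drop(crossprod(E, f))
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new
      if (delta < tol) break
      if (iter >= max_iter) {
        stop("component ", a, " did not converge within ", max_iter, " iterations")
      }
    }
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(t_a * f) / tt
    # sign convention: largest-|weight| entry positive
    if (w[which.max(abs(w))] < 0) {
      w <- -w; t_a <- -t_a; p_a <- -p_a; q_a <- -q_a
    }
    E <- E - tcrossprod(t_a, p_a)
    f <- f - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    ssx_part[a] <- 100 * tt * sum(p_a^2) / ssx_total
    ssy_part[a] <- 100 * q_a^2 * tt / ssy_total
  }

  coefficients <- drop(W %*% solve(crossprod(P, W), q))
  intercept <- y_mean - sum(column_means * coefficients)
  ledger <- variance_ledger(ssx_part, ssy_part)
  vn <- colnames(X)
  if (is.null(vn)) vn <- paste0("V", seq_len(p))
  structure(list(n_components = A,
                 weights = W,
                 x_scores = Tm,
                 x_loadings = P,
                 y_loadings = q,
                 coefficients = stats::setNames(coefficients, vn),
                 intercept = intercept,
                 centering_enabled = center,
                 column_means = column_means,
                 y_mean = y_mean,
                 variance_ledger = ledger,
                 ssx_total = ssx_total,
                 ssy_total = ssy_total,
                 variable_names = vn,
                 n_subjects = n),
            class = "pls_model")
}

# build the per-LV explained-variance table from partial percentages
variance_ledger <- function(x_partial, y_partial) {
  stopifnot(length(x_partial) == length(y_partial))
  data.frame(component = seq_along(x_partial),
             x_partial = x_partial,
             x_total = cumsum(x_partial),
             y_partial = y_partial,
             y_total = cumsum(y_partial))
}

#' @export
print.pls_model <- function(x, ...) {
  led <- x$variance_ledger
  cat("PLS model:", x$n_components, "latent variable(s),",
      length(x$coefficients), "variables,",
      if (x$centering_enabled) "centered" else "uncentered (about the origin)", "\n")
  cat(sprintf("  X explained: %.1f%%   y explained: %.1f%%\n",
              led$x_total[nrow(led)], led$y_total[nrow(led)]))
  invisible(x)
}

#' Predict the response for new samples
#'
#' Applies the composite regression vector of a fitted PLS model (plus
#' intercept when centering was enabled). In-sample predictions are the
#' "calculated response" values handed to the class-modeling layer.
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix (or [phenotype_matrix()]) with the same
#'   number of columns the model was fitted on. A bare vector is taken as a
#'   single sample.
#' @param ... Unused.
#' @return Numeric vector of predicted response values.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "phenotype_matrix")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " columns but the model expects ",
         length(object$coefficients))
  }
  drop(newdata %*% object$coefficients) + object$intercept
}

#' Per-LV explained variance of the X and y blocks
#'
#' Returns the variance ledger of a fitted model: for each latent variable
#' the individual (partial) and accumulated (total) percentage of the X-block
#' and y-block sum of squares it explains. Under `center = FALSE` the sums of
#' squares are taken about the origin, under `center = TRUE` about the mean;
#' partials always sum to totals and totals are non-decreasing.
#'
#' @param model A fitted `pls_model`.
#' @return A data frame with columns `component`, `x_partial`, `x_total`,
#'   `y_partial`, `y_total` (percentages).
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  model$variance_ledger
}

#' Knee rule on per-LV response variance
#'
#' Keeps latent variables while their marginal contribution to the explained
#' response variance is at least `knee_points` percentage points; the chosen
#' dimension is the last component meeting that bar (at least 1).
#'
#' @param y_partial Numeric vector of per-LV y-block partial percentages.
#' @param knee_points Marginal-contribution cutoff in percentage points.
#' @return The chosen number of components.
#' @export
#' @examples
#' knee_components(c(38.1, 26.2, 16.9, 3.4))  # 3
knee_components <- function(y_partial, knee_points = 5) {
  stopifnot(length(y_partial) >= 1L, knee_points > 0)
  keep <- which(y_partial >= knee_points)
  if (length(keep) == 0L) 1L else max(keep)
}

#' Choose the number of latent variables
#'
#' Optimises the PLS dimension either by the knee rule on the per-LV
#' explained response variance (smallest model whose later components each
#' add less than `knee_points` percentage points) or by leave-one-out
#' cross-validated squared prediction error.
#'
#' @param X Numeric matrix or [phenotype_matrix()].
#' @param y Response vector.
#' @param A_max Largest dimension to consider, `A_max <= min(n, p)`.
#' @param criterion `"explained_variance_knee"` (default) or `"loo_cv"`.
#' @param center Passed to [fit_pls()].
#' @param knee_points Cutoff for the knee rule, in percentage points.
#' @return The chosen number of components (integer).
#' @export
select_n_components <- function(X, y, A_max,
                                criterion = c("explained_variance_knee", "loo_cv"),
                                center = FALSE, knee_points = 5) {
  criterion <- match.arg(criterion)
  if (inherits(X, "phenotype_matrix")) X <- X$values
  A_max <- as.integer(A_max)
  if (A_max < 1L) stop("A_max must be at least 1")
  A_max <- min(A_max, nrow(X) - as.integer(criterion == "loo_cv"), ncol(X))
  if (criterion == "explained_variance_knee") {
    m <- fit_pls_up_to(X, y, A_max, center = center)
    knee_components(m$variance_ledger$y_partial, knee_points)
  } else {
    n <- nrow(X)
    A_max <- min(A_max, fit_pls_up_to(X, y, A_max, center = center)$n_components)
    press <- numeric(A_max)
    for (i in seq_len(n)) {
      m <- fit_pls_up_to(X[-i, , drop = FALSE], y[-i], A_max, center = center)
      for (a in seq_len(A_max)) {
        aa <- min(a, m$n_components)
        b_a <- drop(m$weights[, 1:aa, drop = FALSE] %*%
                      solve(crossprod(m$x_loadings[, 1:aa, drop = FALSE],
                                      m$weights[, 1:aa, drop = FALSE]),
                            m$y_loadings[1:aa]))
        icpt <- m$y_mean - sum(m$column_means * b_a)
        press[a] <- press[a] + (y[i] - (sum(X[i, ] * b_a) + icpt))^2
      }
    }
    which.min(press)
  }
}

# fit with as many components as the data's effective rank allows, up to A:
# retries with a smaller dimension when a residual block degenerates to zero
fit_pls_up_to <- function(X, y, A, center = FALSE) {
  repeat {
    m <- tryCatch(fit_pls(X, y, A, center = center), error = identity)
    if (!inherits(m, "error")) return(m)
    degenerate <- grepl("degenerate direction: zero (weight|score) vector",
                        conditionMessage(m))
    if (A > 1L && degenerate) A <- A - 1L else stop(m)
  }
}
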
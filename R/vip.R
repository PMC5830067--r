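#' Variable influence on projection (VIP)
#'
#' The per-variable importance score of a fitted PLS model, aggregating each
#' variable's squared weight across components, with each component weighted
#' by the amount of response variance it explains:
#' \deqn{VIP_j = \sqrt{ p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a }}
#' where the weight vectors are unit length, \eqn{SSY_a} is the y-block sum
#' of squares captured by component \eqn{a} and \eqn{p} the number of
#' variables. By construction the mean squared VIP equals 1 (so
#' \eqn{\sum_j VIP_j^2 = p}); a score above 1 marks an above-average
#' contributor.
#'
#' @param model A fitted `pls_model` (see [fit_pls()]).
#' @return An object of class `vip_scores`: list with `scores` (named
#'   numeric, one per variable) and `n_components_used`.
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$variance_ledger$y_partial            # proportional to SSY_a
  if (sum(ssy) <= 0) stop("undefined VIP: no response variance explained by any component")
  W2 <- model$weights^2                             # columns already unit norm
  p <- nrow(W2)
  scores <- sqrt(p * drop(W2 %*% ssy) / sum(ssy))
  structure(list(scores = stats::setNames(scores, model$variable_names),
                 n_components_used = model$n_components),
            class = "vip_scores")
}

#' @export
print.vip_scores <- function(x, ...) {
  cat("VIP scores for", length(x$scores), "variables (",
      x$n_components_used, "components );",
      sum(x$scores > 1), "above 1\n")
  invisible(x)
}

#' Select variables by VIP threshold
#'
#' Keeps the variables whose VIP is strictly greater than the threshold
#' ("higher than" semantics: a score exactly at the threshold is excluded).
#' Original column order is preserved. An empty selection is allowed here and
#' flagged downstream by [two_stage_fit()].
#'
#' @param vip A `vip_scores` object from [compute_vip()].
#' @param threshold Positive cutoff, default 1.
#' @return Integer vector of selected column indices, in original order.
#' @export
#' @examples
#' v <- structure(list(scores = c(a = 1.4, b = 0.2, c = 1.0),
#'                     n_components_used = 1L), class = "vip_scores")
#' select_variables(v, 1)  # only the first
select_variables <- function(vip, threshold = 1) {
  stopifnot(inherits(vip, "vip_scores"))
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be positive")
  which(unname(vip$scores) > threshold)
}

#' Two-stage PLS fit with VIP-based variable selection
#'
#' The fit-select-refit workflow: a first PLS model on the full matrix, VIP
#' scores, selection of variables with VIP above the threshold, then a second
#' PLS model restricted to the selected columns. Both models are retained;
#' downstream class modeling uses the stage-2 model's calculated responses.
#'
#' @param X Numeric matrix or [phenotype_matrix()].
#' @param y Binary 0/1 response vector.
#' @param A_stage1 Components for the full-matrix model.
#' @param A_stage2 Components for the reduced model (default: same as
#'   stage 1); capped at the number of selected variables.
#' @param threshold VIP cutoff (strictly greater than), default 1.
#' @param center Passed to [fit_pls()]; default `FALSE` (no preprocessing).
#' @return An object of class `selection_result`: list with
#'   `selected_indices`, `selected_names`, `threshold`, `vip`,
#'   `stage1_model`, `stage2_model`.
#' @export
two_stage_fit <- function(X, y, A_stage1, A_stage2 = A_stage1,
                          threshold = 1, center = FALSE) {
  if (inherits(X, "phenotype_matrix")) X <- X$values
  X <- as.matrix(X)
  stage1 <- fit_pls(X, y, A_stage1, center = center)
  vip <- compute_vip(stage1)
  sel <- select_variables(vip, threshold)
  if (length(sel) == 0L) {
    stop("VIP selection is empty at threshold ", threshold,
         "; lower the threshold or inspect the stage-1 model")
  }
  A2 <- min(as.integer(A_stage2), length(sel), nrow(X))
  stage2 <- fit_pls(X[, sel, drop = FALSE], y, A2, center = center)
  structure(list(selected_indices = sel,
                 selected_names = names(vip$scores)[sel],
                 threshold = threshold,
                 vip = vip,
                 stage1_model = stage1,
                 stage2_model = stage2),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("two-stage PLS: ", length(x$vip$scores), " variables -> ",
      length(x$selected_indices), " selected (VIP > ", x$threshold, ")\n", sep = "")
  print(x$stage2_model)
  invisible(x)
}
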
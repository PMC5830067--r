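#' Rotate a two-component score projection
#'
#' Projects the scores of a chosen pair of latent variables onto a plane and
#' applies a counterclockwise rotation, as used to display class separation
#' along a single rotated coordinate. Rotation is an isometry: each row's
#' Euclidean norm is preserved.
#'
#' @param T Score matrix (subjects x components), e.g. `model$x_scores`.
#' @param pair Length-2 integer vector of component indices `(a, b)`,
#'   `a != b`.
#' @param angle_deg Counterclockwise rotation angle in degrees.
#' @return An object of class `score_projection`: list with
#'   `component_pair`, `angle_deg`, `rotated_scores` (n x 2),
#'   `separating_value` (NA here), `perfectly_separated` (NA here).
#' @export
#' @examples
#' T <- cbind(1:4, c(0, 1, 0, 1))
#' rotate_scores(T, c(1, 2), 90)
rotate_scores <- function(T, pair, angle_deg) {
  T <- as.matrix(T)
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1L] == pair[2L] ||
      any(pair < 1L) || any(pair > ncol(T))) {
    stop("pair must be two distinct component indices within the score matrix")
  }
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  S <- T[, pair, drop = FALSE] %*% t(R)
  colnames(S) <- c("rotated_x", "rotated_y")
  structure(list(component_pair = pair,
                 angle_deg = angle_deg,
                 rotated_scores = S,
                 separating_value = NA_real_,
                 perfectly_separated = NA),
            class = "score_projection")
}

#' Search for a separating rotation of a score plane
#'
#' Grid search over rotation angles in `[0, 180)` degrees for a vertical
#' line (a value of the rotated first coordinate) separating the two classes.
#' Among angles achieving separation the one maximizing the margin (the gap
#' between the class extremes on the rotated first coordinate) is returned;
#' if no angle separates, the max-margin angle is returned with
#' `perfectly_separated = FALSE`. The separating value is the midpoint of the
#' gap. A half-turn suffices because a vertical separator is invariant under
#' 180-degree rotation with the sides swapped.
#'
#' @param T Score matrix (subjects x components).
#' @param labels Binary 0/1 class labels.
#' @param pair Component indices to project, default `c(2, 3)`.
#' @param step_deg Grid step in degrees, default 0.5.
#' @return A `score_projection` with `separating_value`,
#'   `perfectly_separated` and `margin` filled in.
#' @export
find_separating_rotation <- function(T, labels, pair = c(2L, 3L), step_deg = 0.5) {
  T <- as.matrix(T)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(T), all(labels %in% c(0L, 1L)),
            any(labels == 0L), any(labels == 1L), step_deg > 0)
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1L] == pair[2L] ||
      any(pair < 1L) || any(pair > ncol(T))) {
    stop("pair must be two distinct component indices within the score matrix")
  }
  S <- T[, pair, drop = FALSE]
  angles <- seq(0, 180 - step_deg, by = step_deg)
  best <- list(margin = -Inf, angle = 0, value = NA_real_)
  for (ang in angles) {
    th <- ang * pi / 180
    x <- S[, 1L] * cos(th) - S[, 2L] * sin(th)   # rotated first coordinate
    x0 <- x[labels == 0L]; x1 <- x[labels == 1L]
    m_right <- min(x1) - max(x0)                  # class 0 left, class 1 right
    m_left <- min(x0) - max(x1)                   # mirrored
    if (m_right >= m_left) {
      margin <- m_right; value <- (max(x0) + min(x1)) / 2
    } else {
      margin <- m_left; value <- (max(x1) + min(x0)) / 2
    }
    if (margin > best$margin) best <- list(margin = margin, angle = ang, value = value)
  }
  proj <- rotate_scores(T, pair, best$angle)
  proj$separating_value <- best$value
  proj$perfectly_separated <- best$margin > 0
  proj$margin <- best$margin
  proj
}

#' @export
print.score_projection <- function(x, ...) {
  cat(sprintf("score projection of LV%d/LV%d rotated %.1f deg\n",
              x$component_pair[1L], x$component_pair[2L], x$angle_deg))
  if (!is.na(x$perfectly_separated)) {
    cat(if (isTRUE(x$perfectly_separated)) "  perfectly separated" else "  not separated",
        sprintf("(separating value %.4f, margin %.4f)\n", x$separating_value,
                if (is.null(x$margin)) NA_real_ else x$margin))
  }
  invisible(x)
}
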
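#' Run the full PLS class-modeling pipeline
#'
#' Orchestrates, in fixed order: stage-1 PLS fit on the full matrix, VIP
#' selection, stage-2 fit on the selected variables, per-class normal
#' density modeling of the calculated responses, the alpha/beta risk curve,
#' the equal-error operating point, sample assignment, the separating
#' rotation of a two-LV score plane, the univariate Mann-Whitney screen, the
#' selection-by-significance partition, and the importance-vs-p association.
#' No preprocessing is applied to the data (uncentered PLS), matching the
#' intended use on same-scale percentage variables.
#'
#' The paper-faithful class model is fitted on in-sample calculated
#' responses. With `validation = "loo"` the pipeline additionally re-runs
#' the entire two-stage fit once per held-out subject and models the
#' cross-validated responses, giving an honest (non-optimistic) operating
#' point — recommended when the pipeline is used to judge whether signal is
#' present at all.
#'
#' @param pheno A [phenotype_matrix()].
#' @param A_stage1,A_stage2 Latent-variable counts, or `"auto"` to choose by
#'   the knee rule (see [select_n_components()]). Stage 2 `"auto"` re-applies
#'   the rule on the reduced matrix.
#' @param vip_threshold VIP selection cutoff (default 1).
#' @param alpha_significance Raw significance level of the screen (0.05).
#' @param normality_alpha Warning threshold for normality tests (0.10).
#' @param projection_pair LV indices for the score projection (default 2, 3;
#'   falls back to the first two components if the model is smaller).
#' @param grid_size Risk-curve grid size (default 512).
#' @param step_deg Rotation-search step in degrees (default 0.5).
#' @param knee_points Knee-rule cutoff in percentage points (default 5).
#' @param A_max Largest dimension considered by `"auto"` (default 8).
#' @param validation `"none"` (default) or `"loo"`.
#' @param out_dir Optional directory; when given, [write_report()] is called
#'   and the manifest attached.
#' @param verbose Log per-stage progress and timings to stderr.
#' @return An object of class `plscm_run`; a list with elements `selection`
#'   (see [two_stage_fit()]), `y_hat`, `densities`, `risk`, `operating_point`,
#'   `assignment`, `projection`, `screen`, `partition`, `association`,
#'   `validated` (list with `y_hat`, `densities`, `operating_point`, or NULL),
#'   `config` (the resolved settings), `timings`, and `manifest` (if written).
#' @export
run_plscm <- function(pheno,
                      A_stage1 = "auto", A_stage2 = "auto",
                      vip_threshold = 1,
                      alpha_significance = 0.05,
                      normality_alpha = 0.10,
                      projection_pair = c(2L, 3L),
                      grid_size = 512L,
                      step_deg = 0.5,
                      knee_points = 5,
                      A_max = 8L,
                      validation = c("none", "loo"),
                      out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(pheno, "phenotype_matrix"))
  validation <- match.arg(validation)
  stopifnot(vip_threshold > 0, alpha_significance > 0, normality_alpha > 0)
  X <- pheno$values
  y <- pheno$class_labels
  log_stage <- function(...) if (verbose) message("[plscm] ", ...)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  A1 <- if (identical(A_stage1, "auto")) {
    select_n_components(X, y, min(A_max, nrow(X), ncol(X)),
                        criterion = "explained_variance_knee",
                        knee_points = knee_points)
  } else as.integer(A_stage1)
  log_stage("stage-1 components: ", A1)

  selection <- two_stage_fit(X, y, A_stage1 = A1, A_stage2 = A1,
                             threshold = vip_threshold)
  if (identical(A_stage2, "auto")) {
    Xsel <- X[, selection$selected_indices, drop = FALSE]
    A2 <- select_n_components(Xsel, y, min(A_max, nrow(X), ncol(Xsel)),
                              criterion = "explained_variance_knee",
                              knee_points = knee_points)
    if (A2 != selection$stage2_model$n_components) {
      selection$stage2_model <- fit_pls(Xsel, y, A2)
    }
  } else {
    A2 <- min(as.integer(A_stage2), length(selection$selected_indices))
    if (A2 != selection$stage2_model$n_components) {
      selection$stage2_model <- fit_pls(X[, selection$selected_indices, drop = FALSE], y, A2)
    }
  }
  timings["fit"] <- tic() - t0
  log_stage(length(selection$selected_indices), " variables selected; stage-2 components: ",
            selection$stage2_model$n_components)

  t0 <- tic()
  y_hat <- predict(selection$stage2_model, X[, selection$selected_indices, drop = FALSE])
  densities <- fit_class_densities(y_hat, y, normality_alpha = normality_alpha)
  risk <- risk_curve(densities, grid_size = grid_size)
  op <- equal_error_point(densities)
  assignment <- assign_samples(y_hat, op, labels = y, coding = pheno$coding)
  timings["class_model"] <- tic() - t0
  log_stage(sprintf("equal-error sensitivity = specificity = %.1f%%", op$sensitivity))

  t0 <- tic()
  Tm <- selection$stage2_model$x_scores
  pair <- as.integer(projection_pair)
  if (max(pair) > ncol(Tm)) {
    pair <- if (ncol(Tm) >= 2L) c(1L, 2L) else NULL
  }
  projection <- if (!is.null(pair)) {
    find_separating_rotation(Tm, y, pair = pair, step_deg = step_deg)
  } else NULL
  timings["projection"] <- tic() - t0

  t0 <- tic()
  screen <- screen_variables(pheno, alpha = alpha_significance)
  partition <- partition_by_selection(selection$selected_indices, screen,
                                      alpha = alpha_significance)
  association <- tryCatch(
    loading_pvalue_association(selection$stage2_model,
                               screen[selection$selected_indices, , drop = FALSE]),
    error = function(e) list(rho = NA_real_, p_value = NA_real_,
                             error = conditionMessage(e)))
  timings["univariate"] <- tic() - t0

  validated <- NULL
  if (validation == "loo") {
    t0 <- tic()
    vy <- loo_responses(X, y, A1 = A1,
                        A_stage1_auto = identical(A_stage1, "auto"),
                        A2 = selection$stage2_model$n_components,
                        A_stage2_auto = identical(A_stage2, "auto"),
                        vip_threshold = vip_threshold,
                        knee_points = knee_points, A_max = A_max)
    vdens <- fit_class_densities(vy, y, normality_alpha = normality_alpha)
    validated <- list(y_hat = vy,
                      densities = vdens,
                      operating_point = equal_error_point(vdens))
    timings["loo_validation"] <- tic() - t0
    log_stage(sprintf("LOO-validated sensitivity = %.1f%%",
                      validated$operating_point$sensitivity))
  }

  run <- structure(list(selection = selection,
                        y_hat = y_hat,
                        densities = densities,
                        risk = risk,
                        operating_point = op,
                        assignment = assignment,
                        projection = projection,
                        screen = screen,
                        partition = partition,
                        association = association,
                        validated = validated,
                        subject_ids = pheno$subject_ids,
                        class_labels = y,
                        coding = pheno$coding,
                        config = list(A_stage1 = A1,
                                      A_stage2 = selection$stage2_model$n_components,
                                      vip_threshold = vip_threshold,
                                      alpha_significance = alpha_significance,
                                      normality_alpha = normality_alpha,
                                      projection_pair = pair,
                                      grid_size = as.integer(grid_size),
                                      step_deg = step_deg,
                                      validation = validation),
                        timings = timings),
                   class = "plscm_run")
  if (!is.null(out_dir)) run$manifest <- write_report(run, out_dir)
  run
}

# leave-one-out calculated responses for the whole two-stage pipeline;
# selection and (if auto) dimension choice are repeated inside each fold
loo_responses <- function(X, y, A1, A_stage1_auto, A2, A_stage2_auto,
                          vip_threshold, knee_points, A_max) {
  n <- nrow(X)
  y_hat <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    a1 <- if (A_stage1_auto) {
      select_n_components(Xi, yi, min(A_max, nrow(Xi), ncol(Xi)),
                          criterion = "explained_variance_knee",
                          knee_points = knee_points)
    } else A1
    sel <- two_stage_fit(Xi, yi, A_stage1 = a1, A_stage2 = a1,
                         threshold = vip_threshold)
    if (A_stage2_auto) {
      Xs <- Xi[, sel$selected_indices, drop = FALSE]
      a2 <- select_n_components(Xs, yi, min(A_max, nrow(Xs), ncol(Xs)),
                                criterion = "explained_variance_knee",
                                knee_points = knee_points)
      if (a2 != sel$stage2_model$n_components) {
        sel$stage2_model <- fit_pls(Xs, yi, a2)
      }
    } else {
      a2 <- min(A2, length(sel$selected_indices))
      if (a2 != sel$stage2_model$n_components) {
        sel$stage2_model <- fit_pls(Xi[, sel$selected_indices, drop = FALSE], yi, a2)
      }
    }
    y_hat[i] <- predict(sel$stage2_model, X[i, sel$selected_indices, drop = FALSE])
  }
  y_hat
}

#' @export
print.plscm_run <- function(x, ...) {
  cat("PLS class-modeling run\n")
  cat("  variables: ", length(x$selection$vip$scores), " -> ",
      length(x$selection$selected_indices), " selected (VIP > ",
      x$selection$threshold, ")\n", sep = "")
  cat("  components: stage 1 = ", x$config$A_stage1,
      ", stage 2 = ", x$config$A_stage2, "\n", sep = "")
  print(x$densities)
  print(x$operating_point)
  if (!is.null(x$validated)) {
    cat(sprintf("  LOO-validated sensitivity = specificity = %.1f%%\n",
                x$validated$operating_point$sensitivity))
  }
  if (!is.null(x$projection)) {
    cat(sprintf("  projection LV%d/LV%d at %.1f deg: %s\n",
                x$projection$component_pair[1L], x$projection$component_pair[2L],
                x$projection$angle_deg,
                if (isTRUE(x$projection$perfectly_separated)) "perfectly separated"
                else "not separated"))
  }
  print(x$partition)
  invisible(x)
}

#' Simulate a cohort and run the pipeline on it
#'
#' Generates a synthetic cohort from `config`, runs [run_plscm()] on it, and
#' joins the generator's ground truth into the result: recall and precision
#' of the VIP selection against the planted informative set. Because the
#' question a simulation answers is "does the pipeline find the planted
#' signal, and does it report none when there is none", the default here is
#' `validation = "loo"`, so the reported recovery operating point comes from
#' cross-validated responses rather than the optimistic in-sample fit.
#'
#' @param config A [cohort_config()].
#' @param ... Passed to [run_plscm()].
#' @param validation As in [run_plscm()]; default `"loo"`.
#' @return A `plscm_run` with an extra element `truth_metrics`: list with
#'   `recall`, `precision`, `n_informative`, `n_selected`, plus `truth` and
#'   `clip_fraction` from the generator.
#' @export
simulate_plscm <- function(config, ..., validation = "loo") {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- generate_cohort(config)
  run <- run_plscm(cohort$phenotype, validation = validation, ...)
  planted <- cohort$truth$informative_indices
  sel <- run$selection$selected_indices
  run$truth <- cohort$truth
  run$clip_fraction <- cohort$clip_fraction
  run$truth_metrics <- list(
    recall = if (length(planted)) mean(planted %in% sel) else NA_real_,
    precision = if (length(sel)) mean(sel %in% planted) else NA_real_,
    n_informative = length(planted),
    n_selected = length(sel))
  run
}

#' Write the report files of a run
#'
#' Serialises whatever parts of a (possibly partial) run are present:
#' per-LV variance table in the partial/total x X/y layout
#' (`variance_table.csv`), selected-variable table
#' (`selected_variables.csv`), class-density parameters
#' (`class_densities.csv`), risk curve (`risk_curve.csv`), operating point
#' (`operating_point.json`), univariate screen (`screen.csv`), score
#' projection (`projection.csv`) and a machine-readable run summary
#' (`run_summary.json`).
#'
#' @param run A `plscm_run`, or any list carrying a subset of its fields.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths (the manifest), invisibly
#'   sorted in write order.
#' @export
write_report <- function(run, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L) stop("cannot write to directory: ", dir)
  manifest <- character(0)
  emit <- function(name) {
    path <- file.path(dir, name)
    manifest <<- c(manifest, path)
    path
  }

  ledgers <- list()
  if (!is.null(run$selection)) {
    ledgers <- list(stage1 = run$selection$stage1_model$variance_ledger,
                    stage2 = run$selection$stage2_model$variance_ledger)
  } else if (inherits(run$model, "pls_model")) {
    ledgers <- list(model = run$model$variance_ledger)
  } else if (!is.null(run$variance_ledger)) {
    ledgers <- list(model = run$variance_ledger)
  }
  if (length(ledgers)) {
    tab <- do.call(rbind, lapply(names(ledgers), function(nm) {
      led <- ledgers[[nm]]
      data.frame(model = nm, latent_variable = led$component,
                 x_partial = led$x_partial, x_total = led$x_total,
                 y_partial = led$y_partial, y_total = led$y_total)
    }))
    utils::write.csv(tab, emit("variance_table.csv"), row.names = FALSE)
  }

  if (!is.null(run$selection)) {
    vip <- run$selection$vip
    tab <- data.frame(variable_name = names(vip$scores),
                      vip_score = unname(vip$scores),
                      selected = seq_along(vip$scores) %in% run$selection$selected_indices)
    utils::write.csv(tab, emit("selected_variables.csv"), row.names = FALSE)
  }

  if (!is.null(run$densities)) {
    d <- run$densities
    tab <- data.frame(class = c(0L, 1L), mean = c(d$mu0, d$mu1),
                      sd = c(d$sigma0, d$sigma1),
                      normality_p = c(d$normality_p0, d$normality_p1),
                      n = c(d$n0, d$n1))
    utils::write.csv(tab, emit("class_densities.csv"), row.names = FALSE)
  }

  if (!is.null(run$risk)) {
    utils::write.csv(run$risk, emit("risk_curve.csv"), row.names = FALSE)
  }

  if (!is.null(run$operating_point)) {
    op <- run$operating_point
    jsonlite::write_json(list(threshold = op$threshold, alpha = op$alpha,
                              beta = op$beta, sensitivity = op$sensitivity,
                              specificity = op$specificity,
                              sensitivity_rounded = op$sensitivity_rounded,
                              specificity_rounded = op$specificity_rounded,
                              orientation = op$orientation),
                         emit("operating_point.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (!is.null(run$screen)) {
    tab <- run$screen
    if (!is.null(run$selection)) {
      tab$selected <- seq_len(nrow(tab)) %in% run$selection$selected_indices
    }
    utils::write.csv(tab, emit("screen.csv"), row.names = FALSE)
  }

  if (!is.null(run$projection)) {
    pr <- run$projection
    tab <- data.frame(subject_id = if (!is.null(run$subject_ids)) run$subject_ids
                      else seq_len(nrow(pr$rotated_scores)),
                      rotated_x = pr$rotated_scores[, 1L],
                      rotated_y = pr$rotated_scores[, 2L],
                      class = if (!is.null(run$class_labels)) run$class_labels else NA)
    utils::write.csv(tab, emit("projection.csv"), row.names = FALSE)
  }

  summary <- list(config = run$config,
                  n_selected = if (!is.null(run$selection)) length(run$selection$selected_indices) else NULL,
                  partition = if (!is.null(run$partition)) unclass(run$partition) else NULL,
                  association = if (!is.null(run$association)) run$association[c("rho", "p_value")] else NULL,
                  projection = if (!is.null(run$projection)) {
                    list(angle_deg = run$projection$angle_deg,
                         separating_value = run$projection$separating_value,
                         perfectly_separated = run$projection$perfectly_separated,
                         margin = run$projection$margin)
                  } else NULL,
                  validated_operating_point = if (!is.null(run$validated)) {
                    vo <- run$validated$operating_point
                    list(threshold = vo$threshold, sensitivity = vo$sensitivity)
                  } else NULL,
                  truth_metrics = run$truth_metrics,
                  files = basename(manifest))
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       emit("run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
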
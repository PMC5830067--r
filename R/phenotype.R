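#' Class coding legend
#'
#' Records which group is coded 0 and which is coded 1 in the binary response
#' of a PLS class model, so the same matrix can serve different contrasts
#' (e.g. patients vs healthy controls, or cases vs controls within patients)
#' without relabelling columns.
#'
#' @param label_for_zero Label of the group coded 0.
#' @param label_for_one Label of the group coded 1.
#' @return An object of class `class_coding`.
#' @export
#' @examples
#' class_coding("EC", "HC")
class_coding <- function(label_for_zero, label_for_one) {
  stopifnot(is.character(label_for_zero), length(label_for_zero) == 1L,
            is.character(label_for_one), length(label_for_one) == 1L)
  if (identical(label_for_zero, label_for_one)) {
    stop("the two class labels must differ")
  }
  structure(list(label_for_zero = label_for_zero,
                 label_for_one = label_for_one),
            class = "class_coding")
}

#' Subjects-by-variables percentage matrix with class labels
#'
#' The core container of the pipeline: a numeric matrix of immunophenotype
#' subset frequencies (percentages in \[0, 100\]), one row per subject, plus a
#' binary class label per subject. All values are validated on construction;
#' out-of-range or non-finite entries are treated as data corruption and
#' rejected with the offending cell named.
#'
#' @param values Numeric matrix, subjects x variables, values in \[0, 100\].
#' @param subject_ids Character vector of unique subject identifiers.
#' @param variable_names Character vector of unique variable (subset) labels.
#' @param class_labels Integer vector of 0/1 class codes, one per subject;
#'   both classes must be present.
#' @param coding Optional [class_coding()] legend for the 0/1 codes.
#' @return An object of class `phenotype_matrix` with fields `values`,
#'   `subject_ids`, `variable_names`, `class_labels`, `coding`.
#' @export
#' @examples
#' x <- phenotype_matrix(matrix(c(10, 20, 30, 40), 2, 2),
#'                       c("s1", "s2"), c("v1", "v2"), c(0, 1))
#' dim(x$values)
phenotype_matrix <- function(values, subject_ids, variable_names, class_labels,
                             coding = class_coding("class0", "class1")) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  subject_ids <- as.character(subject_ids)
  variable_names <- as.character(variable_names)
  if (nrow(values) != length(subject_ids)) {
    stop("number of rows (", nrow(values), ") does not match number of subject ids (",
         length(subject_ids), ")")
  }
  if (ncol(values) != length(variable_names)) {
    stop("number of columns (", ncol(values), ") does not match number of variable names (",
         length(variable_names), ")")
  }
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  }
  if (anyDuplicated(variable_names)) {
    stop("duplicate variable names: ",
         paste(unique(variable_names[duplicated(variable_names)]), collapse = ", "))
  }
  bad <- which(!is.finite(values) | values < 0 | values > 100, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("value out of [0, 100] or non-finite at subject '", subject_ids[i],
         "', variable '", variable_names[j], "': ", format(values[i, j]))
  }
  class_labels <- as.integer(class_labels)
  if (length(class_labels) != nrow(values)) {
    stop("class_labels length does not match number of subjects")
  }
  if (!all(class_labels %in% c(0L, 1L))) {
    stop("class_labels must contain only 0 and 1")
  }
  if (!all(c(0L, 1L) %in% class_labels)) {
    stop("both classes (0 and 1) must be present")
  }
  if (!inherits(coding, "class_coding")) stop("coding must be a class_coding object")
  dimnames(values) <- list(subject_ids, variable_names)
  structure(list(values = values,
                 subject_ids = subject_ids,
                 variable_names = variable_names,
                 class_labels = class_labels,
                 coding = coding),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat("phenotype_matrix:", nrow(x$values), "subjects x", ncol(x$values), "variables\n")
  cat("  class 0 (", x$coding$label_for_zero, "): ", sum(x$class_labels == 0L),
      "   class 1 (", x$coding$label_for_one, "): ", sum(x$class_labels == 1L), "\n", sep = "")
  invisible(x)
}

#' @export
dim.phenotype_matrix <- function(x) dim(x$values)

#' Read a phenotype matrix from CSV
#'
#' Expects a header row; the first column holds subject ids, the second the
#' 0/1 class label, and the remaining columns hold numeric percentages.
#' Column order is preserved. Comma-separated, UTF-8, decimal point.
#'
#' @param path Path to the CSV file.
#' @param coding Optional [class_coding()] legend attached to the result.
#' @return A validated [phenotype_matrix()].
#' @export
read_phenotype_csv <- function(path, coding = class_coding("class0", "class1")) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("phenotype CSV needs id, class and at least one variable column")
  ids <- as.character(df[[1L]])
  cls <- df[[2L]]
  vars <- colnames(df)[-(1:2)]
  vals <- df[, -(1:2), drop = FALSE]
  for (j in seq_along(vars)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop("non-numeric value in column '", vars[j], "', row ",
           if (length(bad)) bad else "?", " ('", col[if (length(bad)) bad else 1L], "')")
    }
  }
  phenotype_matrix(as.matrix(vals), ids, vars, cls, coding = coding)
}

#' Write a phenotype matrix to CSV
#'
#' Inverse of [read_phenotype_csv()]: full-precision round trip.
#'
#' @param x A [phenotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(x, path) {
  stopifnot(inherits(x, "phenotype_matrix"))
  df <- data.frame(subject_id = x$subject_ids,
                   class = x$class_labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.data.frame(x$values, optional = TRUE)
  rownames(vals) <- NULL
  df <- cbind(df, vals)
  # format() would truncate; write numbers at full double precision
  for (j in seq(3L, ncol(df))) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-subject CD4 trajectory
#'
#' A longitudinal series of CD4 counts used to estimate the subject's CD4
#' slope (cells/uL per year). At least three visits are required and times
#' must be strictly increasing.
#'
#' @param subject_id Subject identifier.
#' @param times Years since baseline, non-negative and strictly increasing.
#' @param counts CD4 counts in cells/uL, positive.
#' @return An object of class `cd4_trajectory`.
#' @export
cd4_trajectory <- function(subject_id, times, counts) {
  times <- as.numeric(times); counts <- as.numeric(counts)
  if (length(times) != length(counts)) stop("times and counts lengths differ")
  if (length(times) < 3L) stop("a CD4 trajectory needs at least 3 time points")
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be finite and non-negative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(counts)) || any(counts <= 0)) stop("counts must be finite and positive")
  structure(list(subject_id = as.character(subject_id),
                 times = times, counts = counts),
            class = "cd4_trajectory")
}

#' Read CD4 trajectories from CSV
#'
#' Expects columns `subject_id`, `time_years`, `cd4_count`; rows are grouped
#' by subject and sorted by time within subject. Any series with at least
#' three visits is accepted; visit-exclusion rules are left to the caller.
#'
#' @param path Path to the CSV file.
#' @return A named list of [cd4_trajectory()] objects.
#' @export
read_cd4_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_years", "cd4_count")
  if (!all(need %in% colnames(df))) {
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  }
  split_df <- split(df, df$subject_id)
  out <- lapply(split_df, function(d) {
    d <- d[order(d$time_years), , drop = FALSE]
    cd4_trajectory(d$subject_id[1L], d$time_years, d$cd4_count)
  })
  out[order(names(out))]
}
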
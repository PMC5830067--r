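#' Configuration of a synthetic immunophenotype cohort
#'
#' Full statistical recipe for generating a two-class cohort of correlated
#' percentage variables with a sparse planted set of discriminative
#' variables. The defaults emulate the dimensions of a case-control design
#' within a patient cohort (22 vs 14 subjects, 350 variables); the `"pls1"`
#' preset switches to a 36-vs-14 patients-vs-healthy design. Because
#' per-variable baselines are drawn once and shared by all subjects, the
#' uncentered matrix has a dominant mean-offset direction, so the first
#' latent variable of an uncentered PLS fit explains the bulk of the X-block
#' sum of squares — the regime the class-modeling pipeline assumes.
#'
#' @param n_class0,n_class1 Subject counts per class (defaults 22, 14).
#' @param n_variables Number of percentage variables (default 350).
#' @param n_informative Number of discriminative variables (default 30).
#' @param effect_size Class-mean shift at informative variables, in units of
#'   the within-class SD (default 1.5).
#' @param n_latent_factors Number of shared factors driving correlation
#'   blocks (default 6).
#' @param factor_strength Fraction of within-class variance contributed by
#'   the shared factors, in `[0, 1)` (default 0.3).
#' @param baseline_mean_range Interval (percent) for per-variable baseline
#'   levels (default `c(5, 40)`).
#' @param noise_sd_range Interval (percent) for per-variable independent
#'   noise SD (default `c(1, 5)`).
#' @param seed Integer seed; all randomness fans out from it through
#'   per-component substreams.
#' @param preset `"pls2"` (default sizes), `"pls1"` (36 vs 14) or `"none"`.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cohort_config(seed = 1)
#' cohort_config(preset = "pls1", seed = 1)
cohort_config <- function(n_class0 = 22L, n_class1 = 14L, n_variables = 350L,
                          n_informative = 30L, effect_size = 1.5,
                          n_latent_factors = 6L, factor_strength = 0.3,
                          baseline_mean_range = c(5, 40),
                          noise_sd_range = c(1, 5),
                          seed = 1L, preset = c("pls2", "pls1", "none")) {
  preset <- match.arg(preset)
  if (preset == "pls1") { n_class0 <- 36L; n_class1 <- 14L }
  cfg <- list(n_class0 = as.integer(n_class0), n_class1 = as.integer(n_class1),
              n_variables = as.integer(n_variables),
              n_informative = as.integer(n_informative),
              effect_size = effect_size,
              n_latent_factors = as.integer(n_latent_factors),
              factor_strength = factor_strength,
              baseline_mean_range = as.numeric(baseline_mean_range),
              noise_sd_range = as.numeric(noise_sd_range),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_class0 > 0L, n_class1 > 0L, n_variables > 0L,
              n_informative >= 0L, n_informative <= n_variables,
              effect_size >= 0, n_latent_factors >= 0L,
              factor_strength >= 0, factor_strength < 1,
              length(baseline_mean_range) == 2L,
              all(baseline_mean_range >= 0), all(baseline_mean_range <= 100),
              baseline_mean_range[1L] <= baseline_mean_range[2L],
              length(noise_sd_range) == 2L, all(noise_sd_range > 0),
              noise_sd_range[1L] <= noise_sd_range[2L])
  })
  structure(cfg, class = "cohort_config")
}

# deterministic substream seeds below 2^31, so different blocks of draws do
# not shift when one block's parameters change
substream_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

#' Generate a synthetic two-class phenotype cohort
#'
#' Draws `values = baseline + factor contribution + class shift + noise`,
#' clipped to `[0, 100]`. Per-variable baselines come from
#' `baseline_mean_range`; each variable belongs to one latent-factor block
#' contributing `factor_strength` of its within-class variance (with a
#' random sign); the planted informative variables receive a class-1 mean
#' shift of `effect_size` within-class SDs (random sign); the rest is
#' independent Gaussian noise. Deterministic given `config$seed`, with
#' separate substreams for baselines, noise SDs, factor structure, the
#' informative set, factor scores and noise.
#'
#' @param config A [cohort_config()].
#' @return A list with `phenotype` (a [phenotype_matrix()]), `truth` (list:
#'   `informative_indices`, `true_effects` — signed per-variable mean shifts
#'   in percent, nonzero exactly at the informative set — and
#'   `factor_loadings`), and `clip_fraction` (share of cells clipped).
#'   A warning (class `plscm_clipping_warning`) is raised when more than 10%
#'   of cells were clipped.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' cohort$phenotype
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  p <- config$n_variables
  n0 <- config$n_class0; n1 <- config$n_class1; n <- n0 + n1
  k <- config$n_latent_factors
  fs <- config$factor_strength

  set.seed(substream_seed(config$seed, 1L))
  baseline <- stats::runif(p, config$baseline_mean_range[1L], config$baseline_mean_range[2L])
  set.seed(substream_seed(config$seed, 2L))
  noise_sd <- stats::runif(p, config$noise_sd_range[1L], config$noise_sd_range[2L])
  within_sd <- noise_sd / sqrt(1 - fs)

  L <- matrix(0, p, max(k, 1L))
  if (k > 0L) {
    set.seed(substream_seed(config$seed, 3L))
    block <- rep_len(seq_len(k), p)
    sgn <- sample(c(-1, 1), p, replace = TRUE)
    L[cbind(seq_len(p), block)] <- within_sd * sqrt(fs) * sgn
  }

  set.seed(substream_seed(config$seed, 4L))
  informative <- if (config$n_informative > 0L) sort(sample.int(p, config$n_informative)) else integer(0)
  effect_sign <- sample(c(-1, 1), length(informative), replace = TRUE)
  true_effects <- numeric(p)
  true_effects[informative] <- config$effect_size * within_sd[informative] * effect_sign

  labels <- c(rep(0L, n0), rep(1L, n1))
  set.seed(substream_seed(config$seed, 5L))
  Z <- matrix(stats::rnorm(n * max(k, 1L)), n, max(k, 1L))
  set.seed(substream_seed(config$seed, 6L))
  noise <- matrix(stats::rnorm(n * p), n, p) * rep(noise_sd, each = n)

  X <- matrix(rep(baseline, each = n), n, p) +
    (if (k > 0L) Z %*% t(L) else 0) +
    outer(labels, true_effects) +
    noise
  clipped <- X < 0 | X > 100
  clip_fraction <- mean(clipped)
  X <- pmin(pmax(X, 0), 100)
  if (clip_fraction > 0.10) {
    warning(warningCondition(
      sprintf("%.1f%% of generated values were clipped to [0, 100]; the configuration is near-infeasible",
              100 * clip_fraction),
      class = "plscm_clipping_warning"))
  }

  pheno <- phenotype_matrix(X,
                            subject_ids = sprintf("S%03d", seq_len(n)),
                            variable_names = sprintf("V%03d", seq_len(p)),
                            class_labels = labels)
  list(phenotype = pheno,
       truth = list(informative_indices = informative,
                    true_effects = true_effects,
                    factor_loadings = L),
       clip_fraction = clip_fraction)
}

#' Generate synthetic CD4 trajectories
#'
#' Controls have a flat expected trajectory (slope 0); cases decline at
#' `case_slope` cells/uL per year. Visit-level Gaussian noise is added and
#' counts are floored at 1 cell/uL to stay positive. The default decline of
#' -66 cells/uL per year matches the median slope reported for progressing
#' patients.
#'
#' @param n_cases,n_controls Subject counts.
#' @param visits Visits per subject (>= 3), default 10.
#' @param years Follow-up span in years, default 10.
#' @param case_slope Expected slope for cases (negative), default -66.
#' @param baseline Expected CD4 count at time 0, default 900 cells/uL.
#' @param noise_sd Visit-level noise SD in cells/uL, default 50.
#' @param seed Integer seed.
#' @return A list with `trajectories` (list of [cd4_trajectory()]) and
#'   `truth` (data frame: `subject_id`, `group`).
#' @export
generate_trajectories <- function(n_cases, n_controls, visits = 10L, years = 10,
                                  case_slope = -66, baseline = 900,
                                  noise_sd = 50, seed = 1L) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  if (n_cases < 0L || n_controls < 0L || n_cases + n_controls < 1L) {
    stop("invalid subject counts")
  }
  visits <- as.integer(visits)
  if (visits < 3L) stop("visits must be at least 3")
  if (case_slope > 0) stop("case_slope must be negative or zero")
  set.seed(substream_seed(as.integer(seed), 11L))
  times <- seq(0, years, length.out = visits)
  group <- c(rep("case", n_cases), rep("control", n_controls))
  ids <- sprintf("T%03d", seq_along(group))
  trajectories <- lapply(seq_along(group), function(i) {
    slope <- if (group[i] == "case") case_slope else 0
    counts <- pmax(baseline + slope * times + stats::rnorm(visits, sd = noise_sd), 1)
    cd4_trajectory(ids[i], times, counts)
  })
  names(trajectories) <- ids
  list(trajectories = trajectories,
       truth = data.frame(subject_id = ids, group = group, stringsAsFactors = FALSE))
}
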
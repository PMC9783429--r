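# Residuals from the nuisance-only model: population + test environment +
# the trait's unit adjustment (no SA terms, no origin x test interaction).
nuisance_residuals <- function(data, spec) {
  spec <- as_trait_spec(spec)
  data <- transform_response(data, spec)
  n <- nrow(data)
  blocks <- c(
    list(intercept = matrix(1, n, 1),
         population = sum_contrast_cols(data$population, "pop."),
         test_env = sum_contrast_cols(data$test, "test.")),
    tail_block(data, spec)
  )
  X <- do.call(cbind, blocks)
  data$resid <- as.numeric(resid_against(data$response, X))
  data
}

#' Residualized genetic and plastic effect means per origin x test cell
#'
#' Fits the nuisance-only model (population, test environment, and the
#' trait's unit adjustment; no SA terms, no interaction) across both
#' phases, then summarizes its residuals per test x origin cell: the
#' genetic mean is the common-phase residual mean (the pattern persisting
#' after common-environment rearing), the plastic mean is the field-phase
#' minus common-phase residual mean (the part that washes out).
#'
#' 95% intervals: the genetic mean uses the common-phase residual spread;
#' the plastic mean treats the field-phase variance as (plastic + genetic
#' noise) and subtracts the common-phase variance, so its interval is
#' reported as absent (`NA`) whenever the common-phase variance exceeds the
#' field-phase variance.
#'
#' @inheritParams sa_test_single
#' @return A tibble of class `sa_effect_cells`, one row per realized
#'   test x origin cell.
#' @export
effect_means <- function(data, spec) {
  spec <- as_trait_spec(spec)
  if (length(unique(data$phase)) < 2) {
    sa_abort_precondition("effect_means requires both phases")
  }
  data <- nuisance_residuals(data, spec)
  cells <- data |>
    dplyr::group_by(.data$test, .data$origin) |>
    dplyr::summarise(
      n_common = sum(.data$phase == "common"),
      n_field = sum(.data$phase == "field"),
      genetic_mean = mean(.data$resid[.data$phase == "common"]),
      genetic_sd = sd(.data$resid[.data$phase == "common"]),
      field_mean = mean(.data$resid[.data$phase == "field"]),
      field_sd = sd(.data$resid[.data$phase == "field"]),
      .groups = "drop"
    )
  incomplete <- cells$n_common == 0 | cells$n_field == 0
  if (any(incomplete)) {
    rlang::warn(paste0("dropping ", sum(incomplete),
                       " origin x test cell(s) with an empty phase"))
    cells <- cells[!incomplete, , drop = FALSE]
  }
  z <- qnorm(0.975)
  cells <- cells |>
    dplyr::mutate(
      plastic_mean = .data$field_mean - .data$genetic_mean,
      genetic_se = .data$genetic_sd / sqrt(.data$n_common),
      genetic_ci_low = .data$genetic_mean - z * .data$genetic_se,
      genetic_ci_high = .data$genetic_mean + z * .data$genetic_se,
      plastic_var = .data$field_sd^2 - .data$genetic_sd^2,
      plastic_se = ifelse(.data$plastic_var > 0,
                          sqrt(pmax(.data$plastic_var, 0) / .data$n_field),
                          NA_real_),
      plastic_ci_low = .data$plastic_mean - z * .data$plastic_se,
      plastic_ci_high = .data$plastic_mean + z * .data$plastic_se
    ) |>
    dplyr::select("test", "origin", "n_common", "n_field",
                  "genetic_mean", "genetic_se", "genetic_ci_low",
                  "genetic_ci_high", "plastic_mean", "plastic_se",
                  "plastic_ci_low", "plastic_ci_high")
  class(cells) <- c("sa_effect_cells", class(cells))
  cells
}

#' Per-population trait means on original vs alternative environments
#'
#' For one assay phase, pairs each population's mean transformed trait on
#' its sympatric (original) environment with its mean on each allopatric
#' (alternative) environment — the layout behind original-vs-alternative
#' scatter plots, where points below the identity line indicate a
#' sympatric advantage.
#'
#' @inheritParams sa_test_single
#' @param phase `"common"` or `"field"`.
#' @return A tibble with one row per population x alternative environment:
#'   the original-environment mean/SE (shared within population), the
#'   alternative-environment mean/SE, and the population's total unit
#'   (vial/arena) count `n_vials` in this phase.
#' @export
original_vs_alternative <- function(data, spec, phase = c("common", "field")) {
  spec <- as_trait_spec(spec)
  phase <- match.arg(phase)
  data <- transform_response(data, spec)
  data <- data[data$phase == phase, , drop = FALSE]
  if (nrow(data) == 0) {
    sa_abort_precondition(paste0("no records in phase '", phase, "'"))
  }
  has_symp <- data |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(any_symp = any(.data$test == .data$origin), .groups = "drop")
  missing <- has_symp$population[!has_symp$any_symp]
  if (length(missing) > 0) {
    rlang::warn(paste0("excluding population(s) without sympatric assays: ",
                       paste(missing, collapse = ", ")))
    data <- data[!(data$population %in% missing), , drop = FALSE]
  }
  vials <- data |>
    dplyr::distinct(.data$population, .data$unit) |>
    dplyr::count(.data$population, name = "n_vials")
  env_means <- data |>
    dplyr::group_by(.data$population, .data$origin, .data$test) |>
    dplyr::summarise(mean = mean(.data$response),
                     se = sd(.data$response) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  orig <- env_means |>
    dplyr::filter(.data$test == .data$origin) |>
    dplyr::select("population", "origin",
                  mean_original = "mean", se_original = "se", n_original = "n")
  alt <- env_means |>
    dplyr::filter(.data$test != .data$origin) |>
    dplyr::select("population", alt_env = "test",
                  mean_alternative = "mean", se_alternative = "se",
                  n_alternative = "n")
  orig |>
    dplyr::inner_join(alt, by = "population") |>
    dplyr::inner_join(vials, by = "population") |>
    dplyr::arrange(.data$population, .data$alt_env)
}

#' Weighted Pearson correlation with a Fisher-z confidence interval
#'
#' Weighted means, variances, and covariance throughout; the 95% interval
#' uses the Fisher z transform with the effective sample size
#' `n_eff = (sum w)^2 / sum(w^2)`.
#'
#' @param x,y Numeric vectors of equal length (>= 3 after removing
#'   incomplete pairs).
#' @param w Non-negative weights; equal weights reduce to the ordinary
#'   Pearson coefficient.
#' @param conf_level Confidence level for the interval.
#' @param weights_used Label recorded in the output.
#' @return A one-row tibble of class `sa_wcor`: `rho`, `ci_low`, `ci_high`,
#'   `n_eff`, `n`, `weights_used`.
#' @examples
#' weighted_pearson(1:5, c(2, 4, 5, 8, 11), rep(1, 5))
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x)), conf_level = 0.95,
                             weights_used = "supplied") {
  if (length(x) != length(y) || length(x) != length(w)) {
    sa_abort_value("x, y, and w must have equal lengths")
  }
  if (any(w < 0, na.rm = TRUE)) sa_abort_value("weights must be non-negative")
  keep <- complete.cases(x, y, w)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 3) sa_abort_precondition("need at least 3 complete pairs")
  if (sum(w) <= 0) sa_abort_value("weights must not all be zero")
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    rlang::warn("weighted correlation undefined: zero weighted variance")
    return(tibble_wcor(NaN, NA_real_, NA_real_, NA_real_, length(x), weights_used))
  }
  rho <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  rho <- max(-1, min(1, rho))
  n_eff <- sum(w)^2 / sum(w^2)
  if (n_eff > 3 && abs(rho) < 1) {
    zse <- 1 / sqrt(n_eff - 3)
    zcrit <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(atanh(rho) + c(-1, 1) * zcrit * zse)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  tibble_wcor(rho, ci[1], ci[2], n_eff, length(x), weights_used)
}

tibble_wcor <- function(rho, lo, hi, n_eff, n, weights_used) {
  out <- tibble::tibble(rho = rho, ci_low = lo, ci_high = hi, n_eff = n_eff,
                        n = n, weights_used = weights_used)
  class(out) <- c("sa_wcor", class(out))
  out
}

#' Cross-generation correlation of population means per test environment
#'
#' Correlates each population's mean transformed trait in the field phase
#' with its mean in the common phase, separately per test environment,
#' weighting populations by their total number of rearing units (vials)
#' contributing to that environment across both phases.
#'
#' @inheritParams sa_test_single
#' @return A tibble of class `sa_wcor`, one row per test environment.
#' @export
cross_generation_correlation <- function(data, spec) {
  spec <- as_trait_spec(spec)
  if (length(unique(data$phase)) < 2) {
    sa_abort_precondition("cross_generation_correlation requires both phases")
  }
  data <- transform_response(data, spec)
  means <- data |>
    dplyr::group_by(.data$test, .data$population, .data$phase) |>
    dplyr::summarise(mean = mean(.data$response),
                     n_units = dplyr::n_distinct(.data$unit), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase",
                       values_from = c("mean", "n_units")) |>
    dplyr::filter(!is.na(.data$mean_field) & !is.na(.data$mean_common))
  out <- means |>
    dplyr::group_by(.data$test) |>
    dplyr::group_modify(function(d, key) {
      weighted_pearson(d$mean_field, d$mean_common,
                       d$n_units_field + d$n_units_common,
                       weights_used = "total vials per population")
    }) |>
    dplyr::ungroup()
  class(out) <- c("sa_wcor", class(out))
  out
}

#' Correlation between preference and performance population means
#'
#' Residualizes each trait with its own nuisance model (as in
#' [effect_means()]), averages residuals per population x test environment
#' within the requested phase, pairs the two traits, and reports the
#' weighted correlation (weights: the population's total vial count across
#' both tables in that phase). Populations present in only one table are
#' dropped with a warning.
#'
#' @param pref Observation table for oviposition preference (choice assay).
#' @param perf Observation table for offspring performance
#'   (egg-to-adult survival).
#' @param phase `"common"` (e.g. G2 preference vs G3 performance) or
#'   `"field"` (G0 vs G1).
#' @param pref_spec,perf_spec Trait specs for the two tables.
#' @return A one-row tibble of class `sa_wcor`.
#' @export
preference_performance_correlation <- function(pref, perf,
                                               phase = c("common", "field"),
                                               pref_spec = trait_spec("preference"),
                                               perf_spec = trait_spec("performance")) {
  phase <- match.arg(phase)
  pref_r <- nuisance_residuals(pref, pref_spec)
  perf_r <- nuisance_residuals(perf, perf_spec)
  cell_means <- function(d) {
    d[d$phase == phase, , drop = FALSE] |>
      dplyr::group_by(.data$population, .data$test) |>
      dplyr::summarise(mean = mean(.data$resid),
                       n_units = dplyr::n_distinct(.data$unit),
                       .groups = "drop")
  }
  a <- cell_means(pref_r)
  b <- cell_means(perf_r)
  only <- union(setdiff(unique(a$population), unique(b$population)),
                setdiff(unique(b$population), unique(a$population)))
  if (length(only) > 0) {
    rlang::warn(paste0("dropping population(s) present in only one table: ",
                       paste(only, collapse = ", ")))
  }
  joined <- dplyr::inner_join(a, b, by = c("population", "test"),
                              suffix = c("_pref", "_perf"))
  weighted_pearson(joined$mean_pref, joined$mean_perf,
                   joined$n_units_pref + joined$n_units_perf,
                   weights_used = "total vials per population")
}
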
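drop_design_block <- function(design, name) {
  design$blocks <- design$blocks[setdiff(names(design$blocks), name)]
  design
}

term_row <- function(fit, term) {
  i <- match(term, fit$table$term)
  as.list(fit$table[i, ])
}

# Joint-fit (partial) coefficient of an SA covariate: the SA column is
# residualized against the span of every other model term, with its own
# interaction block reduced to the remainder orthogonal to the SA column so
# the model is full rank (Frisch-Waugh). This is the estimate a joint
# least-squares fit of the model reports, and it attributes a field-only
# sympatric bonus entirely to the plastic term.
partial_sa <- function(design, y, sa_term, int_term) {
  blocks <- design$blocks
  sa_col <- blocks[[sa_term]]
  others <- blocks[setdiff(names(blocks), sa_term)]
  others[[int_term]] <- resid_against(blocks[[int_term]], sa_col)
  M <- do.call(cbind, unname(others))
  sa_t <- resid_against(resid_against(sa_col, M), M)
  nrm2 <- sum(sa_t^2)
  list(beta = sum(sa_t * y) / nrm2, nrm2 = nrm2)
}

# Assemble one SA component (estimate, F test, phi) from a fitted model.
# `ss_scale` is the intercept-corrected total mean square, used to decide
# when a denominator mean square is numerically zero (noise-free data).
sa_component <- function(fit, est, sa_term, den_term, ss_scale,
                         ms_constrained = NULL) {
  sa <- term_row(fit, sa_term)
  den <- term_row(fit, den_term)
  if (is.na(den$df) || den$df == 0) {
    sa_abort_precondition(paste0(
      "F denominator '", den_term, "' has 0 degrees of freedom; with two ",
      "environments the interaction is fully consumed by the SA contrast - ",
      "use the dual-generation test or assay more environments"))
  }
  f_undefined <- is.na(den$ms) || den$ms <= 1e-14 * max(ss_scale, 1e-300)
  F_stat <- if (f_undefined) NaN else sa$ms / den$ms
  p <- if (f_undefined) NA_real_ else pf(F_stat, sa$df, den$df, lower.tail = FALSE)
  ms_den <- if (f_undefined) 0 else den$ms
  se <- sqrt(ms_den / est$nrm2)
  list(
    estimate = est$beta,
    se = se,
    statistic = F_stat,
    df_num = sa$df,
    df_den = den$df,
    p_value = p,
    phi = if (is.null(ms_constrained)) NA_real_ else phi(ms_constrained, den$ms),
    f_undefined = f_undefined
  )
}

total_ms <- function(fit) {
  (sum(fit$table$ss) + fit$residual$ss) / max(fit$engine$n - 1, 1)
}

#' Single-generation sympatric-allopatric test
#'
#' Tests for a trait difference between sympatric (original) and allopatric
#' (alternative) environments within one assay phase, controlling for
#' population and test-environment quality. The SA term is tested with
#' `F = MS(sa) / MS(interaction remainder)` on
#' `(1, (J-1)(K-1) - 1)` degrees of freedom. A positive estimate indicates a
#' pattern of local adaptation (for the common phase) and a negative one
#' maladaptation.
#'
#' @param data An observation tibble (raw counts; the trait transform is
#'   applied unless a `response` column is already present).
#' @param spec A trait name or [trait_spec()] object.
#' @param phase `"common"` (default; genetic pattern) or `"field"`.
#' @param compute_phi Also refit the SA-constrained model and report the
#'   fraction of interaction mean square explained by the SA term.
#' @return An object of class `sa_single_result`.
#' @export
sa_test_single <- function(data, spec, phase = c("common", "field"),
                           compute_phi = TRUE) {
  spec <- as_trait_spec(spec)
  phase <- match.arg(phase)
  data <- transform_response(data, spec)
  design <- build_single_design(data, spec, phase)
  y <- data$response[data$phase == phase]
  fit <- fit_sequential_anova(design, y, coefficients = FALSE)
  ms_constrained <- NULL
  if (compute_phi) {
    cfit <- fit_sequential_anova(drop_design_block(design, "sa"), y,
                                 coefficients = FALSE)
    ms_constrained <- term_row(cfit, "interaction")$ms
  }
  est <- partial_sa(design, y, "sa", "interaction")
  structure(
    list(
      sa = sa_component(fit, est, "sa", "interaction", total_ms(fit),
                        ms_constrained),
      anova = fit$table,
      residual = fit$residual,
      fit = fit,
      meta = list(model = "single", phase = phase, trait = spec$trait,
                  transform = spec$transform, n = design$n,
                  envs = design$meta$envs)
    ),
    class = "sa_single_result"
  )
}

#' Dual-generation test for local adaptation and adaptive plasticity
#'
#' Jointly analyzes field-derived (e.g. G0/G1) and common-environment
#' (e.g. G2/G3) assays. The genetic SA term, shared by both phases,
#' measures local adaptation; the plastic SA term, confined to the field
#' phase, measures adaptive phenotypic plasticity. Each is tested against
#' its own interaction-remainder mean square:
#' `F_genetic = MS(sa_genetic) / MS(origin x test remainder)` and
#' `F_plastic = MS(sa_plastic) / MS(field-phase interaction-deviation
#' remainder)`, both on `(1, (J-1)(K-1) - 1)` degrees of freedom. A
#' significant F with a positive estimate supports local adaptation
#' (genetic) or adaptive plasticity (plastic); `phi` reports the fraction
#' of the relevant interaction mean square removed by the SA term, from
#' independent constrained/free fits.
#'
#' @inheritParams sa_test_single
#' @return An object of class `sa_dual_result` with components `genetic`
#'   and `plastic` (estimate, se, statistic, df, p_value, phi), the
#'   sequential ANOVA table, and fit metadata. Use [tidy()] / [glance()]
#'   for tabular summaries.
#' @examples
#' obs <- generate_dataset(sim_config(sa_genetic_true = 0.5, seed = 42))
#' fit <- sa_test_dual(obs, "fecundity")
#' tidy(fit)
#' @export
sa_test_dual <- function(data, spec, compute_phi = TRUE) {
  spec <- as_trait_spec(spec)
  data <- transform_response(data, spec)
  design <- build_dual_design(data, spec)
  y <- data$response
  fit <- fit_sequential_anova(design, y, coefficients = FALSE)
  ms_g <- ms_p <- NULL
  if (compute_phi) {
    gfit <- fit_sequential_anova(drop_design_block(design, "sa_genetic"), y,
                                 coefficients = FALSE)
    ms_g <- term_row(gfit, "interaction")$ms
    pfit <- fit_sequential_anova(drop_design_block(design, "sa_plastic"), y,
                                 coefficients = FALSE)
    ms_p <- term_row(pfit, "delta_interaction")$ms
  }
  est_g <- partial_sa(design, y, "sa_genetic", "interaction")
  est_p <- partial_sa(design, y, "sa_plastic", "delta_interaction")
  scale <- total_ms(fit)
  structure(
    list(
      genetic = sa_component(fit, est_g, "sa_genetic", "interaction", scale,
                             ms_g),
      plastic = sa_component(fit, est_p, "sa_plastic", "delta_interaction",
                             scale, ms_p),
      anova = fit$table,
      residual = fit$residual,
      fit = fit,
      meta = list(model = "dual", trait = spec$trait,
                  transform = spec$transform, n = design$n,
                  n_capped = if ("capped" %in% names(data)) sum(data$capped) else 0L,
                  envs = design$meta$envs)
    ),
    class = "sa_dual_result"
  )
}

component_tibble <- function(comp, label) {
  tibble::tibble(
    component = label,
    estimate = comp$estimate,
    se = comp$se,
    statistic = comp$statistic,
    df_num = comp$df_num,
    df_den = comp$df_den,
    p_value = comp$p_value,
    phi = comp$phi
  )
}

#' @method tidy sa_dual_result
#' @export
tidy.sa_dual_result <- function(x, ...) {
  dplyr::bind_rows(component_tibble(x$genetic, "genetic"),
                   component_tibble(x$plastic, "plastic"))
}

#' @method tidy sa_single_result
#' @export
tidy.sa_single_result <- function(x, ...) {
  component_tibble(x$sa, "sa")
}

#' @method glance sa_dual_result
#' @export
glance.sa_dual_result <- function(x, ...) {
  tibble::tibble(
    trait = x$meta$trait,
    transform = x$meta$transform,
    n = x$meta$n,
    df_residual = x$residual$df,
    sigma2 = x$residual$ms,
    phi_genetic = x$genetic$phi,
    phi_plastic = x$plastic$phi
  )
}

#' @method glance sa_single_result
#' @export
glance.sa_single_result <- function(x, ...) {
  tibble::tibble(
    trait = x$meta$trait,
    phase = x$meta$phase,
    transform = x$meta$transform,
    n = x$meta$n,
    df_residual = x$residual$df,
    sigma2 = x$residual$ms,
    phi = x$sa$phi
  )
}

print_component <- function(comp, label) {
  cat(sprintf(
    "  %-8s estimate = %8.4f (SE %.4f)  F(%d,%d) = %s, p = %s, phi = %s\n",
    label, comp$estimate, comp$se, comp$df_num, comp$df_den,
    if (comp$f_undefined) "undefined" else sprintf("%.3f", comp$statistic),
    if (is.na(comp$p_value)) "NA" else format.pval(comp$p_value, digits = 3),
    if (is.na(comp$phi)) "NA" else sprintf("%.3f", comp$phi)))
}

#' @export
print.sa_dual_result <- function(x, ...) {
  cat("Dual-generation sympatric-allopatric test (trait: ",
      x$meta$trait, ", n = ", x$meta$n, ")\n", sep = "")
  print_component(x$genetic, "genetic")
  print_component(x$plastic, "plastic")
  invisible(x)
}

#' @export
print.sa_single_result <- function(x, ...) {
  cat("Single-generation sympatric-allopatric test (trait: ",
      x$meta$trait, ", phase: ", x$meta$phase, ", n = ", x$meta$n, ")\n",
      sep = "")
  print_component(x$sa, "sa")
  invisible(x)
}

#' Serialize an SA test result as JSON
#'
#' Stable field names: each SA component is an object with `estimate`,
#' `se`, `statistic`, `df_num`, `df_den`, `p_value`, `phi`; the sequential
#' ANOVA table is an array of `{term, df, ss, ms}` rows plus a `residual`
#' object.
#'
#' @param x An `sa_dual_result` or `sa_single_result`.
#' @return A JSON string (class `json`).
#' @export
sa_result_json <- function(x) {
  comps <- if (inherits(x, "sa_dual_result")) {
    list(genetic = x$genetic, plastic = x$plastic)
  } else {
    list(sa = x$sa)
  }
  comps <- lapply(comps, function(c) c[c("estimate", "se", "statistic",
                                         "df_num", "df_den", "p_value",
                                         "phi", "f_undefined")])
  payload <- list(
    schema = "sadapt/sa_result/v1",
    meta = x$meta,
    components = comps,
    anova = x$anova,
    residual = x$residual[c("df", "ss", "ms")]
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
}
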
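#' Sympatric indicator
#'
#' Returns 1 when the test environment matches the population's environment
#' of origin (sympatric assay) and 0 otherwise (allopatric assay).
#'
#' @param test_env,origin_env Environment labels (vectorized, recycled).
#' @param env_set Optional set of known environment labels; when supplied,
#'   any label outside it is an error.
#' @return An integer vector of 0/1.
#' @export
sympatric_indicator <- function(test_env, origin_env, env_set = NULL) {
  test_env <- normalize_env(test_env)
  origin_env <- normalize_env(origin_env)
  if (!is.null(env_set)) {
    env_set <- normalize_env(env_set)
    bad <- setdiff(unique(c(test_env, origin_env)), env_set)
    if (length(bad) > 0) {
      sa_abort_value(paste0("unknown environment label(s): ",
                            paste(bad, collapse = ", ")))
    }
  }
  as.integer(test_env == origin_env)
}

# Sum-to-zero contrast columns for a factor; k levels -> k-1 columns.
sum_contrast_cols <- function(x, prefix) {
  f <- factor(x)
  k <- nlevels(f)
  if (k < 2) {
    return(matrix(numeric(0), nrow = length(x), ncol = 0))
  }
  C <- stats::contr.sum(k)
  M <- C[as.integer(f), , drop = FALSE]
  colnames(M) <- paste0(prefix, levels(f)[-k])
  M
}

# Origin x test interaction columns: products of the two sum-contrast sets.
interaction_cols <- function(test, origin) {
  Tc <- sum_contrast_cols(test, "t.")
  Oc <- sum_contrast_cols(origin, "o.")
  if (ncol(Tc) == 0 || ncol(Oc) == 0) {
    return(matrix(numeric(0), nrow = length(test), ncol = 0))
  }
  cols <- list()
  for (a in seq_len(ncol(Tc))) {
    for (b in seq_len(ncol(Oc))) {
      cols[[paste0(colnames(Tc)[a], ":", colnames(Oc)[b])]] <- Tc[, a] * Oc[, b]
    }
  }
  do.call(cbind, cols)
}

# Unit (arena/vial) contrast columns, centered within population x phase so
# between-unit differences in population mean stay in the population block.
unit_block_cols <- function(population, phase, unit) {
  n <- length(unit)
  grp <- paste(population, phase, sep = "\r")
  cols <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    u <- factor(unit[idx])
    k <- nlevels(u)
    if (k < 2) next
    C <- stats::contr.sum(k)
    M <- matrix(0, nrow = n, ncol = k - 1)
    M[idx, ] <- C[as.integer(u), , drop = FALSE]
    colnames(M) <- paste0("unit.", levels(u)[-k])
    cols[[g]] <- M
  }
  if (length(cols) == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  do.call(cbind, cols)
}

# The SA covariate must retain variation after residualization against the
# main-effect blocks; otherwise the data carry no sympatric-vs-allopatric
# contrast (e.g. every assay sympatric).
check_sa_contrast <- function(col, tol = 1e-10) {
  if (sqrt(sum(col^2)) < tol * max(1, nrow(col))) {
    sa_abort_precondition(paste0(
      "SA contrast undefined: the data carry no sympatric-vs-allopatric ",
      "contrast beyond population and test-environment effects ",
      "(check reciprocal coverage of test environments)"))
  }
  invisible(col)
}

# Residualize columns against a basis (least-squares projection removed).
resid_against <- function(x, M) {
  q <- qr(M)
  x - qr.fitted(q, x)
}

tail_block <- function(data, spec) {
  switch(spec$unit_adjustment,
    arena_block = list(unit = unit_block_cols(data$population, data$phase, data$unit)),
    log_egg_density = {
      m <- matrix(log(data$eggs + spec$offset), ncol = 1,
                  dimnames = list(NULL, "log_eggs"))
      list(egg_density = m)
    },
    none = list()
  )
}

new_sa_design <- function(blocks, data, meta) {
  blocks <- Filter(function(b) ncol(b) > 0, blocks)
  structure(
    list(blocks = blocks, n = nrow(data), row_id = seq_len(nrow(data)),
         meta = meta),
    class = "sa_design"
  )
}

#' Build the dual-generation SA design matrix
#'
#' Constructs the labeled block design for the joint analysis of both assay
#' phases. Term (block) order, which fixes the sequential sums of squares:
#' intercept, population, test environment, genetic SA covariate,
#' origin x test interaction, field-phase population deviations (including
#' the overall field-phase shift), field-phase test-environment deviations,
#' plastic SA covariate, field-phase interaction deviations, then the
#' trait's unit adjustment (arena block for preference, log egg-density
#' covariate for performance, nothing for fecundity).
#'
#' All factors use sum-to-zero contrasts. The genetic SA covariate is the
#' sympatric indicator residualized against the population and
#' test-environment blocks; the plastic SA covariate is the field-phase
#' indicator times the sympatric indicator, residualized against the
#' main-effect and field-deviation blocks. Both live inside their
#' respective interaction spaces once the sequential fit orthogonalizes
#' each block against its predecessors, and each interaction block then
#' retains `(J-1)(K-1) - 1` degrees of freedom after its SA column.
#'
#' @param data An observation tibble spanning both phases (rows already
#'   filtered/transformed as intended for analysis).
#' @param spec A trait name or [trait_spec()] object.
#' @return An object of class `sa_design`: a named list of column blocks in
#'   term order plus row alignment and metadata.
#' @export
build_dual_design <- function(data, spec) {
  spec <- as_trait_spec(spec)
  validate_observations(data)
  if (length(unique(data$phase)) < 2) {
    sa_abort_precondition("dual design requires both 'field' and 'common' phases")
  }
  n <- nrow(data)
  I_field <- as.numeric(data$phase == "field")
  S <- sympatric_indicator(data$test, data$origin)

  intercept <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  pop <- sum_contrast_cols(data$population, "pop.")
  test <- sum_contrast_cols(data$test, "test.")
  inter <- interaction_cols(data$test, data$origin)

  sa_g <- matrix(resid_against(S, cbind(intercept, pop, test)), ncol = 1,
                 dimnames = list(NULL, "sa_genetic"))
  check_sa_contrast(sa_g)

  # Field-phase deltas: the phase indicator itself is part of the
  # delta-population block (one free deviation per population).
  d_pop <- cbind(field = I_field, pop * I_field)
  colnames(d_pop) <- c("field", paste0("d.", colnames(pop)))
  d_test <- test * I_field
  if (ncol(d_test) > 0) colnames(d_test) <- paste0("d.", colnames(test))
  d_inter <- inter * I_field
  if (ncol(d_inter) > 0) colnames(d_inter) <- paste0("d.", colnames(inter))

  # The plastic SA covariate is the raw field-phase sympatric indicator
  # centered against the main-effect and field-deviation blocks only, so the
  # joint-fit estimate attributes a field-only sympatric bonus entirely to
  # plasticity; the sequential fit re-orthogonalizes it against everything
  # that precedes it, so the sequential SS is unaffected by this choice.
  pre_plastic <- cbind(intercept, pop, test, d_pop, d_test)
  sa_p <- matrix(resid_against(I_field * S, pre_plastic), ncol = 1,
                 dimnames = list(NULL, "sa_plastic"))

  blocks <- c(
    list(intercept = intercept, population = pop, test_env = test,
         sa_genetic = sa_g, interaction = inter,
         delta_population = d_pop, delta_test_env = d_test,
         sa_plastic = sa_p, delta_interaction = d_inter),
    tail_block(data, spec)
  )
  new_sa_design(blocks, data, meta = list(
    model = "dual", trait = spec$trait, spec = spec,
    J = length(unique(data$test)), K = length(unique(data$origin)),
    envs = sort(unique(data$test))
  ))
}

#' Build the single-generation SA design matrix
#'
#' Restricts the analysis to one assay phase. Block order: intercept,
#' population, test environment, SA covariate (sympatric indicator
#' residualized against the preceding blocks), origin x test interaction
#' remainder, then the trait's unit adjustment.
#'
#' @inheritParams build_dual_design
#' @param phase `"field"` or `"common"`.
#' @return An object of class `sa_design`.
#' @export
build_single_design <- function(data, spec, phase = c("common", "field")) {
  spec <- as_trait_spec(spec)
  phase <- match.arg(phase)
  validate_observations(data)
  data <- data[data$phase == phase, , drop = FALSE]
  if (nrow(data) == 0) {
    sa_abort_precondition(paste0("no records in phase '", phase, "'"))
  }
  n <- nrow(data)
  S <- sympatric_indicator(data$test, data$origin)
  intercept <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  pop <- sum_contrast_cols(data$population, "pop.")
  test <- sum_contrast_cols(data$test, "test.")
  inter <- interaction_cols(data$test, data$origin)
  sa <- matrix(resid_against(S, cbind(intercept, pop, test)), ncol = 1,
               dimnames = list(NULL, "sa"))
  check_sa_contrast(sa)
  blocks <- c(
    list(intercept = intercept, population = pop, test_env = test,
         sa = sa, interaction = inter),
    tail_block(data, spec)
  )
  new_sa_design(blocks, data, meta = list(
    model = "single", phase = phase, trait = spec$trait, spec = spec,
    J = length(unique(data$test)), K = length(unique(data$origin)),
    envs = sort(unique(data$test))
  ))
}

#' Realize an `sa_design` as a single labeled numeric matrix
#'
#' @param design An `sa_design` object.
#' @param drop Optional character vector of block names to omit (used for
#'   the constrained fits behind the phi statistics).
#' @return A numeric matrix with labeled columns, plus a `"blocks"`
#'   attribute mapping block name to column indices.
#' @export
design_matrix <- function(design, drop = NULL) {
  blocks <- design$blocks
  if (!is.null(drop)) blocks <- blocks[setdiff(names(blocks), drop)]
  X <- do.call(cbind, unname(blocks))
  sizes <- vapply(blocks, ncol, integer(1))
  idx <- split(seq_len(sum(sizes)), rep(names(blocks), sizes))
  attr(X, "blocks") <- idx[names(blocks)]
  X
}

#' @export
print.sa_design <- function(x, ...) {
  sizes <- vapply(x$blocks, ncol, integer(1))
  cat("SA design (", x$meta$model, " model, trait = ", x$meta$trait, "): ",
      x$n, " rows\n", sep = "")
  cat("  blocks (columns): ",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
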
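#' Configure a synthetic reciprocal common-environment experiment
#'
#' The defaults mirror the study layout the package targets: J = 3
#' environments (cherry, strawberry, blackberry), 9/3/13 populations per
#' origin (25 in total), 8 rearing units per population per phase, one
#' observation per unit x test environment, and both assay phases.
#'
#' Effects are drawn on the link scale: population quality, test-environment
#' quality, two independent sum-to-zero origin x test interaction surfaces
#' (one shared across phases, one confined to the field phase), unit
#' effects, and residuals, all zero-mean Gaussian with the configured SDs.
#' `sa_genetic_true` is added to every sympatric record in both phases;
#' `sa_plastic_true` to sympatric records in the field phase only. The link
#' is identity (normal), log with Poisson egg counts (poisson), or logit
#' with Binomial adult counts out of Poisson-distributed egg counts
#' (binomial).
#'
#' @param n_envs Number of environments J (= number of origins K).
#' @param pops_per_env Integer vector of length `n_envs`: populations
#'   collected from each origin environment.
#' @param units_per_pop_phase Rearing units (arenas/vials) per population
#'   per phase.
#' @param obs_per_unit_env Records per unit x test environment.
#' @param family `"normal"`, `"poisson"`, or `"binomial"`.
#' @param mu Baseline on the link scale (trait mean; log mean eggs for
#'   poisson; logit survival for binomial).
#' @param sd_pop,sd_test_env,sd_interaction,sd_unit,sd_res Standard
#'   deviations of the variance components on the link scale.
#' @param sa_genetic_true,sa_plastic_true Injected SA effects (link scale).
#' @param trials_binomial Mean egg count per vial for the binomial family.
#' @param design_multiplier Replication multiplier (see [scale_design()]).
#' @param seed Integer seed; every dataset is a pure function of its config.
#' @return A list of class `sa_sim_config`.
#' @export
sim_config <- function(n_envs = 3,
                       pops_per_env = c(9, 3, 13),
                       units_per_pop_phase = 8,
                       obs_per_unit_env = 1,
                       family = c("normal", "poisson", "binomial"),
                       mu = if (family[1] == "poisson") log(20) else if (family[1] == "binomial") 0 else 5,
                       sd_pop = 0.5,
                       sd_test_env = 0.5,
                       sd_interaction = 0.25,
                       sd_unit = 0.25,
                       sd_res = 0.5,
                       sa_genetic_true = 0,
                       sa_plastic_true = 0,
                       trials_binomial = 20,
                       design_multiplier = 1,
                       seed = 1) {
  family <- match.arg(family)
  if (n_envs < 2) sa_abort_value("n_envs must be >= 2")
  if (length(pops_per_env) != n_envs || any(pops_per_env < 1)) {
    sa_abort_value("pops_per_env must have one positive entry per environment")
  }
  sds <- c(sd_pop, sd_test_env, sd_interaction, sd_unit, sd_res)
  if (any(sds < 0)) sa_abort_value("variance-component SDs must be non-negative")
  if (design_multiplier < 1 || design_multiplier != round(design_multiplier)) {
    sa_abort_value("design_multiplier must be a positive integer")
  }
  if (family == "binomial" &&
      (is.null(trials_binomial) || trials_binomial < 1)) {
    sa_abort_value("binomial family requires trials_binomial >= 1")
  }
  structure(
    list(n_envs = n_envs, pops_per_env = as.integer(pops_per_env),
         units_per_pop_phase = as.integer(units_per_pop_phase),
         obs_per_unit_env = as.integer(obs_per_unit_env),
         family = family, mu = mu, sd_pop = sd_pop, sd_test_env = sd_test_env,
         sd_interaction = sd_interaction, sd_unit = sd_unit, sd_res = sd_res,
         sa_genetic_true = sa_genetic_true, sa_plastic_true = sa_plastic_true,
         trials_binomial = trials_binomial,
         design_multiplier = as.integer(design_multiplier),
         seed = as.integer(seed)),
    class = "sa_sim_config"
  )
}

#' Scale up a simulated design
#'
#' Multiplies the number of rearing units per population per phase, leaving
#' effect sizes and variance components unchanged (the X1/X2/X10/X100
#' design-scaling convention).
#'
#' @param config An [sim_config()] object.
#' @param factor Positive integer multiplier.
#' @return The scaled config.
#' @export
scale_design <- function(config, factor) {
  stopifnot(inherits(config, "sa_sim_config"))
  if (factor < 1 || factor != round(factor)) {
    sa_abort_value("factor must be a positive integer")
  }
  config$units_per_pop_phase <- config$units_per_pop_phase * as.integer(factor)
  config$design_multiplier <- config$design_multiplier * as.integer(factor)
  config
}

default_env_names <- function(J) {
  if (J == 3) c("cherry", "strawberry", "blackberry") else paste0("env", seq_len(J))
}

# Double-center a J x J draw so it is a pure interaction surface.
double_center <- function(M) {
  sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M)) + mean(M)
}

#' Generate a synthetic reciprocal common-environment dataset
#'
#' See [sim_config()] for the generative model. Gaussian data carry the
#' trait value directly in a `response` column (`eggs` is `NA`); Poisson
#' data carry egg counts (analyze as `"fecundity"`); Binomial data carry
#' egg and adult counts (analyze as `"performance"`).
#'
#' @param config An [sim_config()] object.
#' @return A validated observation tibble; deterministic given
#'   `config$seed`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sa_sim_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  J <- config$n_envs
  envs <- default_env_names(J)
  origins <- rep(envs, config$pops_per_env)
  n_pop <- length(origins)
  pops <- sprintf("pop%02d", seq_len(n_pop))

  pop_eff <- rnorm(n_pop, 0, config$sd_pop)
  test_eff <- rnorm(J, 0, config$sd_test_env)
  int_shared <- double_center(matrix(rnorm(J * J, 0, config$sd_interaction), J, J))
  int_field <- double_center(matrix(rnorm(J * J, 0, config$sd_interaction), J, J))
  dimnames(int_shared) <- dimnames(int_field) <- list(envs, envs) # test x origin

  U <- config$units_per_pop_phase
  R <- config$obs_per_unit_env
  grid <- tidyr::expand_grid(
    pop_idx = seq_len(n_pop),
    phase = c("field", "common"),
    unit_idx = seq_len(U),
    test = envs,
    rep = seq_len(R)
  )
  grid$population <- pops[grid$pop_idx]
  grid$origin <- origins[grid$pop_idx]
  grid$unit <- paste(grid$population, substr(grid$phase, 1, 1),
                     sprintf("u%03d", grid$unit_idx), sep = "_")

  unit_key <- unique(grid$unit)
  unit_eff <- setNames(rnorm(length(unit_key), 0, config$sd_unit), unit_key)

  I_field <- as.numeric(grid$phase == "field")
  S <- as.numeric(grid$test == grid$origin)
  eta <- config$mu +
    pop_eff[grid$pop_idx] +
    test_eff[match(grid$test, envs)] +
    int_shared[cbind(grid$test, grid$origin)] +
    I_field * int_field[cbind(grid$test, grid$origin)] +
    config$sa_genetic_true * S +
    config$sa_plastic_true * I_field * S +
    unit_eff[grid$unit] +
    rnorm(nrow(grid), 0, config$sd_res)

  out <- tibble::tibble(
    population = grid$population,
    origin = grid$origin,
    test = grid$test,
    phase = grid$phase,
    unit = grid$unit
  )
  if (config$family == "normal") {
    out$eggs <- NA_integer_
    out$response <- eta
  } else if (config$family == "poisson") {
    out$eggs <- rpois(nrow(out), exp(eta))
  } else {
    eggs <- rpois(nrow(out), config$trials_binomial)
    out$eggs <- eggs
    out$adults <- rbinom(nrow(out), eggs, stats::plogis(eta))
  }
  validate_observations(out)
  out
}

# Per-replicate seeds spawned from a master seed by one draw stream, so
# replicates are independent and individually reproducible.
spawn_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

sim_trait_for_family <- function(family) {
  switch(family, normal = "fecundity", poisson = "fecundity",
         binomial = "performance")
}

run_replicates <- function(config, n_reps, alpha, directional = TRUE) {
  seeds <- spawn_seeds(config$seed, n_reps)
  trait <- sim_trait_for_family(config$family)
  res <- purrr::map(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- seeds[r]
    tab <- generate_dataset(cfg)
    tryCatch({
      fit <- sa_test_dual(tab, trait, compute_phi = FALSE)
      tibble::tibble(
        ok = TRUE,
        est_genetic = fit$genetic$estimate,
        est_plastic = fit$plastic$estimate,
        p_genetic = fit$genetic$p_value,
        p_plastic = fit$plastic$p_value
      )
    }, error = function(e) {
      tibble::tibble(ok = FALSE, est_genetic = NA_real_, est_plastic = NA_real_,
                     p_genetic = NA_real_, p_plastic = NA_real_)
    })
  })
  res <- dplyr::bind_rows(res)
  ok <- res[res$ok & !is.na(res$p_genetic) & !is.na(res$p_plastic), ]
  detect <- function(p, est) {
    if (directional) p < alpha & est > 0 else p < alpha
  }
  n_ok <- nrow(ok)
  rg <- mean(detect(ok$p_genetic, ok$est_genetic))
  rp <- mean(detect(ok$p_plastic, ok$est_plastic))
  tibble::tibble(
    family = config$family,
    layout = paste(config$pops_per_env, collapse = "/"),
    design_multiplier = config$design_multiplier,
    sa_genetic_true = config$sa_genetic_true,
    sa_plastic_true = config$sa_plastic_true,
    alpha = alpha,
    directional = directional,
    n_reps = n_reps,
    n_estimable = n_ok,
    n_inestimable = n_reps - n_ok,
    reject_rate_genetic = rg,
    reject_rate_plastic = rp,
    mc_se_genetic = sqrt(rg * (1 - rg) / n_ok),
    mc_se_plastic = sqrt(rp * (1 - rp) / n_ok),
    mean_est_genetic = mean(ok$est_genetic),
    mean_est_plastic = mean(ok$est_plastic),
    sd_est_genetic = sd(ok$est_genetic),
    sd_est_plastic = sd(ok$est_plastic)
  )
}

#' Estimate the false-positive rate of the dual SA tests
#'
#' Runs generate -> transform -> [sa_test_dual()] over `n_reps` null
#' replicates and reports the fraction detecting a genetic or plastic
#' effect at level `alpha`, with Monte-Carlo standard errors. Detection is
#' directional by default: a replicate counts as a false positive when the
#' F test rejects *and* the SA estimate is positive, matching the
#' interpretation that only a significant positive contrast supports local
#' adaptation or adaptive plasticity. Replicates with an inestimable model
#' are excluded from the rate and counted separately.
#'
#' @param null_config An [sim_config()] with both true SA effects zero.
#' @param n_reps Number of replicates.
#' @param alpha Nominal test level.
#' @param directional Count only positive-estimate rejections (default);
#'   set `FALSE` for the raw two-sided F rejection rate.
#' @return A one-row tibble of class `sa_power_result`.
#' @export
estimate_fpr <- function(null_config, n_reps = 1000, alpha = 0.05,
                         directional = TRUE) {
  stopifnot(inherits(null_config, "sa_sim_config"))
  if (null_config$sa_genetic_true != 0 || null_config$sa_plastic_true != 0) {
    sa_abort_precondition("null_config must have both true SA effects equal to zero")
  }
  if (alpha < 0 || alpha > 1) sa_abort_value("alpha must be in [0, 1]")
  out <- run_replicates(null_config, n_reps, alpha, directional)
  class(out) <- c("sa_power_result", class(out))
  out
}

#' Estimate power across a grid of simulation conditions
#'
#' One [run][estimate_fpr] per condition; conditions typically vary the
#' injected SA effect sizes and/or the design multiplier.
#'
#' @param config_grid A list of [sim_config()] objects.
#' @param n_reps Replicates per condition.
#' @param alpha Nominal test level.
#' @param directional Count only positive-estimate rejections (default).
#' @return A tibble of class `sa_power_result`, one row per condition.
#' @export
estimate_power <- function(config_grid, n_reps = 500, alpha = 0.05,
                           directional = TRUE) {
  if (inherits(config_grid, "sa_sim_config")) config_grid <- list(config_grid)
  if (alpha < 0 || alpha > 1) sa_abort_value("alpha must be in [0, 1]")
  out <- purrr::map(config_grid, run_replicates, n_reps = n_reps,
                    alpha = alpha, directional = directional) |>
    dplyr::bind_rows()
  class(out) <- c("sa_power_result", class(out))
  out
}
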
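noise_free <- function(sa_genetic = 0, sa_plastic = 0, sd_pop = 0, sd_test = 0) {
  sim_config(pops_per_env = c(3, 3, 3), units_per_pop_phase = 2,
             sd_pop = sd_pop, sd_test_env = sd_test, sd_interaction = 0,
             sd_unit = 0, sd_res = 0, sa_genetic_true = sa_genetic,
             sa_plastic_true = sa_plastic, family = "normal", seed = 41)
}

test_that("noise-free injections are recovered exactly, with undefined F flagged", {
  fit <- sa_test_dual(generate_dataset(noise_free(sa_genetic = 1)), "fecundity")
  expect_equal(fit$genetic$estimate, 1, tolerance = 1e-10)
  expect_equal(fit$plastic$estimate, 0, tolerance = 1e-10)
  expect_equal(fit$genetic$phi, 1, tolerance = 1e-10)
  expect_true(fit$genetic$f_undefined)
  expect_true(is.na(fit$genetic$p_value))

  fit2 <- sa_test_dual(generate_dataset(noise_free(sa_plastic = 0.7)), "fecundity")
  expect_equal(fit2$plastic$estimate, 0.7, tolerance = 1e-10)
  expect_equal(fit2$genetic$estimate, 0, tolerance = 1e-10)
  expect_equal(fit2$plastic$phi, 1, tolerance = 1e-10)

  # pure main effects leave the SA contrast at zero
  fit3 <- sa_test_dual(generate_dataset(noise_free(sd_pop = 0.8, sd_test = 0.6)),
                       "fecundity")
  expect_equal(fit3$genetic$estimate, 0, tolerance = 1e-10)
  expect_equal(fit3$plastic$estimate, 0, tolerance = 1e-10)

  single <- sa_test_single(generate_dataset(noise_free(sa_genetic = 0.7)),
                           "fecundity", phase = "common")
  expect_equal(single$sa$estimate, 0.7, tolerance = 1e-10)
  expect_true(single$sa$f_undefined)
})

test_that("dual F statistics and phi match the nested-model refit oracle", {
  for (family in c("normal", "poisson")) {
    tab <- generate_dataset(tiny_config(family = family, seed = 42))
    tab <- transform_response(tab, "fecundity")
    fit <- sa_test_dual(tab, "fecundity")
    d <- build_dual_design(tab, "fecundity")
    oracle <- oracle_sequential(d, tab$response)
    ss <- setNames(oracle$ss, oracle$term)
    df <- setNames(oracle$df, oracle$term)
    F_g <- (ss[["sa_genetic"]] / 1) / (ss[["interaction"]] / df[["interaction"]])
    F_p <- (ss[["sa_plastic"]] / 1) /
      (ss[["delta_interaction"]] / df[["delta_interaction"]])
    expect_equal(fit$genetic$statistic, unname(F_g), tolerance = 1e-8)
    expect_equal(fit$plastic$statistic, unname(F_p), tolerance = 1e-8)
    expect_equal(fit$genetic$phi,
                 oracle_phi(d, tab$response, "sa_genetic", "interaction"),
                 tolerance = 1e-8)
    expect_equal(fit$plastic$phi,
                 oracle_phi(d, tab$response, "sa_plastic", "delta_interaction"),
                 tolerance = 1e-8)
    # estimates equal the joint-fit coefficients from an independent lm()
    # on the reduced full-rank parameterization
    b <- d$blocks
    int_rem <- b$interaction - b$sa_genetic %*%
      solve(crossprod(b$sa_genetic), crossprod(b$sa_genetic, b$interaction))
    dint_rem <- b$delta_interaction - b$sa_plastic %*%
      solve(crossprod(b$sa_plastic), crossprod(b$sa_plastic, b$delta_interaction))
    X <- cbind(b$intercept, b$population, b$test_env, int_rem,
               b$delta_population, b$delta_test_env, dint_rem,
               b$sa_genetic, b$sa_plastic)
    co <- lm(tab$response ~ 0 + X)$coefficients
    expect_equal(unname(co["Xsa_genetic"]), fit$genetic$estimate, tolerance = 1e-8)
    expect_equal(unname(co["Xsa_plastic"]), fit$plastic$estimate, tolerance = 1e-8)
  }
})

test_that("estimates recover the injected genetic effect on average", {
  cfg <- tiny_config(family = "normal", sa_genetic_true = 0.3, seed = 43)
  seeds <- withr::with_seed(43, sample.int(1e6, 200))
  ests <- vapply(seeds, function(s) {
    cfg$seed <- s
    sa_test_dual(generate_dataset(cfg), "fecundity", compute_phi = FALSE)$genetic$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.3), 2 * sd(ests) / sqrt(length(ests)))
})

test_that("the single-generation null test rejects at no more than the nominal rate", {
  cfg <- tiny_config(family = "normal", seed = 44)
  seeds <- withr::with_seed(44, sample.int(1e6, 400))
  rej <- vapply(seeds, function(s) {
    cfg$seed <- s
    fit <- sa_test_single(generate_dataset(cfg), "fecundity", phase = "common",
                          compute_phi = FALSE)
    fit$sa$p_value < 0.05
  }, logical(1))
  rate <- mean(rej)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / length(rej)))
})

test_that("results expose tidy, glance, JSON, and plotting surfaces", {
  tab <- generate_dataset(tiny_config(family = "poisson", seed = 45))
  fit <- sa_test_dual(tab, "fecundity")
  td <- tidy(fit)
  expect_equal(td$component, c("genetic", "plastic"))
  expect_named(td, c("component", "estimate", "se", "statistic", "df_num",
                     "df_den", "p_value", "phi"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, nrow(tab))

  parsed <- jsonlite::fromJSON(sa_result_json(fit))
  expect_equal(parsed$schema, "sadapt/sa_result/v1")
  expect_named(parsed$components, c("genetic", "plastic"))
  expect_equal(parsed$components$genetic$estimate, fit$genetic$estimate)
  expect_s3_class(autoplot(fit), "ggplot")

  single <- sa_test_single(tab, "fecundity")
  expect_equal(tidy(single)$component, "sa")
  expect_equal(glance(single)$phase, "common")
})
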
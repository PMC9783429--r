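test_that("weighted Pearson reduces to ordinary Pearson and obeys invariances", {
  set.seed(51)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  w <- rep(2.5, 20)
  expect_equal(weighted_pearson(x, y, w)$rho, cor(x, y), tolerance = 1e-12)

  # perfect linear relation
  expect_equal(weighted_pearson(x, 2 * x + 1, rep(1, 20))$rho, 1, tolerance = 1e-12)

  # affine invariance in x and y, scale invariance in w
  w2 <- rpois(20, 5) + 1
  base <- weighted_pearson(x, y, w2)
  expect_equal(weighted_pearson(3 * x - 2, -0.5 * y + 7, w2)$rho, -base$rho,
               tolerance = 1e-12)
  expect_equal(weighted_pearson(x, y, 10 * w2)$rho, base$rho, tolerance = 1e-12)
})

test_that("the three-point weighted example matches the direct formula", {
  x <- c(1, 2, 3); y <- c(1, 2, 4); w <- c(1, 1, 2)
  # independent direct computation of the weighted product-moment formula
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  rho_direct <- sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  out <- weighted_pearson(x, y, w)
  expect_equal(out$rho, rho_direct, tolerance = 1e-12)
  expect_equal(out$rho, 0.986440, tolerance = 1e-5)
  expect_equal(out$n_eff, 16 / 6, tolerance = 1e-12)
})

test_that("degenerate weighted correlations are flagged", {
  expect_warning(out <- weighted_pearson(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)),
                 "zero weighted variance")
  expect_true(is.nan(out$rho))
  expect_error(weighted_pearson(1:3, 1:3, c(1, -1, 1)), class = "sadapt_value_error")
  expect_error(weighted_pearson(1:2, 1:2, c(1, 1)), class = "sadapt_precondition_error")
})

test_that("Fisher-z intervals cover zero for independent data at roughly the nominal rate", {
  covered <- withr::with_seed(52, vapply(1:200, function(i) {
    x <- rnorm(40); y <- rnorm(40); w <- rpois(40, 6) + 1
    ci <- weighted_pearson(x, y, w)
    ci$ci_low <= 0 && ci$ci_high >= 0
  }, logical(1)))
  expect_gte(mean(covered), 0.9)
})

test_that("effect means match an explicit two-step projection oracle", {
  tab <- generate_dataset(tiny_config(family = "normal", seed = 53,
                                      sa_genetic_true = 0.4))
  cells <- effect_means(tab, "fecundity")

  # oracle: lm residuals of the nuisance model, then cell averages
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  res <- residuals(lm(response ~ factor(population) + factor(test), data = tab))
  agg <- tapply(res, list(tab$test, tab$origin, tab$phase), mean)
  for (i in seq_len(nrow(cells))) {
    g <- agg[cells$test[i], cells$origin[i], "common"]
    f <- agg[cells$test[i], cells$origin[i], "field"]
    expect_equal(cells$genetic_mean[i], unname(g), tolerance = 1e-10)
    expect_equal(cells$plastic_mean[i], unname(f - g), tolerance = 1e-10)
  }
})

test_that("effect means are shift-invariant and vanish when phases coincide", {
  tab <- generate_dataset(tiny_config(family = "normal", seed = 54))
  cells <- effect_means(tab, "fecundity")
  shifted <- tab
  shifted$response <- shifted$response + 11
  cells2 <- effect_means(shifted, "fecundity")
  expect_equal(cells2$genetic_mean, cells$genetic_mean, tolerance = 1e-10)
  expect_equal(cells2$plastic_mean, cells$plastic_mean, tolerance = 1e-10)

  # copy common-phase responses into the field phase cell-for-cell
  mirror <- tab[tab$phase == "common", ]
  field <- mirror
  field$phase <- "field"
  field$unit <- paste0(field$unit, "_f")
  both <- rbind(mirror, field)
  cells3 <- effect_means(both, "fecundity")
  expect_equal(cells3$plastic_mean, rep(0, nrow(cells3)), tolerance = 1e-10)
})

test_that("original-vs-alternative pairs each population with its allopatric means", {
  toy <- tibble::tibble(
    population = "P1", origin = "cherry",
    test = c("cherry", "strawberry", "blackberry"),
    phase = "common", unit = c("v1", "v2", "v3"),
    eggs = NA_integer_, response = c(2.0, 1.0, 1.5))
  out <- original_vs_alternative(toy, "fecundity")
  expect_equal(nrow(out), 2)
  expect_equal(unique(out$mean_original), 2.0)
  expect_equal(sort(out$mean_alternative), c(1.0, 1.5))
  expect_equal(unique(out$n_vials), 3L)

  # identical values everywhere put every point on the identity line
  flat <- generate_dataset(tiny_config(family = "normal", sd_pop = 0,
                                       sd_test_env = 0, sd_interaction = 0,
                                       sd_unit = 0, sd_res = 0, seed = 55))
  flat_out <- original_vs_alternative(flat, "fecundity")
  expect_equal(flat_out$mean_alternative, flat_out$mean_original)

  # a sympatric bonus pushes allopatric points below the identity line
  adv <- generate_dataset(tiny_config(family = "normal", sa_genetic_true = 1,
                                      seed = 56))
  adv_out <- original_vs_alternative(adv, "fecundity")
  expect_gt(mean(adv_out$mean_alternative < adv_out$mean_original), 0.5)

  # populations without sympatric assays are dropped with a warning
  nosym <- generate_dataset(tiny_config(family = "normal", seed = 57))
  nosym <- nosym[!(nosym$population == "pop01" & nosym$test == nosym$origin), ]
  expect_warning(out2 <- original_vs_alternative(nosym, "fecundity"),
                 "without sympatric")
  expect_false("pop01" %in% out2$population)
})

test_that("cross-generation correlations track shared population quality", {
  tab <- generate_dataset(tiny_config(family = "normal", seed = 58))
  mirror <- tab[tab$phase == "common", ]
  field <- mirror
  field$phase <- "field"
  field$unit <- paste0(field$unit, "_f")
  out <- cross_generation_correlation(rbind(mirror, field), "fecundity")
  expect_equal(out$rho, rep(1, nrow(out)), tolerance = 1e-10)

  # strong shared population quality, weak noise: positive correlation
  strong <- generate_dataset(tiny_config(family = "normal", sd_pop = 2,
                                         sd_res = 0.2, sd_unit = 0.1,
                                         seed = 59))
  out2 <- cross_generation_correlation(strong, "fecundity")
  expect_true(all(out2$rho > 0))
})

test_that("preference-performance correlation detects affine dependence", {
  pref <- generate_dataset(tiny_config(family = "poisson", mu = log(20), seed = 60))
  pref_res <- transform_response(pref, "preference")
  # performance table built so its response is an affine map of preference
  perf <- pref_res
  perf$unit <- paste0(perf$unit, "_p")
  perf$response <- 0.3 * perf$response + 0.1
  out <- preference_performance_correlation(pref_res, perf,
                                            perf_spec = trait_spec("preference"))
  expect_equal(out$rho, 1, tolerance = 1e-8)

  # a shared sympatric bonus in both traits gives a positive correlation
  shared_pref <- generate_dataset(tiny_config(family = "normal",
                                              sa_genetic_true = 1.5,
                                              sd_interaction = 0.05, seed = 61))
  shared_perf <- generate_dataset(tiny_config(family = "normal",
                                              sa_genetic_true = 1.5,
                                              sd_interaction = 0.05, seed = 62))
  shared_perf$unit <- paste0(shared_perf$unit, "_p")
  out2 <- preference_performance_correlation(shared_pref, shared_perf,
                                             pref_spec = trait_spec("preference"),
                                             perf_spec = trait_spec("fecundity"))
  expect_gt(out2$rho, 0)

  # mismatched population sets are dropped with a warning
  sub <- shared_perf[shared_perf$population != "pop01", ]
  expect_warning(
    preference_performance_correlation(shared_pref, sub,
                                       pref_spec = trait_spec("preference"),
                                       perf_spec = trait_spec("fecundity")),
    "only one table")
})
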
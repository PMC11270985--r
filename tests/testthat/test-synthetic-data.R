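test_that("the forward model reduces to the bare curve when all stresses are zero", {
  cfg <- synthetic_config(
    stress_prochloraz = c(`0` = 0, `1` = 0, `10` = 0),
    stress_temperature = c(`16` = 0, `19` = 0, `22` = 0),
    adaptation_cost = 0)
  grid <- expected_survival_grid(cfg)
  ref <- dplyr::filter(grid, population == "reference")
  expect_equal(ref$expected_survival,
               1 - ll5_effect(ref$clothianidin_conc, 2, 0, 1, 67, 1),
               tolerance = 1e-12)
})

test_that("identical seeds give identical tables; different seeds differ", {
  cfg <- quick_config(seed = 123)
  t1 <- generate_experiment(cfg)
  t2 <- generate_experiment(cfg)
  expect_identical(t1$n_immobile, t2$n_immobile)
  t3 <- generate_experiment(quick_config(seed = 124))
  expect_false(identical(t1$n_immobile, t3$n_immobile))
})

test_that("adding a condition does not perturb other cells' draws", {
  base <- generate_experiment(quick_config(seed = 5))
  wider <- generate_experiment(quick_config(
    seed = 5, doses = c(0, 0.01, 0.1, 1, 10, 50, 100, 215, 465, 1000)))
  key <- function(d) paste(d$population, d$temperature, d$prochloraz_conc,
                           d$clothianidin_conc, d$stream, d$replicate)
  shared <- intersect(key(base), key(wider))
  expect_equal(base$n_immobile[match(shared, key(base))],
               wider$n_immobile[match(shared, key(wider))])
})

test_that("expected immobility is nondecreasing in dose and in each stress source", {
  cfg <- synthetic_config()
  grid <- expected_survival_grid(cfg)
  by_cond <- dplyr::group_by(grid, population, temperature, prochloraz_conc)
  ordered <- dplyr::arrange(by_cond, clothianidin_conc, .by_group = TRUE)
  mono <- dplyr::summarise(ordered,
                           ok = all(diff(1 - expected_survival) >= -1e-12),
                           .groups = "drop")
  expect_true(all(mono$ok))
  # more co-toxicant stress and warmer water both lower expected survival
  wide <- tidyr::pivot_wider(
    dplyr::select(grid, population, temperature, prochloraz_conc,
                  clothianidin_conc, expected_survival),
    names_from = prochloraz_conc, values_from = expected_survival)
  expect_true(all(wide$`1` <= wide$`0` + 1e-12 & wide$`10` <= wide$`1` + 1e-12))
  wideT <- tidyr::pivot_wider(
    dplyr::select(grid, population, temperature, prochloraz_conc,
                  clothianidin_conc, expected_survival),
    names_from = temperature, values_from = expected_survival)
  expect_true(all(wideT$`19` <= wideT$`16` + 1e-12 &
                    wideT$`22` <= wideT$`19` + 1e-12))
})

test_that("with zero stresses the fitted group EC50s recover the configured truth", {
  cfg <- synthetic_config(
    seed = 77,
    stress_prochloraz = c(`0` = 0, `1` = 0, `10` = 0),
    stress_temperature = c(`16` = 0, `19` = 0, `22` = 0),
    adaptation_cost = 0,
    n_per_treatment = 200, n_streams = c(reference = 1, agricultural = 1),
    prochloraz_levels = 0, temperatures = 16)
  tab <- generate_experiment(cfg)
  for (spec_pop in list(c("reference", 67), c("agricultural", 148))) {
    fit <- fit_ll5(dplyr::filter(tab, population == spec_pop[1]))
    ci <- ec_x(fit, 50)
    truth <- as.numeric(spec_pop[2])
    expect_gt(truth, ci$ci_low)
    expect_lt(truth, ci$ci_high)
  }
})

test_that("temperature stress lowers the fitted EC50 in expectation across seeds", {
  ec50s <- t(vapply(1:50, function(s) {
    cfg <- synthetic_config(seed = s, prochloraz_levels = 0,
                            n_streams = c(reference = 4, agricultural = 4))
    tab <- generate_experiment(cfg)
    ref <- dplyr::filter(tab, population == "reference")
    e16 <- ec_x(fit_ll5(dplyr::filter(ref, temperature == 16)), 50,
                ci_method = "delta")$dose
    e22 <- ec_x(fit_ll5(dplyr::filter(ref, temperature == 22)), 50,
                ci_method = "delta")$dose
    c(e16 = e16, e22 = e22)
  }, numeric(2)))
  # direction of effect in expectation, and a decisive Monte-Carlo sign test
  expect_lt(mean(ec50s[, "e22"]), mean(ec50s[, "e16"]))
  sign_p <- stats::binom.test(sum(ec50s[, "e22"] < ec50s[, "e16"]),
                              nrow(ec50s), 0.5,
                              alternative = "greater")$p.value
  expect_lt(sign_p, 1e-4)
})

test_that("the ground-truth sidecar travels with the table", {
  cfg <- quick_config(seed = 2)
  tab <- generate_experiment(cfg)
  gt <- ground_truth(tab)
  expect_identical(gt$config$seed, 2L)
  expect_true("expected_survival" %in% names(gt$expected))
  expect_error(ground_truth(data.frame(x = 1)),
               class = "multistress_domain_error")
})

test_that("invalid config fields are rejected by name", {
  expect_error(synthetic_config(doses = c(1, 10, 100)), "doses",
               class = "multistress_validation_error")
  expect_error(synthetic_config(adaptation_cost = -0.1), "adaptation_cost",
               class = "multistress_validation_error")
  expect_error(synthetic_config(n_per_treatment = 0), "n_per_treatment",
               class = "multistress_validation_error")
  expect_error(
    synthetic_config(stress_temperature = c(`16` = 0, `19` = 0.1)),
    "stress_temperature", class = "multistress_validation_error")
})

test_that("site tables are deterministic, configurable and recover the trend", {
  s0 <- generate_site_table(n_sites = 12, noise_sd = 0, seed = 1)
  expect_equal(nrow(s0), 12)
  reg0 <- suppressWarnings(site_index_regression(s0))  # exact fit warning
  expect_equal(reg0$r_squared, 1, tolerance = 1e-12)
  expect_equal(reg0$slope, -0.13, tolerance = 1e-9)

  s1 <- generate_site_table(n_sites = 100, seed = 9)
  expect_identical(s1, generate_site_table(n_sites = 100, seed = 9))
  reg1 <- site_index_regression(s1)
  m <- attr(reg1, "model")
  ci <- stats::confint(m)["tu_log10", ]
  expect_gt(-0.13, ci[1]); expect_lt(-0.13, ci[2])
  expect_error(generate_site_table(n_sites = 2),
               class = "multistress_validation_error")
})
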
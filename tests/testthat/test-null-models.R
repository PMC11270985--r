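test_that("effect addition follows Bliss independence with its identities", {
  expect_equal(ea_combined_effect(0.5), 0.5)              # singleton
  expect_equal(ea_combined_effect(c(0.5, 0)), 0.5)        # null component
  expect_equal(ea_combined_effect(c(0.5, 0.2)), 0.6)      # 1 - 0.5*0.8
  expect_equal(ea_combined_effect(numeric(0)), 0)
  expect_error(ea_combined_effect(c(0.5, 1.2)),
               class = "multistress_domain_error")
  # order invariance and fold associativity on random cases
  withr::with_seed(4, for (i in 1:25) {
    e <- runif(sample(2:6, 1))
    expect_equal(ea_combined_effect(e), ea_combined_effect(rev(e)))
    expect_equal(ea_combined_effect(e),
                 ea_combined_effect(c(ea_combined_effect(e[1:2]), e[-(1:2)])))
  })
})

test_that("concentration addition is the reciprocal fraction-weighted sum", {
  expect_equal(ca_combined_ecx(c(0.5, 0.5), c(100, 100)), 100)  # sham mixture
  expect_equal(ca_combined_ecx(c(1, 0), c(42, 7)), 42)          # degenerate
  expect_error(ca_combined_ecx(c(0.6, 0.6), c(1, 1)),
               class = "multistress_domain_error")
  expect_error(ca_combined_ecx(c(0.5, 0.5), c(0, 10)),
               class = "multistress_domain_error")
  # random 5-component mixtures against the direct summation oracle
  withr::with_seed(8, for (i in 1:50) {
    p <- runif(5); p <- p / sum(p)
    ecx <- runif(5, 1, 500)
    expect_equal(ca_combined_ecx(p, ecx), 1 / sum(p / ecx), tolerance = 1e-12)
  })
  # sham combination at any split of the same compound
  withr::with_seed(9, for (i in 1:20) {
    p <- runif(4); p <- p / sum(p)
    expect_equal(ca_combined_ecx(p, rep(123.4, 4)), 123.4, tolerance = 1e-12)
  })
})

test_that("a null co-stressor leaves the predicted EC50 unchanged under both models", {
  fit <- fit_ll5(exact_curve_table(b = 2, e = 100, f = 1))
  ec50 <- ec_x(fit, 50)$dose
  expect_equal(predict_ec50_with_costressor(fit, 0, "ea"), ec50,
               tolerance = 1e-8)
  expect_equal(predict_ec50_with_costressor(fit, 0, "ca"), ec50,
               tolerance = 1e-8)
})

test_that("the EA prediction equals an independent grid/bisection oracle", {
  fit <- fit_ll5(exact_curve_table(b = 2, c = 0.05, d = 0.95, e = 100, f = 1))
  for (ec in c(0.05, 0.1, 0.3)) {
    got <- predict_ec50_with_costressor(fit, ec, "ea")
    # oracle: dense grid search for the midpoint crossing of the combined
    # effect between co-stressed control and co-stressed maximum
    grid <- 10^seq(-4, 6, length.out = 400001)
    comb <- 1 - (1 - effect_at(fit, grid)) * (1 - ec)
    lo <- 1 - (1 - effect_at(fit, 0)) * (1 - ec)
    hi <- 1 - (1 - fit$par[["d"]]) * (1 - ec)
    target <- lo + 0.5 * (hi - lo)
    oracle <- grid[which.max(comb >= target)]
    expect_equal(got, oracle, tolerance = 1e-4)
  }
})

test_that("predictions are nonincreasing in the co-stressor effect for both models", {
  fit <- fit_ll5(exact_curve_table(b = 1.5, c = 0.02, d = 0.98, e = 60, f = 2))
  for (model in c("ea", "ca")) {
    preds <- vapply(seq(0, 0.45, by = 0.05),
                    function(ec) predict_ec50_with_costressor(fit, ec, model),
                    numeric(1))
    expect_true(all(diff(preds) <= 1e-8))
  }
})

test_that("a co-stressor reaching the effect criterion admits no finite prediction", {
  fit <- fit_ll5(exact_curve_table(b = 2, e = 100))
  expect_error(predict_ec50_with_costressor(fit, 0.6, "ea"),
               class = "multistress_domain_error")
  expect_error(predict_ec50_with_costressor(fit, 0.5, "ca"),
               class = "multistress_domain_error")
})

test_that("model deviation ratios reproduce the printed comparison values", {
  expect_equal(round(mdr(40.32, 25.41), 2), 1.59)
  expect_equal(round(mdr(145.34, 175.49), 2), 0.83)
  expect_equal(round(mdr(66.46, 24.67), 2), 2.69)
  expect_equal(mdr(7, 7), 1)
  expect_error(mdr(-1, 2), class = "multistress_domain_error")
  expect_error(mdr(1, 0), class = "multistress_domain_error")
})

test_that("MDR classification partitions the positive axis with documented boundaries", {
  expect_equal(as.character(classify_mdr(0.4)), "antagonism")
  expect_equal(as.character(classify_mdr(0.5)), "additive")
  expect_equal(as.character(classify_mdr(1)), "additive")
  expect_equal(as.character(classify_mdr(1.59)), "weak_synergism")
  expect_equal(as.character(classify_mdr(2)), "weak_synergism")
  expect_equal(as.character(classify_mdr(2.69)), "strong_synergism")
  # no gaps, no overlaps: every positive value gets exactly one class
  vals <- withr::with_seed(3, c(runif(500, 1e-6, 5), 0.5, 1, 2))
  cls <- classify_mdr(vals)
  expect_false(any(is.na(cls)))
  expect_equal(length(cls), length(vals))
})
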
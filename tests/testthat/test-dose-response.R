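test_that("the effect function honours its closed-form anchor points", {
  expect_equal(ll5_effect(100, 2, 0, 1, 100, 1), 0.5)
  expect_equal(ll5_effect(0, 2, 0.1, 0.9, 100, 1), 0.1)     # control on asymptote
  expect_equal(ll5_effect(100, 2, 0, 1, 100, 3), 1 / 2^3)   # asymmetry at e
  expect_error(ll5_effect(-1, 2, 0, 1, 100, 1),
               class = "multistress_domain_error")
})

test_that("simulated curves are recovered with the true EC50 inside its CI", {
  tab <- noisy_curve_table(seed = 11, e = 100, n = 200)
  fit <- fit_ll5(tab)
  expect_true(fit$converged)
  ci <- ec_x(fit, 50)
  expect_gt(100, ci$ci_low)
  expect_lt(100, ci$ci_high)
  expect_lt(abs(log(ci$dose / 100)), 0.2)
})

test_that("refitting the same table is bit-identical (no RNG in fitting)", {
  tab <- noisy_curve_table(seed = 5, n = 12)
  f1 <- fit_ll5(tab); f2 <- fit_ll5(tab)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("fits are invariant to row order and replicate splitting", {
  tab <- noisy_curve_table(seed = 9, n = 24)
  f0 <- fit_ll5(tab)
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  expect_equal(fit_ll5(shuffled)$par, f0$par)
  split <- rbind(
    transform(tab, n_exposed = 12, n_immobile = pmin(n_immobile, 12)),
    transform(tab, n_exposed = 12, n_immobile = n_immobile - pmin(n_immobile, 12)))
  expect_equal(fit_ll5(split)$par, f0$par, tolerance = 1e-8)
})

test_that("degenerate all-or-nothing step data raise a fit error, never a silent fit", {
  step <- data.frame(dose = c(0, 1, 10, 100, 1000), n_exposed = 12,
                     n_immobile = c(0, 0, 0, 12, 12))
  expect_error(fit_ll5(step), class = "multistress_fit_error")
  flat <- data.frame(dose = c(0, 1, 10, 100, 1000), n_exposed = 12,
                     n_immobile = 0)
  expect_error(fit_ll5(flat), class = "multistress_fit_error")
  expect_error(fit_ll5(data.frame(dose = c(1, 10, 100, 215, 465),
                                  n_exposed = 12, n_immobile = 1:5)),
               class = "multistress_validation_error")  # no control dose
})

test_that("ec_x inverts effect_at: closed form matches a bracketing-root oracle", {
  # the oracle solves effect(dose) = rescaled target by bisection, fully
  # independently of the closed-form inversion in ec_x
  oracle_ecx <- function(fit, x) {
    p <- fit$par
    target <- p[["c"]] + (x / 100) * (p[["d"]] - p[["c"]])
    uniroot(function(u) effect_at(fit, u) - target,
            c(1e-8, 1e10), tol = 1e-12)$root
  }
  sym <- fit_ll5(exact_curve_table(b = 2, e = 100, f = 1))
  expect_equal(ec_x(sym, 50)$dose, 100, tolerance = 1e-3)
  asym <- fit_ll5(exact_curve_table(b = 1.5, e = 80, f = 3))
  for (fit in list(sym, asym)) {
    for (x in c(10, 50, 90)) {
      expect_equal(ec_x(fit, x)$dose, oracle_ecx(fit, x), tolerance = 1e-6)
    }
  }
  # with f != 1 the EC50 is not the inflection dose
  expect_gt(abs(ec_x(asym, 50)$dose - asym$par[["e"]]), 1)
})

test_that("effect_at is monotone over six decades and anchored at the asymptote", {
  fit <- fit_ll5(exact_curve_table(b = 1.2, c = 0.05, d = 0.95, e = 50, f = 2))
  expect_equal(effect_at(fit, 0), fit$par[["c"]])
  doses <- 10^seq(-3, 3, length.out = 1000)
  eff <- effect_at(fit, doses)
  expect_true(all(diff(eff) >= -1e-12))
  expect_true(all(eff >= fit$par[["c"]] - 1e-9 & eff <= fit$par[["d"]] + 1e-9))
  expect_error(effect_at(fit, -5), class = "multistress_domain_error")
})

test_that("absolute ECx targets the unscaled effect fraction and errors out of range", {
  fit <- fit_ll5(exact_curve_table(b = 2, c = 0.2, d = 0.9, e = 100, f = 1))
  abs50 <- ec_x(fit, 50, type = "absolute")
  expect_equal(effect_at(fit, abs50$dose), 0.5, tolerance = 1e-6)
  rel50 <- ec_x(fit, 50, type = "relative")
  expect_equal(effect_at(fit, rel50$dose),
               0.2 + 0.5 * (fit$par[["d"]] - 0.2), tolerance = 1e-6)
  expect_error(ec_x(fit, 95, type = "absolute"),
               class = "multistress_domain_error")
  expect_error(ec_x(fit, 150), class = "multistress_domain_error")
})

test_that("the least-squares cross-check path agrees with ML on clean data", {
  tab <- exact_curve_table(b = 2, e = 100, n = 1e4)
  ml <- fit_ll5(tab, method = "ml")
  ls <- fit_ll5(tab, method = "ls")
  expect_equal(ec_x(ls, 50)$dose, ec_x(ml, 50)$dose, tolerance = 1e-2)
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_ll5(noisy_curve_table(seed = 2, n = 50))
  td <- tidy(fit)
  expect_tibble(td)
  expect_equal(td$term, c("b", "c", "d", "e", "f"))
  expect_true(all(td$std.error >= 0, na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(gl$nobs, sum(fit$data$n_exposed))
  expect_true(gl$converged)
})
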
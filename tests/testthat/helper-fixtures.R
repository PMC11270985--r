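# Shared fixtures, built in code at test time.

# Deterministic "large-n" table following a known five-parameter curve:
# expected counts rounded, so the fitted curve is essentially the truth.
exact_curve_table <- function(b = 2, c = 0, d = 1, e = 100, f = 1,
                              doses = c(0, 0.01, 0.1, 1, 10, 100, 215, 465, 1000),
                              n = 1e5) {
  eff <- ll5_effect(doses, b, c, d, e, f)
  data.frame(dose = doses, n_exposed = n, n_immobile = round(n * eff))
}

# Binomial draw around a known curve at a given per-dose n.
noisy_curve_table <- function(seed, b = 2, c = 0, d = 1, e = 100, f = 1,
                              doses = c(0, 0.01, 0.1, 1, 10, 100, 215, 465, 1000),
                              n = 12) {
  eff <- ll5_effect(doses, b, c, d, e, f)
  withr::with_seed(seed,
    data.frame(dose = doses, n_exposed = n,
               n_immobile = rbinom(length(doses), n, eff)))
}

# A small, quick synthetic design for pipeline tests: one stream per class.
quick_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, n_streams = c(reference = 2, agricultural = 2),
                   ...)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
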
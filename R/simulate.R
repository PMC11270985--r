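#' Configuration of a synthetic multi-stressor experiment
#'
#' Describes a full-factorial acute-toxicity experiment: a dose series of the
#' primary toxicant crossed with co-toxicant levels and temperatures, for one
#' or more populations with known true dose-response curves, plus the true
#' General-Stress contributed by each co-stressor level. Defaults emulate the
#' study design the package targets: nine clothianidin concentrations
#' (0, 0.01, 0.1, 1, 10, 100, 215, 465, 1000 µg/L) x three prochloraz levels
#' (0, 1, 10 µg/L) x three temperatures (16, 19, 22 °C), twelve animals per
#' treatment in three replicate vessels of four, and reference/agricultural
#' populations with 16 °C EC50s of 67 and 148 µg/L.
#'
#' True stress magnitudes are fixture choices placed so that default runs
#' span the weak-to-strong synergism range; they are not estimates of any
#' real population's latent parameters, and they are echoed verbatim in the
#' ground-truth sidecar of [generate_experiment()].
#'
#' @param doses Dose series of the primary toxicant (µg/L), including 0.
#' @param prochloraz_levels Co-toxicant concentrations (µg/L), including 0.
#' @param temperatures Test temperatures (°C); the first is the reference.
#' @param populations Tibble with one row per population: `population`,
#'   true curve parameters `b`, `c`, `d`, `e` (EC50 at reference conditions,
#'   µg/L) and `f`.
#' @param stress_prochloraz Named numeric: true General-Stress per co-toxicant
#'   level (names = concentrations).
#' @param stress_temperature Named numeric: true General-Stress per
#'   temperature (names = °C); 0 at the reference temperature.
#' @param adaptation_cost True General-Stress added for the agricultural
#'   population whenever any co-stressor is active (the fitness cost of
#'   pesticide adaptation).
#' @param n_per_treatment Animals per treatment cell and stream population
#'   (default 12).
#' @param n_replicates Replicate vessels per stream and cell (default 3;
#'   animals are split as evenly as possible).
#' @param n_streams Named integer vector: number of stream populations
#'   contributing to each population class (default 4 reference and
#'   8 agricultural streams, the sampling structure of the emulated study).
#'   Group-level analyses pool the class's streams, so a treatment cell
#'   carries `n_per_treatment * n_streams` animals at the class level. All
#'   streams of a class share the class's true curve; stream-to-stream
#'   tolerance variation is not emulated.
#' @param capacity [stress_capacity()] law used by the forward model.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    doses = c(0, 0.01, 0.1, 1, 10, 100, 215, 465, 1000),
    prochloraz_levels = c(0, 1, 10),
    temperatures = c(16, 19, 22),
    populations = tibble::tibble(
      population = c("reference", "agricultural"),
      b = 2, c = 0, d = 1, e = c(67, 148), f = 1),
    stress_prochloraz = c(`0` = 0, `1` = 0.035, `10` = 0.10),
    stress_temperature = c(`16` = 0, `19` = 0.13, `22` = 0.145),
    adaptation_cost = 0.045,
    n_per_treatment = 12,
    n_replicates = 3,
    n_streams = c(reference = 4, agricultural = 8),
    capacity = stress_capacity(),
    seed = 1L) {
  chk <- function(ok, field)
    if (!ok) ms_abort(paste0("invalid synthetic config field: ", field),
                      "multistress_validation_error")
  chk(is.numeric(doses) && all(is.finite(doses)) && all(doses >= 0) &&
        0 %in% doses && length(unique(doses)) >= 5, "doses")
  chk(is.numeric(prochloraz_levels) && all(prochloraz_levels >= 0),
      "prochloraz_levels")
  chk(is.numeric(temperatures) && length(temperatures) >= 1, "temperatures")
  chk(is.data.frame(populations) &&
        all(c("population", "b", "c", "d", "e", "f") %in% names(populations)) &&
        all(populations$e > 0) && all(populations$f > 0) &&
        all(populations$c >= 0 & populations$c <= populations$d &
              populations$d <= 1), "populations")
  chk(all(stress_prochloraz >= 0) &&
        all(as.character(prochloraz_levels) %in% names(stress_prochloraz)),
      "stress_prochloraz")
  chk(all(stress_temperature >= 0) &&
        all(as.character(temperatures) %in% names(stress_temperature)),
      "stress_temperature")
  chk(is.numeric(adaptation_cost) && adaptation_cost >= 0, "adaptation_cost")
  chk(is.numeric(n_per_treatment) && n_per_treatment >= 1, "n_per_treatment")
  chk(is.numeric(n_replicates) && n_replicates >= 1, "n_replicates")
  chk(is.numeric(n_streams) && all(n_streams >= 1), "n_streams")
  structure(list(doses = sort(unique(doses)),
                 prochloraz_levels = sort(unique(prochloraz_levels)),
                 temperatures = sort(unique(temperatures)),
                 populations = tibble::as_tibble(populations),
                 stress_prochloraz = stress_prochloraz,
                 stress_temperature = stress_temperature,
                 adaptation_cost = adaptation_cost,
                 n_per_treatment = as.integer(n_per_treatment),
                 n_replicates = as.integer(n_replicates),
                 n_streams = n_streams,
                 capacity = as_capacity(capacity),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# stable 31-bit string hash (polynomial rolling); used to derive independent
# per-cell substreams so adding a condition never perturbs other cells' draws
stable_hash <- function(key) {
  m <- 2147483647
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% m
  as.integer(h)
}

#' Expected survival of the synthetic forward model
#'
#' The forward model composes the population's log-logistic toxicant response
#' with the additive General-Stress of the co-stressors:
#' `survival = stress_to_survival( survival_to_stress(1 - E_tox(dose)) +
#' S_prochloraz + S_temperature + S_adaptation * [agricultural & co-stressed] )`.
#' With all true stresses zero it reduces exactly to the bare log-logistic
#' curve.
#'
#' @param config A [synthetic_config()].
#' @return Tibble over the full design grid with the deterministic expected
#'   survival (`expected_survival`) and its components.
#' @export
expected_survival_grid <- function(config) {
  if (!inherits(config, "synthetic_config"))
    ms_abort("`config` must be a synthetic_config.", "multistress_domain_error")
  grid <- tidyr::expand_grid(
    population = config$populations$population,
    temperature = config$temperatures,
    prochloraz_conc = config$prochloraz_levels,
    clothianidin_conc = config$doses)
  grid <- dplyr::left_join(grid, config$populations, by = "population")
  s_p <- config$stress_prochloraz[as.character(grid$prochloraz_conc)]
  s_t <- config$stress_temperature[as.character(grid$temperature)]
  co_stressed <- (s_p + s_t) > 0
  s_a <- ifelse(grid$population == "agricultural" & co_stressed,
                config$adaptation_cost, 0)
  surv_tox <- 1 - ll5_effect_rowwise(grid)
  s_total <- survival_to_stress(surv_tox, config$capacity) + s_p + s_t + s_a
  dplyr::mutate(
    dplyr::select(grid, "population", "temperature", "prochloraz_conc",
                  "clothianidin_conc"),
    stress_prochloraz = unname(s_p),
    stress_temperature = unname(s_t),
    stress_adaptation = unname(s_a),
    survival_toxicant = unname(surv_tox),
    expected_survival = unname(stress_to_survival(s_total, config$capacity)))
}

ll5_effect_rowwise <- function(grid) {
  vapply(seq_len(nrow(grid)), function(i)
    ll5_effect(grid$clothianidin_conc[i], grid$b[i], grid$c[i], grid$d[i],
               grid$e[i], grid$f[i]),
    numeric(1))
}

#' Generate a synthetic multi-stressor experiment
#'
#' Draws immobile counts binomially around the forward-model expected
#' survival of [expected_survival_grid()], split across replicate vessels.
#' Each design cell uses its own pseudorandom substream derived by stable
#' hashing of the cell key from the run seed, so identical seeds give
#' identical tables and adding conditions does not perturb existing cells.
#' The true curves and stresses are attached as the `ground_truth` attribute
#' (the sidecar), retrievable with [ground_truth()].
#'
#' @param config A [synthetic_config()].
#' @return A validated trial-table tibble with a `ground_truth` attribute.
#' @export
generate_experiment <- function(config) {
  grid <- expected_survival_grid(config)
  n_rep <- config$n_replicates
  sizes1 <- rep(config$n_per_treatment %/% n_rep, n_rep)
  extra <- config$n_per_treatment %% n_rep
  if (extra > 0) sizes1[seq_len(extra)] <- sizes1[seq_len(extra)] + 1

  rows <- purrr::pmap_dfr(grid, function(population, temperature,
                                         prochloraz_conc, clothianidin_conc,
                                         expected_survival, ...) {
    n_str <- streams_for(config, population)
    sizes <- rep(sizes1, n_str)
    key <- paste(population, temperature, prochloraz_conc, clothianidin_conc,
                 sep = "|")
    cell_seed <- (config$seed %% 65521) * 32749 + stable_hash(key)
    counts <- withr::with_seed(cell_seed %% 2147483647,
                               rbinom(length(sizes), sizes,
                                      1 - expected_survival))
    tibble::tibble(clothianidin_conc = clothianidin_conc,
                   prochloraz_conc = prochloraz_conc,
                   temperature = temperature,
                   population = population,
                   stream = rep(seq_len(n_str), each = n_rep),
                   replicate = rep(seq_len(n_rep), n_str),
                   n_exposed = sizes,
                   n_immobile = counts,
                   duration_h = 48)
  })
  out <- validate_trial_table(rows)
  attr(out, "ground_truth") <- list(
    config = config,
    expected = grid,
    note = "true stresses are fixture choices, not estimates of any field population")
  out
}

streams_for <- function(config, population) {
  ns <- config$n_streams
  if (!is.null(names(ns)) && population %in% names(ns))
    as.integer(ns[[population]])
  else as.integer(ns[[1]])
}

#' Ground-truth sidecar of a synthetic table
#'
#' @param table A table from [generate_experiment()].
#' @return The sidecar list (config, expected-survival grid, provenance note).
#' @export
ground_truth <- function(table) {
  gt <- attr(table, "ground_truth")
  if (is.null(gt))
    ms_abort("no ground-truth sidecar attached; was this table simulated?",
             "multistress_domain_error")
  gt
}

#' Generate a synthetic site table for exposure-effect regression
#'
#' Produces per-site toxic-unit exposure and a community index that is linear
#' in log TU plus Gaussian noise, as a fixture for the site-level regression
#' utility. Defaults mimic a small agricultural-stream monitoring campaign:
#' twelve sites spanning log TU_max from about -4.8 to -0.8 with a declining
#' community index.
#'
#' @param n_sites Number of sites (>= 3).
#' @param tu_range Range of log10 TU_max values covered evenly.
#' @param intercept,slope True linear relation of the index on log TU.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Tibble with `site_id`, `tu_log10`, `index`.
#' @export
generate_site_table <- function(n_sites = 12, tu_range = c(-4.8, -0.8),
                                intercept = 0.22, slope = -0.13,
                                noise_sd = 0.05, seed = 1L) {
  if (n_sites < 3)
    ms_abort("`n_sites` must be at least 3.", "multistress_validation_error")
  tu <- seq(tu_range[1], tu_range[2], length.out = n_sites)
  noise <- withr::with_seed(as.integer(seed), rnorm(n_sites, 0, noise_sd))
  tibble::tibble(site_id = sprintf("site_%02d", seq_len(n_sites)),
                 tu_log10 = tu,
                 index = intercept + slope * tu + noise)
}
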
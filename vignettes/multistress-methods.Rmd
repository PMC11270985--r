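---
title: "Methods: dose-response, null models and the stress addition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response, null models and the stress addition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multistress)
```

`multistress` analyses crossed acute-toxicity experiments in which a primary
toxicant dose series is combined with additional stressors — a co-applied
pesticide, elevated temperature, and the fitness cost of pesticide
adaptation. This vignette is the package's own account of the models it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The dose-response model

Immobility after a fixed exposure (48 h by default) is modelled per
treatment as a binomial count with a five-parameter log-logistic mean
$$E(u) = c + \frac{d - c}{\bigl(1 + e^{b(\ln e - \ln u)}\bigr)^{f}},$$
where $c$ is the background effect at dose 0, $d$ the maximal effect, $e$
the inflection dose (µg/L), $b$ a dimensionless slope (positive for an
effect increasing with dose) and $f$ a dimensionless asymmetry. Dose 0 is
handled on the asymptote, never through $\log 0$. Background immobility is
absorbed by $c$; no separate control (Abbott) correction is applied.

**Binomial likelihood, not least squares.** With a dozen animals per
treatment the Gaussian approximation behind least squares on proportions is
poor, so `fit_ll5()` maximises the binomial likelihood of the immobile
counts; `method = "ls"` retains a least-squares path for cross-checks
against conventional dose-response software. Counts are pooled by dose
before fitting, making the fit invariant to row order and to splitting a
dose across replicate rows.

**Optimisation.** Parameters are fitted on a transformed scale
($\log b$, logistic-bounded $c \le d$ in $(0,1)$, $\log e$, $\log f$) with
L-BFGS-B inside fixed bounds. Starting values come from a logit-linear
regression of interpolated proportions on log dose; non-convergence triggers
a fixed ladder of perturbed starts. There is no randomness anywhere in the
fitter, so refitting the same table is bit-identical. Data that are
all-or-nothing at every dose (a step response) leave the slope unbounded and
raise an error rather than a spurious fit.

**ECx.** The default ECx is *relative* — the dose at which the effect,
rescaled between the fitted asymptotes, reaches $x\%$ — with the closed form
$\ln \mathrm{EC}x = \ln e - \ln\!\bigl((x/100)^{-1/f} - 1\bigr)/b$. An
*absolute* ECx (unscaled effect fraction $x/100$, which must lie inside
$(c, d)$) is available by flag. Which convention the emulated study's
software used is not stated; the default is documented here, not asserted as
that study's choice.

**Confidence intervals.** Two interval methods are implemented on the
log-dose scale. The delta-method (Wald) interval uses the curvature of the
likelihood at the optimum; it matches conventional practice but measurably
under-covers at the 12-animal design (about 81% observed coverage for a
nominal 95% interval over 200 simulated experiments). The default is
therefore a profile-likelihood interval that inverts the likelihood-ratio
test along the profiled log-ECx axis; at the same design its observed
coverage is 95%, and the package's coverage property (90–99% across seeded
simulations at 9 doses × 12 animals) is asserted in the test suite at 150
simulations. The delta standard error is reported in either case.

## Null models for combined effects

*Effect addition* (EA, independent action) combines effects
multiplicatively, $E_\mathrm{mix} = 1 - \prod_i (1 - E_i)$. *Concentration
addition* (CA, Loewe) combines potencies,
$\mathrm{EC}x_\mathrm{mix} = \bigl(\sum_i p_i/\mathrm{EC}x_i\bigr)^{-1}$.
The literature the package follows attaches the names inconsistently to
their originators in places; the displayed formulas govern here.

For a fixed-intensity co-stressor, its marginal effect is estimated from the
zero-dose treatments of the co-stressed condition, expressed relative to the
control's background on the Bliss scale and floored at zero. The EA
prediction is then the dose where the combined effect crosses 50% of its own
range (root bisection); the CA prediction converts the marginal effect into
an equivalent dose of the primary toxicant through the inverse fitted curve
and subtracts it from the ECx (dose equivalence). A co-stressor whose own
effect reaches the criterion admits no finite prediction and raises a
domain error; the pipeline records such conditions as `NA` with a warning.

Model deviation ratios are raw quotients; rounding (half-to-even, two
decimals by default) happens only in the report layer. The classification
partitions $(0,\infty)$ exactly: $<0.5$ antagonism, $[0.5, 1]$ additive,
$(1, 2]$ weak synergism, $>2$ strong synergism. The boundary value 2 is
assigned to weak synergism; the source prose is silent on the exact
boundary, so the partition is documented rather than inferred.

## The stress addition model

SAM assumes every individual holds a general stress capacity drawn from a
common distribution on $[0,1]$; the population survives stress $S$ with
probability $N(S) = 1 - F(S)$. The capacity law is a two-parameter beta
distribution, satisfying the boundary conditions $N(0)=1$, $N(S \ge 1)=0$
by construction. The default shape, `beta(3.2, 3.2)`, is inherited from the
established SAM software and literature — the emulated study states only the
boundary conditions — and both shapes are configurable everywhere. No
numeric claim in the package depends on the specific shape: the
self-consistency results hold for any valid capacity law.

Stressor-specific effects are converted to General-Stress with
$S = F^{-1}(1 - N)$, added ($\sum_i S_i$; plain addition is the model), and
transformed back. Two numerical facts matter in practice:

* **Boundary amplification.** $F^{-1}$ has infinite slope at 0 and 1, so a
  tiny background immobility (e.g. 2%) already maps to a non-trivial
  General-Stress (≈ 0.15 under the default shape). Comparisons are therefore
  made on matched curves, and the synthetic generator's default background is
  exactly zero.
* **Saturation.** A fully immobilised treatment ($N = 0$) only bounds the
  stress from below. `quantify_stressor_stress()` excludes such doses from
  its estimate with a classed warning and errors if the entire window is
  saturated — the stress is simply not identifiable there.

**Quantification window.** The additional stress of a co-stressor is read
from the survival drop around the EC50 of the toxicant alone: by default the
two tested doses flanking the fitted alone-EC50 on the log axis, mean
aggregated, with per-dose contributions returned for audit. The window is a
configurable knob because the original web application's windowing is not
public; the self-consistency identity below is independent of the choice.

**Prediction and self-consistency.** The SAM-predicted EC50 is the midpoint
crossing of the predicted curve rescaled to its *stressed* control (the
co-stressor-only treatment); rescaling to the unstressed control is
available by flag, since the convention is not stated by the emulated study.
When the General-Stress is quantified from the same curves subsequently used
for prediction, the predicted and observed EC50 coincide and the MDR is 1 by
construction — the package asserts this identity to 1e-6 over randomised
conditions, and `scripts/acceptance.R` recomputes it end to end.

## The synthetic experiment generator

`generate_experiment()` draws binomial immobile counts around the forward
model
$$N = \mathrm{stress\_to\_survival}\bigl(\mathrm{survival\_to\_stress}(N_\mathrm{tox}(u)) + S_\mathrm{co\text{-}toxicant} + S_\mathrm{temperature} + S_\mathrm{adaptation}\bigr),$$
with $S_\mathrm{adaptation}$ applied to the agricultural group only when a
co-stressor is active. Defaults emulate the study conditions the package
targets: nine clothianidin concentrations (0, 0.01, 0.1, 1, 10, 100, 215,
465, 1000 µg/L) × prochloraz 0/1/10 µg/L × 16/19/22 °C; reference and
agricultural groups with 16 °C EC50s of 67 and 148 µg/L (slope 2, symmetric,
zero background); 12 animals per treatment per stream population in three
vessels of four, pooled over 4 reference and 8 agricultural streams — the
sampling structure behind group-averaged survival. True stress magnitudes
(`0.035`/`0.10` for prochloraz 1/10 µg/L, `0.13`/`0.145` for 19/22 °C,
adaptation cost `0.045`) are fixture choices placed, via the closed-form
forward model, so that default runs span the weak-to-strong synergism range
the emulated study reports; they are labelled as such in the ground-truth
sidecar and are not estimates of any real population's parameters.

Randomness uses one seed with per-cell substreams derived by stable hashing
of the cell key, so identical seeds give identical tables and adding a
condition never perturbs other cells' draws.

What the generator deliberately does **not** emulate: stream-to-stream
tolerance variation within a group (all streams share the group curve),
time-resolved mortality, dose-dependent interactions beyond stress
additivity, chemical fate, and vessel microenvironment effects. Passing
tests therefore demonstrate correctness of the analysis chain under the
stated forward model, not robustness to those real-data features.

## Pipeline conventions

* **Comparison designs.** *Mixture toxicity*: co-toxicant conditions versus
  the co-toxicant-free condition at the same temperature. *Multiple stress*:
  all conditions at elevated temperature versus the best-case control
  (reference temperature, no co-toxicant). Observed EC50s are fitted on
  group-pooled counts, matching group-averaged survival.
* **Total stress for the synergism regression.** Co-toxicant and temperature
  stress are each quantified against the population's best-case control; the
  adaptation-cost term for the agricultural group is the excess of its
  observed stress over the reference group's under the same co-stressors,
  floored at zero. How the original analysis computed this term is not
  published, so the rule is isolated in one function and the regression's
  explained variance is treated as a qualitative, not exact, reproduction
  target; EA is the null model for all synergy statements.
* **Group comparisons.** Pooled versus Welch t tests are chosen by an
  F-ratio variance pre-check at α = 0.05 (the dichotomy is stated by the
  emulated analysis, the criterion is not); EC50s are ln-transformed by flag.
* **Toxic units.** Site aggregation takes the maximum TU within a campaign
  and the mean of campaign maxima across years; the original aggregation is
  described only as "aggregated", so the rule is recorded in the output
  metadata.

## Problem sizes and tolerances

The test suite runs the coverage property at 150 simulated experiments of
the 9 × 12 design, the synergism-direction property at 100 seeded default
runs, self-consistency at 25–30 randomised conditions, and algebraic oracles
at 1e-12; root finders use relative tolerances of 1e-10 on the log-dose
axis. These sizes were chosen to give stable Monte-Carlo estimates of each
property.

## Known limitations

Five parameters from nine doses is an ambitious fit: with small counts the
asymmetry $f$ and slope $b$ are weakly identified and may sit at their
bounds while the relative EC50 remains well determined — interpret the shape
parameters, not just the intervals, with care. The delta-method interval
under-covers at small counts (hence the profile default). SAM results near
the survival boundaries inherit the capacity law's boundary amplification.
The package does not model time-to-event mortality, hormesis, or
dose-response-surface interaction models, and it computes no trait-based
community indices (only a generic site-level regression utility is
provided).
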
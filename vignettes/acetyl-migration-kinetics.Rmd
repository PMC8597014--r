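---
title: "Modeling acetyl group migration and hydrolysis kinetics in mannan saccharides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling acetyl group migration and hydrolysis kinetics in mannan saccharides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmig)
```

## The chemistry and the two networks

Acetyl esters on partially acetylated β-(1→4)-mannans are mobile under
mildly basic aqueous conditions. Three base-catalysed processes matter
on the weeks timescale of an NMR migration experiment:

* a **fast, reversible O3⇌O2 migration** within a mannose unit
  (constants `k_O3_O2`, `k_O2_O3`), roughly a thousand times faster
  than everything else;
* a **slow, irreversible O2→O6 migration** across the glycosidic bond
  onto the primary hydroxyl of the neighbouring unit (`k_O2_O6`);
* **ester hydrolysis**, from the primary O6 position (`k_prim_hydr`)
  and, only modestly slower, from the secondary O2/O3 positions
  (`k_sec_hydr`).

`acmig` encodes this chemistry twice. The **trisaccharide network**
tracks the seven distinguishable acetylation states of a model
trisaccharide: `1a` (central-unit O2-Ac + O3-Ac), `1b` (reducing-end
O6-Ac + central O3-Ac), `1c` (O6-Ac + O2-Ac), `1d` (O3-Ac only), `1e`
(O2-Ac only), `1f` (O6-Ac only) and `1g` (fully deacetylated). The
**GGM network** collapses a polysaccharide to the per-unit states `A`
(O3-acetylated), `B` (O2-acetylated), `C` (O6-acetylated) and `D`
(deacetylated) — a deliberate simplification that treats each mannose
unit independently.

All reactions of the same chemical type share one constant; that tying
is what makes the seven-species scheme identifiable from concentration
data at all. Two structural choices deserve explicit statement:

* The doubly acetylated `1a` loses either of its two secondary acetyls
  independently, so secondary hydrolysis of `1a` is encoded as two
  parallel channels `1a→1d` and `1a→1e`, each at `k_sec_hydr` — its
  total depletion rate from hydrolysis is therefore `2·k_sec_hydr`.
* Primary-position hydrolysis acts on every O6-acetylated species,
  including the final step `1f→1g`; the `1e→1f` step, by contrast, is
  the O2→O6 *migration* and carries `k_O2_O6`.
* The back-migration `1b→1a` (O6 back to O2) is omitted: experimentally
  at most a trace of `1a` re-forms from `1b`, too little to support a
  rate estimate. `build_rate_matrix()` accepts an optional
  `k_back_1b_1a` for sensitivity analyses; it defaults to 0.

Collected in matrix form the mass balances read

$$\frac{dc}{dt} = f(t)\, K\, c,$$

with `K` assembled by `build_rate_matrix()`. Every column of `K` sums
to zero, so total mass is conserved exactly by construction, and the
deacetylated species (`1g`/`D`) is absorbing whenever the hydrolysis
constants are positive.

## The pH correction and the transformed clock

Between pH 7 and 8 every one of these reactions is first order in
hydroxide. The scalar factor

$$f(t) = 10^{\,\mathrm{pH}(t) - 8}$$

(`oh_correction_factor()`) rescales all rates simultaneously, so the
fitted constants are quoted *at pH 8*. An equivalent convention
references the factor to the starting pH of the particular experiment
rather than to pH 8; the two differ by a constant multiplier whenever
the starting pH is not exactly 8, which would silently rescale every
fitted constant. We adopt the pH-8 reference as the primary convention
precisely so that constants from different experiments are comparable,
and expose the alternative through the `reference_ph` argument.

pH logs are sparse (weekly pH-meter readings), so between readings the
pH is interpolated **linearly in pH** (not in hydroxide concentration
— pH is what the meter measures and drifts smoothly), and held constant
beyond either end of the log.

Because `f(t)` multiplies the whole right-hand side, the time-varying
system is the constant-coefficient system run on the transformed clock

$$\tau(t) = \int_0^t 10^{\,\mathrm{pH}(s)-8}\, ds,$$

which `transformed_time()` evaluates *exactly* on each linear-in-pH
segment (the integrand is an exponential there, so each segment has a
closed-form integral; no quadrature error enters). Two consequences are
used throughout the test suite: the set of states visited is
independent of the pH history (only the time axis stretches), and a
constant-pH-8 profile gives τ(t) = t.

## Forward simulation: two routes

`simulate_closed_form()` evaluates the exact solution
`c(t) = exp(K·τ(t))·c(0)`. Internally it diagonalises `K` once and
reuses the eigenbasis for all requested times; if the eigenvector basis
fails an exact-reconstruction check (defective or ill-conditioned `K`),
it falls back to a dense matrix exponential per time point. This route
is both the numerical oracle and the fast path used inside fitting.

`simulate_kinetics()` integrates the same system with a
backward-differentiation (BDF) multistep method. The system is stiff in
the practical sense — `k_O3_O2 ≈ 1.9 h⁻¹` against hydrolysis constants
of order `1.6e-3 h⁻¹` is three decades of separation — so the defaults
are `method = "bdf"`, `rtol = 1e-8`, `atol = 1e-10`. At these
tolerances the two routes agree to better than `1e-6` per component
over randomized constants, starting compositions and pH profiles (100
instances in the test suite), and total mass drifts by less than
`1e-8` over 1000 h.

Round-off can leave tiny negative fractions; these are clipped to zero
**only on output**, never inside the integrator, so the solver's own
error control is not perturbed.

## Fitting

`ssq_objective()` is the plain unweighted sum of squared residuals over
datasets, sampling times and observed species — no variance weighting,
no per-species scaling. Missing observations (`NA`) are simply excluded.

`fit_rate_constants()` minimises this objective with up to two stages:
a Nelder–Mead simplex (robust far from the optimum) followed by
Levenberg–Marquardt refinement on the residual vector. Both operate in
**log10-parameter space**: the constants span three decades, and the
log transform both conditions the problem and enforces positivity.
Box bounds default to `[1e-8, 1e2]` h⁻¹. Because simplex and LM are
local optimizers and nothing constrains the starting point a priori,
the fitter runs a configurable number of multistarts (default 5): the
first from the user's initial guess, the rest perturbed log-uniformly
within ± half a decade, deterministically from the config seed.

Standard errors are the linearized (Gauss–Newton) ones:
`s²(JᵀJ)⁻¹` with `s² = SSQ/(n−p)` and `J` the Jacobian of the residual
vector, computed by central differences with step `1e-4` in log10 space
(small enough for accuracy, large enough to sit well above the `1e-8`
solver tolerance), then mapped to the natural scale via
`dk = k·ln(10)·d(log₁₀k)`. A rank-deficient `J` raises an
identifiability warning and reports `NA` for the affected parameters
rather than a fabricated number. Locked parameters pass through to the
estimates bit-identically and carry no error.

The **degree of explanation**, `100·(1 − SSQ/TSS)`, is reported with
`TSS` centred at the grand mean of all pooled observations by default;
a per-species centring is available (`doe_center = "per_species"`).
Pooled centring is the stricter convention for fraction data whose
species differ wildly in scale, and it is the default because the
choice must be stated, not guessed, when comparing fits.

**Identifiability.** A single experiment started from one compound
constrains the fast exchange pair only through its ratio
`k_O3_O2/(k_O3_O2 + k_O2_O3)` — the equilibration transient is over
before the second sample. The fitter does not hide this: standard
errors on the individual exchange constants explode while their ratio
stays tight. Jointly fitting complementary starting points (one
experiment from `1a`, one from `1b`) in a single SSQ restores full
identifiability, and is the recommended design. For GGM, which starts
*at* the exchange equilibrium, the ratio itself is all the data
contain, so one of the pair must be locked (`k_O2_O3 = 1 h⁻¹` by
convention) — exactly how the GGM presets are defined.

## The synthetic-data generator

`generate_dataset()` emulates what a ¹H-NMR migration experiment
actually yields: species mole fractions from well-separated acetyl
methyl singlets, sampled over about four weeks, under a drifting pH,
with additive integration noise. Its defaults are the study
conditions, chosen once:

* **Sampling design**: 25 points geometrically spaced from 1 h to
  672 h. Dense early sampling resolves the fast O2/O3 equilibration;
  the four-week tail pins the slow constants.
* **pH drift**: linear from 7.95 (the value the buffer settles at on
  dissolution) to 7.75 over 672 h, matching the observed meter drift;
  constant and exponential-approach models are available.
* **Noise**: additive Gaussian, σ = 0.005 absolute mole fraction — a
  plausible precision for integrating well-separated singlets. This is
  a synthetic choice, not a measured value. Noisy fractions are clipped
  to [0, 1] and over-full rows renormalized by default
  (`clip_to_simplex`); unclipped generation is available for noise
  diagnostics.
* **Starting presets**: `from_1a` and `from_1b` put all mass in the
  respective compound; `from_1a` can redistribute an
  `initial_hydrolyzed_fraction` (e.g. 0.10, mirroring the ~10 %
  hydrolysis already visible at a first measurement) into `1d`/`1e` at
  the O2:O3 equilibrium split. `ggm_default` starts at
  `(A, B, C, D) = (0.39, 0.61, 0, 0)`: the acetyl-bearing units are
  normalized to 1 and split by the observed 61:39 O2:O3 equilibrium, O6
  acetylation is taken as absent at the start, and never-acetylated
  mannose units are excluded from the state entirely — acetyl-peak NMR
  cannot see them, so including them would fabricate an observation.

What the generator deliberately does **not** emulate: peak overlap and
baseline error (input begins at clean integrals), multiplicative or
time-correlated noise, and any mechanism for the concentration
dependence seen in GGM (chain–chain interactions presumably slow the
O2→O6 step at higher concentrations; each concentration is simply its
own constant set). Passing recovery tests on this generator therefore
demonstrates the estimator's correctness under its stated assumptions,
not robustness to spectral artefacts.

`recovery_experiment()` wraps the loop that turns the generator into an
acceptance surface: generate `n` noisy replicates, refit each, report
per-parameter relative bias, relative RMSE and ±2-standard-error
coverage. At the default design and σ = 0.005, 20 replicates give
coverage of 85–95 % across all five constants and relative RMSE under
3 % for the fast pair.

## Numerical and design choices, collected

* Integrator: BDF, `rtol 1e-8`, `atol 1e-10`; oracle agreement `1e-6`.
* Closed form: eigendecomposition with exact-reconstruction guard
  (tolerance `1e-10` relative to `max|K|`), dense `expm` fallback.
* Optimization: log10 space, bounds `[1e-8, 1e2]` h⁻¹, simplex then
  LM, 5 multistarts within ± half a decade, seeds fixed by config.
* Sensitivities: central differences, step `1e-4` in log10 space.
* Negative round-off: clipped on output only.
* CSV dialect: comma-separated, `.` decimal, UTF-8, `#` metadata
  comment lines, fixed species column order, 10 significant digits;
  times in hours (a `time_unit: d` key converts on load); missing
  values as empty cells.
* Peak integrals: each acetyl methyl is an equal-molar-response
  reporter, so a doubly acetylated species' proxy is the *mean* of its
  site integrals, not the sum.
* Degree of explanation: grand-mean centring by default, per-species
  optional.

## Problem sizes

The shipped tests and the acceptance script use 25-point designs over
672–700 h, joint two-experiment trisaccharide fits (350 observations),
single-dataset GGM fits (100 observations), a 100-instance randomized
integrator-vs-closed-form comparison, and a 20-replicate noisy-recovery
study. These sizes were chosen as the smallest designs at which all
five constants are comfortably identifiable; the generator accepts
arbitrary designs for larger studies.

## Command-line use

A thin wrapper (`inst/scripts/acmig`) drives the same functions from a
shell: subcommands `simulate`, `generate`, `fit`, `recover`; a YAML run
config with sections mirroring `generator_config()` / `fit_config()`;
flags `--config`, `--seed`, `--out`, `--model {tri,ggm}`,
`--constants-preset {trisaccharide, ggm-2mg, ggm-10mg, ggm-20mg}`
(flags win over the file). Unknown config keys are rejected rather than
ignored, and every run writes its effective config, a version stamp and
a log into the output directory.

## Limitations

* The GGM scheme treats mannose units independently; cooperative or
  neighbour effects along a chain are outside the model.
* No temperature dependence: constants are for 25 °C conditions and
  the package offers no Arrhenius machinery.
* Confidence statements are linearized (Gauss–Newton) only; no
  profile-likelihood or Bayesian intervals.
* The acetyl-integral converter assumes every species contributes at
  least one resolvable singlet; heavily overlapped spectra need
  upstream deconvolution before `integrals_to_fractions()`.
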
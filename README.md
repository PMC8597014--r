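# acmig — kinetics of acetyl group migration in mannan saccharides

Partially acetylated β-(1→4)-linked mannans (model trisaccharides and
native galactoglucomannan, GGM, from Norway spruce) rearrange their
acetyl esters in near-neutral aqueous solution: a fast reversible O3⇌O2
migration within a mannose unit, a slow O2→O6 transfer across the
glycosidic bond to the neighbouring unit, and gradual hydrolysis from
both primary (O6) and secondary (O2/O3) positions. All of these steps
are base-catalysed, so their observable rates track the hydroxide
concentration as the solution pH drifts over a weeks-long NMR
experiment.

`acmig` implements the two first-order reaction networks describing
this chemistry — a seven-species trisaccharide scheme (1a–1g) and a
four-unit GGM scheme (A–D) — as a simulate-and-fit toolkit for anyone
estimating migration/hydrolysis rate constants from ¹H-NMR time
courses, or studying how well such constants can be recovered at a
given sampling design and noise level.

## The model

Five tied pseudo-first-order rate constants (h⁻¹, quoted at pH 8)
parameterize either network: k<sub>O2→O6</sub>, k<sub>O3→O2</sub>,
k<sub>O2→O3</sub>, k<sub>prim.hydr</sub>, k<sub>sec.hydr</sub>.
Collecting the mass balances in matrix form, the state vector *c* of
species mole fractions obeys

```
dc/dt = 10^(pH(t) − 8) · K · c
```

where `K` is the rate matrix assembled from the five constants (every
column sums to zero, so total mass is conserved) and `10^(pH−8)` is the
hydroxide correction that reduces every rate as the pH falls — a drop
from 7.95 to 7.75 slows everything by 37 %. Because the correction is a
scalar multiplier, the system is exactly solvable:
`c(t) = expm(K·τ(t))·c(0)` with the transformed clock
`τ(t) = ∫₀ᵗ 10^(pH(s)−8) ds`. The package provides both this closed
form and a stiff BDF integrator (the O3/O2 exchange is ~1000× faster
than the other steps), cross-validated against each other.

Fitting minimises the unweighted sum of squares
`SSQ = Σ_t Σ_i (c_model − c_obs)²` over one or several jointly fitted
experiments, via Nelder–Mead simplex followed by Levenberg–Marquardt in
log-parameter space, and reports linearized standard errors and an
R²-style "degree of explanation".

The useful quasi-equilibrium result: the fast exchange pins the O2:O3
acetylation split at `k_O3→O2 / (k_O3→O2 + k_O2→O3)` — about 65:35 for
the trisaccharide constants and 61:39 for GGM.

## Worked example

Simulate the published trisaccharide constants from pure 1a under a
realistic pH drift:

```r
library(acmig)
k <- rate_constants_preset("trisaccharide")
tr <- simulate_kinetics(k, c(c_1a = 1),
                        ph_profile(c(0, 672), c(7.95, 7.75)),
                        c(0, 24, 168, 672), "trisaccharide")
print(tr)
#> Kinetic trajectory (trisaccharide): 4 time points, 7 species
#>   time_h       c_1a       c_1b       c_1c       c_1d       c_1e       c_1f        c_1g
#> 1      0 1.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.000000000
#> 2     24 0.89592899 0.01434782 0.02551741 0.02168078 0.03991041 0.00154899 0.001065597
#> 3    168 0.48064797 0.05550745 0.10268271 0.09567624 0.17773978 0.04732157 0.040424283
#> 4    672 0.08322856 0.04437265 0.08248415 0.10496868 0.19520930 0.19357826 0.296158405
```

After four weeks most of the starting diester 1a is gone; the
monoesters 1d/1e sit near the 35:65 O3:O2 split, and ~30 % is fully
deacetylated (1g).

Generate noisy synthetic experiments started from 1a *and* from 1b
(joint fitting of complementary starting points is what makes all five
constants identifiable) and refit:

```r
mk <- function(start) generator_config(constants = k, start = start,
  noise = noise_model("gaussian", 0.005, seed = 42))
ds <- lapply(c("from_1a", "from_1b"), function(s) generate_dataset(mk(s)))
fit <- fit_rate_constants(ds, fit_config(initial_guess = unclass(k) * 1.3,
                                         multistart_count = 1))
print(fit)
#> Kinetic fit result
#>   k_O2_O6      0.002096 h^-1 +/- 2.07e-05
#>   k_O3_O2      1.891 h^-1 +/- 0.0452
#>   k_O2_O3      1.015 h^-1 +/- 0.0257
#>   k_prim_hydr  0.001943 h^-1 +/- 1.53e-05
#>   k_sec_hydr   0.001566 h^-1 +/- 8.7e-06
#>   SSQ = 0.008005 over 350 observations
#>   degree of explanation = 99.96 %
#>   converged: TRUE (505 iterations)

round(100 * equilibrium_O2_fraction(fit$estimates), 1)
#> [1] 65.1
```

All five generating constants are recovered within their ±2 standard
errors, and the implied O2:O3 split is 65:35. Fitting a *single*
experiment instead leaves the two fast exchange constants individually
undetermined (only their ratio is constrained) — the standard errors
blow up accordingly, which is the intended diagnostic.

A thin command-line wrapper exposes the same pipeline
(`inst/scripts/acmig {simulate|generate|fit|recover}` with a YAML
config); see the methods vignette.

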
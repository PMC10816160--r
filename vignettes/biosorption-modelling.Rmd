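---
title: "Statistical-physics modelling of heavy-metal biosorption with biosorb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical-physics modelling of heavy-metal biosorption with biosorb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosorb)
```

## What the package models

`biosorb` analyses batch experiments in which a dissolved heavy-metal ion
(the motivating system is Cu²⁺ on olive-waste powder, its sodium-alginate
composite, and pure alginate beads) partitions onto a solid biosorbent. Four
stages of that analysis are covered, each behind a small fitting or
post-processing function:

1. **Equilibrium**: the single-layer statistical-physics isotherm with a
   real-gas (van der Waals) description of the solute, `fit_slmrg()`.
2. **Kinetics**: pseudo-first-order (PFO), pseudo-second-order (PSO) and
   Weber–Morris intra-particle diffusion models, by linearized and nonlinear
   routes (`fit_pfo_linear()`, `fit_pso_linear()`, `fit_kinetics()`,
   `fit_ipd_segments()`).
3. **Thermodynamics**: Gibbs energy from the equilibrium constant and van't
   Hoff regression for enthalpy/entropy, `vant_hoff()`, plus the pH-drift
   point of zero charge, `pzc_from_titration()`.
4. **Molecular descriptors**: conceptual-DFT reactivity indices from
   frontier-orbital energies, COSMO-RS σ-profile region areas, and QTAIM
   bond-critical-point classification (`global_descriptors()`,
   `sigma_regions()`, `classify_bcp()`). These are pure post-processing; the
   package never runs an electronic-structure calculation.

Seeded generators (`gen_isotherm()`, `gen_kinetics()`,
`gen_vant_hoff_series()`, `gen_pzc_curve()`) produce data with the
statistical structure each stage assumes, so the whole chain is testable
without laboratory measurements.

## The SLMRG isotherm

The model treats the sorbent as `Nm` identical receptor sites per gram, each
of which binds `n` adsorbate units, in grand-canonical equilibrium with the
solution. The occupied fraction gives

$$ q_e(C_e) = \frac{n\,N_m}{1 + (w/f(C_e))^n}, $$

where `w` (mg/L) is the energetic parameter — the effective-concentration
scale of half-saturation — and `f` is the equilibrium concentration
corrected for non-ideality of the dissolved phase by a van der Waals
(real-gas) model:

$$ f(C_e) = \frac{C_e}{1-bC_e}\;
   \exp\!\Big(\frac{bC_e}{1-bC_e}\Big)\,
   \exp\!\big(-2a\beta C_e\big), \qquad \beta = 1/(k_B T). $$

The co-volume `b` (L/mg) inflates the activity as crowding grows (with a
hard singularity at `Ce = 1/b`), while the cohesion pressure `a` deflates
it. At `a = b = 0` the model is the Hill isotherm, and with `n = 1` the
Langmuir isotherm. The plateau capacity is the steric product
`Qsat = n*Nm` (`saturation_capacity()`).

Two conventions in this closed form deserve emphasis, because published
typesettings of the model are often ambiguous about them:

* **Factor order and sign.** We implement the fugacity-style correction
  with the cohesion factor *decreasing* `f` (attraction lowers activity)
  and the crowding factors increasing it. This is the only reading
  consistent with the factor ordering of the printed model and with the
  van der Waals lineage of the correction.
* **Units of `a`.** `a` is stored in units of 10⁻²³ J·L/mg — the convention
  in which fitted values for aqueous metal uptake are of order 10 — so that
  `2aβCe = 2a·Ce/(1.380649·T)` is dimensionless and O(1) at
  `Ce ≈ 50 mg/L`.

`qe(0)` is defined as 0 by continuous extension (the raw expression is
0/0-adjacent there).

A consequence worth knowing: for strongly cohesive parameter sets (large
`a`, e.g. the published alginate sets at 303–313 K where
`2aβ ≈ 0.26–0.31 L/mg`), `f(C_e)` — and with it `q_e` — turns over and
*decreases* at high concentration. The correction is a low-order expansion
and leaves its validity range well below `0.9/b` in such cases; the
package's property tests therefore assert that `q_e` rises and falls
exactly with `f` and stays inside `[0, Qsat)`, rather than global
monotonicity in `C_e`.

### Fitting and its numerics

`fit_slmrg()` minimizes the residual sum of squares over the box

| parameter | lower | upper | rationale |
|---|---|---|---|
| `n` | 0.1 | 10 | usually quoted in \[1, 10\]; relaxed downward for polymeric sorbents (n < 1 observed) |
| `Nm` (mg/g) | >0 | 10⁴ | physically open-ended site density |
| `a` (10⁻²³ J·L/mg) | 0 | 10³ | ideal limit up to strongly cohesive |
| `b` (L/mg) | 0 | 0.9/max(Ce) | keeps the co-volume singularity outside the data |
| `w` (mg/L) | >0 | 10⁴ | half-saturation scale |

The surface has several basins (the `a`/`b` corrections partially trade off
against `n` and `w`), so a single local search is unreliable. The fitter
draws a seeded Latin hypercube 64× larger than the requested number of
starts — `Nm` and `w` sampled log-uniformly, `a` on a square-root scale
(large `a` collapses the model and kills its gradient), `n` and `b`
linearly — screens it by SSE, and runs bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`, `ftol = ptol = 1e-14`, 500 iterations) from the best
`n_starts` candidates plus one data-driven heuristic start (Langmuir-like:
`n = 1`, `Nm = 1.2·max(qe)`, `w = median(Ce)`, `a = b = 0`). The lowest-SSE
solution wins. With the default 32 starts, noiseless 15-point datasets
generated from each of the nine published parameter sets are recovered to
machine precision; at 2 % relative noise the fit reaches the same global
minimum as an independent brute-force grid-plus-refine search.

R² is `1 − SSE/SST` and RMSE is `√(SSE/N)` with no degrees-of-freedom
correction; when the observations are constant, SST is zero and R² is
returned as `NA` with a `degenerate` flag instead of a division error.

```{r slmrg-example}
p <- slmrg_params(n = 2.037, nm = 50.391, a = 8.46, b = 0.008, w = 9.283)
d <- gen_isotherm(p, temperature = 293, n_points = 15, noise_sd = 0.02,
                  seed = 42)
fit <- fit_slmrg(d, seed = 7)
summary(fit)
```

## Kinetics

The integrated forms are the canonical forward models:
`qt = qe(1 − e^{−k1 t})` (PFO), `qt = qe²k₂t/(1 + qe·k₂t)` (PSO) and
`qt = k_id√t + c` (Weber–Morris). The classical linearizations — `log10(qe
− qt)` vs `t`, and `t/qt` vs `t` — are provided separately because the
slope/intercept values they produce are what older literature tabulates;
the PFO linearization needs the experimental plateau `qe_exp` as an input,
matching standard practice. On exact second-order data the PSO
linearization is lossless; a constant trace gives a zero intercept and is
flagged degenerate rather than silently producing an infinite rate.

`fit_ipd_segments()` formalizes the common three-regime reading of
`qt` vs `√t` plots (film diffusion → intra-particle diffusion → plateau):
it searches *exhaustively* over contiguous partitions of the observed
points (traces are short, so the search is cheap), fits each segment by
ordinary least squares, and minimizes total SSE, breaking ties in favour of
the earliest breakpoints. A first-segment intercept within `origin_tol`
(default 0.5 mg/g) of zero is reported as "passing through the origin";
a nonzero intercept indicates boundary-layer resistance.

## Thermodynamics

With a dimensionless equilibrium constant `K`,
`ΔG° = −RT ln K` (kJ/mol, R = 8.314 J/(mol·K), natural logarithm
throughout), and the van't Hoff regression of `ln K` on `1/T` gives
`ΔH° = −R·slope` and `ΔS° = R·intercept`. `classify_sorption()` applies the
conventional physisorption/chemisorption threshold — chemisorption only for
`ΔH° > 40 kJ/mol`, strictly, so the boundary value classifies as
physisorption. `K` is accepted as an input; how a dimensionless constant is
derived from raw distribution measurements varies between laboratories and
is deliberately out of scope.

The point of zero charge is read from a pH-drift titration as the linearly
interpolated zero crossing of `ΔpH` vs initial pH; if the curve crosses
zero more than once, the first crossing wins (matching the
single-intersection reading of a well-behaved drift curve).

```{r thermo-example}
vh <- vant_hoff(c(293, 303, 313), c(1.6829, 2.0825, 2.5422),
                adsorbent = "OWPSA")
vh
```

## Reactivity descriptors

From HOMO/LUMO energies (eV): gap `= E_LUMO − E_HOMO`, chemical potential
`μ = (E_HOMO + E_LUMO)/2`, electronegativity `χ = −μ`, hardness
`η = gap/2`, electrophilicity `ω = μ²/2η`. For the maximum charge-transfer
index two conventions circulate: the pairwise donor/acceptor form
`(χ_A − χ_D)/(2(η_A + η_D))` and the single-species `χ/η`. Published
descriptor tables for metal–biopolymer systems are commonly tabulated with
the single-species form even when the pairwise formula is quoted alongside,
and the two differ substantially; both are implemented in
`charge_transfer()`, with `"table_single"` as the default.

σ-profile integration uses the conventional region edges at ±0.0075 e/Å²
(hydrogen-bond donor below −0.0075, nonpolar inside, acceptor above).
Profile tails beyond ±0.03 e/Å² are assigned to the adjacent polar region
rather than truncated, so the three areas always partition the total and
the fractions sum to one. Edge-crossing grid intervals are split by linear
interpolation before the trapezoidal rule is applied.

QTAIM classification at a bond critical point uses the total energy density
`H = G + V` and the ratio `G/|V|`: a negative Laplacian of the density
means shared-shell covalency; otherwise `G/|V| < 1` (equivalently `H < 0`)
labels a partially covalent interaction and `G/|V| ≥ 1` a weak closed-shell
one — the boundary ratio of exactly 1 is deliberately placed in the weak
class. Hydrogen-bond energy estimates from `V(rc)` are *not* computed: the
conversion factor is convention-dependent and the package does not guess.

## What the synthetic generators do and do not emulate

The generators reproduce the *functional* structure of each stage — SLMRG-
shaped isotherms, integrated-model kinetic traces (including piecewise
three-regime diffusion traces), van't-Hoff-consistent `K(T)` series, and
monotone titration curves — with multiplicative Gaussian noise
(`qe·(1 + ε)`), chosen because capacities span an order of magnitude across
datasets and a constant relative error is the defensible default; an
additive option exists. Default design: 12 (isotherms for fitting: 15)
log-spaced concentrations in `[1, 0.8/b]` mg/L, and a 14-point time grid
from 5 to 600 min spanning the slow approach to equilibrium of bead-type
sorbents.

They do **not** emulate instrument error structure (e.g. atomic-absorption
heteroscedasticity at the detection limit), inter-batch sorbent
variability, or σ-profiles from molecular structure. Passing recovery tests
on these synthetic data therefore demonstrates the estimators' correctness
and stability under the stated noise model — not robustness to every
real-data pathology.

Every generator is bit-reproducible under a fixed seed, and seeding is
*local*: the global random stream of the session is saved and restored, so
library calls never perturb user code.

## Problem sizes and runtime choices

The test-suite study conditions are: 15-point noiseless grids for exact
recovery of each of the nine published parameter sets; 20 replicate
datasets at 2 % noise for the recovery envelope (whose per-parameter bounds
were frozen once from an independent grid-plus-refine search, at 1.5× its
median errors); 14-point kinetic traces; three-temperature van't Hoff
series. These sizes mirror realistic batch designs — isotherms rarely
exceed 15 concentrations — while keeping the whole suite fast.

## Known limitations

* Published parameter tables are rounded; quantities derived from printed
  values (steric products, regression enthalpies, descriptor cells) can
  disagree with their printed counterparts by about one unit in the last
  printed digit, and the package's consistency checks are set at exactly
  that granularity.
* The SLMRG correction is low-order: for strongly cohesive parameter sets
  the fitted isotherm is non-monotone at high concentration and should not
  be extrapolated toward the co-volume singularity.
* `w = Cs·exp(−Ea/RT)` requires a reference concentration `Cs` (commonly
  the solubility) that must be user-supplied; a `w > Cs` input yields a
  negative adsorption energy, returned with a warning flag rather than an
  error.
* Weighted/robust regression, model-selection criteria and parameter
  uncertainty intervals are out of scope; residual diagnostics are exposed
  on every fit object instead.
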
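# biosorb

Statistical-physics modelling of heavy-metal biosorption in R.

`biosorb` is for researchers analysing batch sorption experiments —
equilibrium isotherms, kinetic traces, temperature series — on
lignocellulosic and alginate adsorbents, with optional post-processing of
quantum-chemical outputs for the molecular side of the story. The
motivating system is Cu²⁺ removal from water by olive-waste powder (OWP),
its sodium-alginate composite (OWPSA), and pure alginate beads.

## The models

**Equilibrium — SLMRG.** The single-layer statistical-physics isotherm
coupled to a real-gas description of the solute:

    qe(Ce) = n·Nm / (1 + (w/f)^n)
    f(Ce)  = Ce/(1−bCe) · exp(bCe/(1−bCe)) · exp(−2aβCe),   β = 1/(kB·T)

with steric parameters `n` (adsorbate units per receptor site) and `Nm`
(site density, mg/g), energetic parameter `w` (mg/L), cohesion pressure `a`
(10⁻²³ J·L/mg) and co-volume `b` (L/mg). The saturation capacity is the
steric product `Qsat = n·Nm`. At `a = b = 0` the model reduces to the Hill
isotherm, and further to Langmuir at `n = 1`. `fit_slmrg()` estimates all
five parameters by screened Latin-hypercube multistart bounded
Levenberg–Marquardt least squares.

**Kinetics.** Integrated pseudo-first-order `qt = qe(1−e^{−k1·t})`,
pseudo-second-order `qt = qe²k2·t/(1+qe·k2·t)` and Weber–Morris
`qt = kid·√t + c`, via both the classical linearizations and nonlinear
least squares, plus an exhaustive-search piecewise diffusion fit
(`fit_ipd_segments()`) for the film-diffusion / pore-diffusion / plateau
regimes.

**Thermodynamics.** `ΔG° = −RT ln K`; van't Hoff regression `ln K` on `1/T`
for `ΔH°` and `ΔS°`, with physisorption/chemisorption classification at the
conventional 40 kJ/mol threshold; pH-drift point-of-zero-charge
determination.

**Molecular descriptors.** Conceptual-DFT indices from HOMO/LUMO energies
(gap, μ, χ = −μ, η, ω = μ²/2η, ΔN_max), COSMO-RS σ-profile region areas
(HBD / nonpolar / HBA at ±0.0075 e/Å²), and QTAIM bond-critical-point
classification from ρ, ∇²ρ, G and V.

Seeded generators (`gen_isotherm()`, `gen_kinetics()`,
`gen_vant_hoff_series()`, `gen_pzc_curve()`) make every stage testable
without laboratory data. See the vignette
(`vignettes/biosorption-modelling.Rmd`) for the models, numerical choices
and limitations in full.

## Worked example

Simulate a 15-point isotherm from a published OWP parameter set at 293 K
with 2 % multiplicative noise, then refit it:

```r
library(biosorb)
p <- slmrg_params(n = 2.037, nm = 50.391, a = 8.46, b = 0.008, w = 9.283)
d <- gen_isotherm(p, temperature = 293, n_points = 15, noise_sd = 0.02,
                  seed = 42)
fit <- fit_slmrg(d, seed = 7)
summary(fit)
#> SLMRG fit (15 points, 293 K)
#> Coefficients:
#>       n      nm       a       b       w
#>  2.0820 49.4057  8.1653  0.0075  9.1427
#> R2 = 0.9990, RMSE = 1.122
#> Converged after 32 start(s); SSE = 18.8789
#> Saturation capacity Qsat = n*Nm = 102.8629 mg/g
```

All five parameters come back within a few percent of the generating
values despite the noise, and the estimated plateau capacity (102.86 mg/g)
sits next to the true steric product 2.037 × 50.391 = 102.65 mg/g.

Thermodynamics from a published equilibrium-constant series:

```r
vant_hoff(c(293, 303, 313), c(1.6829, 2.0825, 2.5422), adsorbent = "OWPSA")
#> Van't Hoff analysis: OWPSA, 3 temperatures (293-313 K)
#>   dH = 15.7263 kJ/mol, dS = 0.0580 kJ/(mol K), R2 = 1.00000
#>   dG (kJ/mol): -1.268 (293 K), -1.848 (303 K), -2.428 (313 K)
#>   Regime: physisorption
```

The positive enthalpy marks an endothermic process, the negative Gibbs
energies a spontaneous one, and 15.7 kJ/mol sits well below the 40 kJ/mol
chemisorption threshold.

Reactivity descriptors from frontier-orbital energies:

```r
global_descriptors(-5.211, -3.110, "lignin")
#>   species e_homo e_lumo   gap      mu    chi    eta   omega   dn_max
#> 1  lignin -5.211  -3.11 2.101 -4.1605 4.1605 1.0505 8.23882 3.960495
```

Lignin's small gap (2.101 eV) and large electrophilicity (8.24 eV) make it
the most reactive of the biopolymer building blocks.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "biosorb.R", package = "biosorb")` with subcommands
`simulate`, `fit-isotherm`, `fit-kinetics`, `thermo`, `descriptors` and
`run-study` (YAML-configured end-to-end pipeline, JSON + text reports).

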
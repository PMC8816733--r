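---
title: "Cosolvency models and PC-SAFT solid-liquid equilibria: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosolvency models and PC-SAFT solid-liquid equilibria: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosolvr)
```

This vignette documents the models in `cosolvr`, the assumptions and
numerical choices behind them, and what the test suite does and does not
establish. The running example is acetylsalicylic acid (ASA) saturated in
ethanol + water mixtures at 298.15 K and 310.15 K, packaged as
`asa_ethanol_water()`.

## The data and its scale

A solubility dataset records the saturation concentration `C` of one solute
at solute-free cosolvent volume fractions `f1` in [0, 1] and absolute
temperatures `T`. All packaged concentrations are **molar** (mol/L), and
every model in the package fits and back-calculates on that scale. This is
a deliberate choice: the reference calculations for this system only
reproduce on the molar scale (hand recomputation of the published
mean-relative-deviation scores succeeds with molar concentrations and fails
with mole fractions), and converting molarity to mole fraction requires
saturated-solution densities that are not available — for ASA they are also
confounded by the dissolved salicylic acid produced by hydrolysis. Where
mole fractions are unavoidable (the equation-of-state route), solute-free
solvent compositions are built from pure-liquid densities instead
(`solvent_mole_fractions()`), with water 0.99705/0.99333 and ethanol
0.78522/0.77641 g/cm^3 at 298.15/310.15 K as standard-literature defaults
that a user-supplied `solvent_system()` overrides.

Datasets are validated on construction: fractions in [0, 1], positive
concentrations, Kelvin temperatures, no duplicate `(f1, T, analyte)` keys.
Model fitting additionally requires both neat-solvent anchors (`f1 = 0` and
`f1 = 1`) at every temperature, because all three algebraic models pass
through the anchors by construction.

## Algebraic cosolvency models

**Log-linear (Yalkowsky).** `ln Cm = ln C2 + sigma * f1` assumes the free
energy of transfer is linear in cosolvent fraction. The solubilization
power `sigma` is either correlative (`ln(C1/C2)` from the anchors) or
predictive via `sigma = M logP + N` with cosolvent constants (ethanol:
`M = 2.14`, `N = 0.92`) and the solute's octanol–water log P (ASA: 1.18).
The predictive route needs only the water solubility — its appeal — but for
ASA it misses the interior of the profile by ~38% at 25 °C because the
true profile is convex with a peak at `f1 = 0.9`, which a single
exponential cannot bend around.

**Jouyban–Acree.** Adds temperature-scaled Redlich–Kister-type mixing terms:
`ln Cm,T = f1 ln C1,T + f2 ln C2,T + (f1 f2 / T) sum_{i=0}^{2} Ji (f1-f2)^i`.
Fitting is ordinary least squares *without intercept* of the excess
`y = ln Cm - f1 ln C1,T - f2 ln C2,T` on the regressors `f1 f2 / T`,
`f1 f2 (f1-f2) / T`, `f1 f2 (f1-f2)^2 / T`: anchor rows contribute zero
regressors and zero response, so they are retained but inert. The anchors
themselves are read from the data, making the model exact at `f1 = 0, 1`.
Degenerate designs (fewer interior points than coefficients, or collinear
regressors) are refused rather than silently truncated. The coefficients
carry units of Kelvin. Pre-trained coefficient sets are shipped for
prediction without any mixture data: a two-term set, a generic
three-term ethanol + water set, and an Abraham-extended set whose per-power
coefficients are dot products with the solute descriptor vector
`(1, E, S, A, B, V)` (ASA: 0.84, 1.42, 0.57, 0.77, 1.29). A minimal-training
experiment — anchors at both temperatures plus `f1 = 0.3, 0.5, 0.7` at
25 °C, two terms — reproduces the published two-term coefficients, which
confirms the molar-scale reading of those equations.

**Modified Wilson.** An isothermal two-constant local-composition form,
`-ln Cm = 1 - f1 (1 + ln C1)/(f1 + f2 λ12) - f2 (1 + ln C2)/(f1 λ21 + f2)`,
with `λ12, λ21 > 0`. The published form mixes `x` and `C` symbols; the
package resolves both to the single working concentration scale, which is
what reproduces the published per-temperature deviations (25.2% / 25.7%).
Fitting minimizes the ln-scale sum of squares by L-BFGS-B from a 3 × 3
multi-start grid over `[0.1, 5]^2` (bounds `1e-6`–`1e3`), followed by a
Nelder–Mead polish with `reltol = 1e-15` — the polish matters because the
quasi-Newton finite-difference gradient resolution (~1e-7 steps) limits
parameter accuracy to ~1e-4, while noiseless recovery to 1e-6 is part of
the contract. Objective ties below 1e-12 break toward the smaller `λ12`.

## The PC-SAFT equation of state

The residual Helmholtz energy per mole (in RT units) is the sum of
hard-chain, dispersion and association contributions, with the universal
dispersion-integral constants of the perturbed-chain formulation taken as
given (they are model constants, not fitted here). Pure components carry
five parameters (`m`, `sigma` in Å, `eps/k` in K, association `kappa_AB`
and `eps_AB/k` in K) plus a molar mass; ethanol, water and ASA all
associate on the 2B scheme (one donor + one acceptor site, only
donor–acceptor bonds). Two parameter-table readings deserve note:

* the association-energy column is interpreted as `eps_AB/k` in Kelvin
  (2653.4 ethanol / 2500.7 water are the canonical Kelvin-valued 2B
  parameters, whatever the column label says);
* the ASA association cell is read as `kappa = 0.01`, `eps_AB/k = 2453.80 K`,
  matching the kappa-then-epsilon pattern of the other rows; the alternative
  split (0.01245 / 3.80 K) would be a physically implausible association
  energy and is rejected.

Mixtures use Lorentz–Berthelot combining rules with all binary interaction
parameters zero (purely predictive) and Wolbach–Danner rules for
cross-association. The temperature dependence of the hard-sphere diameter
is the standard exponential correction. Association site fractions solve
the 2B mass-action equations by damped successive substitution (damping
0.5) from the closed-form single-component guess, then Newton steps to
machine precision, with a bounded least-squares root solve as a last
resort. Machine-precision site fractions are not a luxury: every
thermodynamic derivative downstream is numerical, and residual noise in the
association term was the dominant error source before the Newton polish.

Derivatives are evaluated by the **complex-step method**: the Helmholtz
energy is analytic in density and mole numbers, so
`da/drho = Im(a(rho + ih))/h` at `h = 1e-30 rho` is exact to machine
precision with no subtractive cancellation. The compressibility is
`z = 1 + rho * da/drho`; fugacity coefficients use
`ln phi_k = d(n a_res)/dn_k |_{T,V} - ln z`, mathematically identical to
the explicit mole-fraction-derivative form. Richardson-extrapolated central
differences remain as a fallback path. This matters quantitatively because
`z` is ~1e-3 at liquid conditions, so `ln z` amplifies absolute derivative
noise a thousandfold; with complex-step derivatives the Gibbs–Duhem
residual of the fugacities sits at ~1e-8.

Density solving brackets `P(eta) - P` on the packing-fraction grid
(1e-12 to 0.737), refines each sign change with Brent's method and polishes
with Newton; the liquid branch returns the largest root, the vapor branch
the smallest. Iterative callers warm-start from the previous packing
fraction. The pressure is fixed at 1.013 bar throughout (the working
pressure is not stated in the reference; atmospheric is the only sensible
choice for a shake-flask experiment).

One calibration fact to keep in mind: with these 2B water parameters the
model puts ambient liquid water at 0.922 g/cm^3, about 7.5% below reality —
a known weakness of the parameter set, not of the implementation (ethanol
comes out within 0.7%). Tests assert the model's own value.

## Solid–liquid equilibrium

The solubility of a crystalline solid obeys
`ln x = (dHm/R)(1/Tm - 1/T) - ln gamma(x)`, where the first term is the
ideal solubility from the fusion enthalpy and melting point (no
heat-capacity correction — the reference form omits it) and
`gamma = phi(mixture)/phi(pure subcooled liquid)` comes from PC-SAFT. The
fixed point is solved by damped iteration `x <- (1-d) x + d x_ideal/gamma(x)`
with damping 0.5, relative tolerance 1e-8, at most 200 iterations,
initialized at `x_ideal`; the solute-free ethanol:water ratio is held fixed
while renormalizing with the solute. The converged root is independent of
the damping factor, and the fixed-point residual is checked at the
solution. Fusion properties default to the untreated-drug DSC row
(`Tm = 145.3 °C`, `dHm = 165.6 J/g` × 180.16 g/mol), because the reference
does not say which DSC row fed the calculation; the choice is configurable,
and it is the main lever on the neat-ethanol prediction (x = 0.0445 here
vs 0.0395 reported, ~13%).

With zero binary interaction parameters the model severely underpredicts
the water-rich side (activity coefficients of order 1e6 for ASA in water),
so the predicted profile rises monotonically over ~6 orders of magnitude
from water to ethanol. Large composition-to-composition ratios are
therefore intrinsic to the model; the profile test checks smooth monotone
behaviour on the log scale rather than a bounded linear-scale step.

## Scoring and the degradation check

`MRD% = 100/N * sum(|calc - obs|/obs)` is computed on the linear
concentration scale. When data span several temperatures the package
reports the per-temperature values, the pooled (all-points) value *and* the
unweighted mean of the per-temperature values — published "overall" figures
are inconsistent about which of these they are, so both are always
available. Crystallinity is the trapezoid-integrated area of designated
reflections (defaults 7.8° and 15.6° 2-theta, ±0.5° windows) after
subtracting the linear baseline spanned by each window's edges, divided by
the total scattering area. The undersaturation check flags degradation-
product concentrations strictly below the compound's own saturation
solubility — for salicylic acid at 25 °C every mixture composition is
undersaturated, which is why no salicylic acid precipitates into the
recovered solid.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* the analysis assumes:
solubility curves follow a chosen cosolvency model with Gaussian noise on
`ln C` (multiplicative noise keeps concentrations positive and matches the
relative-error metric; default SD 0.05, the scale of the measured
triplicate scatter), on the measured design (11 fractions × 2
temperatures, with triplicate-derived SD columns); diffractograms are
Gaussian peaks over a broad amorphous halo on the 5–50°, 0.02°-step grid;
detector responses are linear with additive noise. All generators are pure
functions of their arguments and a seed, and restore the caller's RNG
state.

They do **not** emulate: hydrolysis kinetics (the degradation-product
series is data, not a simulated process), peak-shape asymmetry or preferred
orientation in diffractograms, heteroscedastic detector noise, or
densities. Passing parameter-recovery tests on synthetic data therefore
establishes estimator correctness and calibration under the assumed noise
model — not robustness to the ways real measurements violate it.

Two statistical contracts are tested: the estimator is unbiased (mean
fitted `J0` within 2% of truth over 200 seeded replicates, and an
independent batch of fits falls inside the parametric-bootstrap 95%
interval of the estimator at the expected rate), and scoring the *true*
model on its own noisy data yields
`E[MRD%] = 100 e^{s^2/2} (2 Phi(s) - 1)` — the folded-lognormal mean, ~3.99%
at `s = 0.05` — within Monte-Carlo error.

## Problem sizes and numerical defaults

Test and acceptance computations run on the packaged 22-point dataset, 200-
to 500-replicate synthetic ensembles for the stochastic contracts, 5–10
seeded states for the thermodynamic consistency checks, and single-digit
grids for the equation-of-state profiles — sizes chosen so the whole suite
exercises every code path in well under a minute of EOS time while keeping
Monte-Carlo error comfortably below the tested tolerances. Key tolerances:
association 1e-15 (Newton), density root to machine precision (Brent then
Newton), SLE fixed point 1e-8 relative, Wilson objective 1e-15 relative.

## Known limitations

* The equation-of-state route is quantitatively weak on the water-rich side
  with `kij = 0`; fitted binary interaction parameters would be the usual
  remedy and are supported via the `kij` argument but none are shipped.
* Mole-fraction conversions of the *measured* data require unavailable
  solution densities; the package supports the conversion given a density
  but deliberately does not guess one.
* No heat-capacity term in the ideal solubility; near-melting-point
  extrapolations warn.
* The log-linear `M`, `N` constants are cosolvent-specific literature
  values; only ethanol's are packaged.
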
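---
title: "Model balancing: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model balancing: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modelbalance)
```

## The statistical model

Model balancing treats a kinetic metabolic model and a set of metabolic
states as one estimation problem.  The observables are kinetic constants
(Keq, kcat±, KM), metabolite concentrations c(s), and enzyme concentrations
e(s) in states s = 1…S; the metabolic fluxes v(s) are *inputs*, assumed
known and thermodynamically feasible.  All multiplicative quantities are
modelled on natural-log scale, where lognormal priors and multiplicative
measurement noise become Gaussian.

The free variables are collected in

y = (q_basic, x(1), …, x(S)),

where x(s) = ln c(s) and q_basic is the *basic kinetic vector*:

* g_i per metabolite — a dimensionless potential-like term (interpretable
  as −μ°/RT) with ln Keq = −Sᵀ g.  Wegscheider cycle conditions
  (kᵀ ln Keq = 0 for every k with S k = 0) then hold identically.
* ln KM_{l,i} per (reaction, participating metabolite) pair, in ln(mM).
* ln kV_l per reaction, in ln(1/s) — the velocity constant, the geometric
  mean of kcat+ and kcat−.

All remaining constants are exact linear functions of q_basic; in
particular ln kcat±_l = ln kV_l ± ½(ln Keq_l − Σ_i S_il ln KM_il), which is
the Haldane relationship solved for kcat±.  Because the expansion is linear
(offset zero), thermodynamic consistency is structural: no penalty terms or
constraint tolerances are involved, and `check_haldane()` /
`check_wegscheider()` residuals are at machine precision for any basic
vector.

Enzyme concentrations are *dependent* variables.  Under the common modular
(CM) reversible rate law — whose uni-uni special case is reversible
Michaelis–Menten — the catalytic rate per unit enzyme is

k_l = (kcat+ Π_sub (c/KM)^m − kcat− Π_prod (c/KM)^m) / D,
D = Π_sub (1+c/KM)^m + Π_prod (1+c/KM)^m − 1,

and the enzyme demand is e_l(s) = v_l(s) / k_l(q, c(s)).  The rate
factorises exactly as k = kcat⁺·η_rev·η_sat with η_rev = 1 − e^(−θ) and a
saturation efficiency η_sat ∈ (0, 1]; the package tests verify this
identity to 1e−10 on random Haldane-consistent draws.  Both ln e and e are
convex in y; this convexity (checked by midpoint tests rather than proven
here) is what makes the whole approach tractable.

## The score and the stringency parameter α

Priors and data are combined per block by precision-weighted Gaussian
combination (precisions add; means are precision-weighted averages), giving
a *preposterior* for the (q, x) blocks and for the log enzyme levels z.
Missing data simply leave the prior; duplicate measurements each add their
precision.  Data on dependent constants (Keq, kcat±, or KM) are Gaussians
on linear functions of q_basic and enter the quadratic form through the
expansion rows, so a Keq datum informs g, and through Haldane also kcat
estimates.

The posterior loss is

R(y) = quad(y − ȳ_po, Σ_po)  +  Σ_s quad_α(z_s(y) − z̄_po,s, Σ_po,z),

with quad(a, Σ) = ½ aᵀ Σ⁻¹ a.  The first term is strictly convex
quadratic.  The enzyme term composes a convex z(y) with a quadratic, which
is convex only where the outer function is non-decreasing — i.e. the
*below-mean* branch of each enzyme term is the only non-convex piece.
quad_α scales exactly that branch by α ∈ [0, 1]:

* α = 0 removes it: the problem becomes strictly convex with a unique
  optimum (multistart runs agree coordinate-wise to < 1e−4 in the tests),
  but enzyme levels may be under-estimated since nothing penalises small
  predicted enzymes.
* α = 1 is the full posterior, possibly multi-modal.
* Intermediate α trades the two off.  The default is α = 0.5, the value
  used in all benchmark runs.  A practical recipe: start small and increase
  α until the enzyme fitting error becomes acceptable; values above about
  0.1 behaved well in our synthetic runs.

Scaling the branch by α is equivalent to assuming a larger standard
deviation for below-mean log enzyme levels, by the factor √(1/α) (≈ 3.16 ≈ 3
at α = 0.1): the variance, not the sd, scales by 1/α.
`alpha_sd_inflation()` measures this factor directly from `quad_alpha()`.

Zero-flux reactions: at v_l(s) = 0 the demand is undefined on log scale
(e = 0 or equilibrium).  Such reactions are omitted from the enzyme score
of that state, and their enzyme data are ignored even if present; the
result marks these estimates as absent (NA), not zero.

## The feasible polytope and the solver

The constraint set over y is a convex polytope: box bounds on g
(|g| ≤ 50), ln KM (1e−5…1e3 mM), ln kV (1e−4…1e5 1/s), and log
concentrations (1e−6…1e2 mM, per-metabolite overrides allowed), plus the
force-sign constraints sign(v_l)·θ_l ≥ ε for every active reaction and
state.  The margin ε = 1e−3 RT replaces the strict inequality; it keeps
η_rev ≥ 1 − e^(−ε) > 0 and enzyme demands finite.  The bounds are our
choices (physiological ranges); ε is likewise a package choice, as no value
is prescribed for it anywhere.

Feasibility of each state's fluxes is certified up front by a linear
program (maximal normalised slack, i.e. a Chebyshev-style centre, solved
with `boot::simplex`); the same LP provides interior starting points.
Initialisation uses the preposterior (q, x) means when strictly feasible,
else their least-squares projection onto a slightly shrunken polytope.

The optimiser is `stats::constrOptim` (adaptive log-barrier with BFGS
inner iterations) with *analytic* gradients: the Jacobian of z(y) is
assembled in closed form and validated against central differences at
relative 1e−5 in the tests.  Rate-law algebra runs on log scale
(`log1p`/`log1mexp`-style evaluations) so polytope corners do not overflow.
For α > 0 the default is continuation: solve the strictly convex α = 0
problem first, then warm-start the target α.  This does not guarantee the
global optimum of a non-convex α = 1 problem, but in practice it lands in
the basin connected to the convex solution, which is the behaviour the
method intends.  Convergence is reported via gradient norm and a KKT
stationarity residual (non-negative least squares on near-active constraint
normals).  A disciplined-convex-programming backend would be a natural
second engine for α = 0; none is available in the dependency set, so
multistart agreement serves as the convexity cross-check instead.

`maximum_likelihood_mode()` inflates all prior sds by 1e3 (capped at 30
natural-log units to stay finite), preserving bounds: with abundant data it
tracks the posterior mode; without data it is bound/polytope-driven and
flagged accordingly.

## The synthetic-data generator

The generator emulates the benchmark protocol: draw a "true" basic vector
from the priors (so the priors are realistic by construction), simulate
steady states with random enzyme levels and external concentrations, and
perturb observations multiplicatively.

Defaults define the stated world and are not tuned per run:

| quantity | median | geometric sd |
|---|---|---|
| Keq | 1 | 10 |
| kV | 10 s⁻¹ | 10 |
| KM | 0.1 mM | 10 |
| metabolite conc. | 0.1 mM | 10 |
| enzyme conc. | 1e−3 mM | 10 |

The g term gets sd log(10)/√2 so that a uni-uni reaction's Keq has
geometric sd 10; for reactions with more participants the implied Keq
spread is wider, which we accept as a property of the potential-based
parameterisation.  Scenarios: S1 exposes all kinetic constants as data,
S1K only equilibrium constants, S2 none; state data (concentrations,
enzymes, fluxes) are always included.  Noisy variants use geometric sd 1.2
for state data and 1.5 for kinetic data; noise-free variants use gsd 1.
Data tables carry an *assumed* uncertainty (the noise gsd, floored at 1.05
for noise-free data so that precisions stay finite); six states is the
default.

Steady states are found by a damped Newton iteration on d(ln c)/dt = 0,
globalised by bursts of an embedded Runge–Kutta (Bogacki–Shampine 3(2))
integrator in log-concentration space, to a relative stationarity tolerance
of 1e−9 s⁻¹.  Draws are retried (fresh enzymes/externals, then a fresh
model) until states converge, stay strictly inside the default bounds, and
keep every active force at least 2ε from zero — otherwise the truth would
sit outside the estimation polytope and recovery tests would be vacuous.
All draws take explicit seeds and are bit-reproducible.

What the generator does *not* emulate: realistic network topologies beyond
small chains/branches/cycles (any user-supplied network works, but the
bundled examples are small), correlated measurement errors, missing-at-
random data patterns, non-stationary snapshot states, and allosteric
regulation (excluded from the default schema).  A green recovery test
therefore establishes correctness of the estimation machinery under the
model's own assumptions, not performance on real omics data.

## Reporting conventions

Recovery is quantified per quantity type by the Pearson correlation of
log values and by the geometric standard deviation of residuals,
exp(√mean((ln a − ln b)²)); both are invariant under common unit
rescaling.  Correlations pool all states (the alternative, per-state
metrics, is not computed; pooling is the documented choice).  Quantity
types backed by data in a scenario are flagged "fitted", others
"predicted".  kcat+ and kcat− are pooled into one "kcat" type.

## Known limitations

* The α = 1 posterior may be multi-modal; continuation from α = 0 yields
  one well-defined mode, with no global guarantee.
* `boot::simplex` is adequate for the small LPs here but not for
  genome-scale polytopes; swapping in a sparse LP/QP backend would be the
  first step toward larger models.
* Stoichiometric coefficients are restricted to integers (they appear as
  exponents in the CM rate law); non-integer input is rejected.
* Cross-covariances between constant types in the preposterior are omitted
  (block treatment); physical dependencies are nevertheless exact because
  they live in the parameterisation, not the covariance.
* Posterior uncertainty (sampling or a Laplace approximation around the
  mode) is not implemented; the package reports the mode only.
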
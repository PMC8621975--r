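# modelbalance

Joint Bayesian estimation of enzyme kinetic constants and metabolic states
("model balancing") for kinetic metabolic models with known fluxes.

## The problem

Kinetic metabolic models need equilibrium constants (Keq), catalytic
constants (kcat±, 1/s), and Michaelis–Menten constants (KM, mM) for every
reaction, plus metabolite concentrations c (mM) and enzyme concentrations e
(mM) for every metabolic state of interest.  In-vivo values are mostly
unknown; omics data are noisy and incomplete; and thermodynamics couples
everything: Wegscheider conditions tie Keq values around cycles, Haldane
relationships tie Keq, kcat± and KM within each reaction, and flux
directions must follow the signs of the thermodynamic forces
θ = ln Keq − Sᵀ ln c.

Given thermodynamically feasible fluxes v(s) for one or more states, this
package estimates all of the above jointly as the mode of a Bayesian
posterior.  Key structural facts, exploited throughout:

* All multiplicative quantities are handled on natural-log scale.
* Kinetic constants are parameterised by an independent *basic* vector
  (a per-metabolite potential-like term g with ln Keq = −Sᵀg, ln KM per
  reactant, ln kV per reaction, where ln kcat± = ln kV ± ½(ln Keq −
  Σᵢ S_il ln KM_il)), so Haldane and Wegscheider identities hold *by
  construction*, not as constraints.
* With fluxes fixed, the enzyme demand e_l = v_l / k_l(q, c) implied by the
  modular reversible (CM) rate law is a convex function of the log
  variables, and the feasible set — bounds plus force-sign constraints
  sign(v_l)·θ_l > 0 — is a convex polytope.
* The posterior score is R(y) = quad(y − ȳ_po, Σ_po) +
  quad_α(z(y) − z̄_po, Σ_po,z), where quad(a, Σ) = ½aᵀΣ⁻¹a and quad_α
  scales the *below-mean* enzyme branch by a stringency parameter
  α ∈ [0, 1].  At α = 0 the problem is strictly convex (unique optimum);
  α = 1 is the full posterior; the package default α = 0.5 is solved by
  continuation from the α = 0 optimum.  Lowering α is equivalent to
  inflating the assumed sd of below-mean log enzyme levels by √(1/α).

A synthetic-data module generates ground-truth models from the priors,
simulates steady states, adds multiplicative noise (geometric sd 1.2 for
state data, 1.5 for kinetic data in the noisy scenarios), and assembles the
benchmark scenarios S1 (all kinetic constants given as data), S1K (only
Keq), and S2 (no kinetic data).  Reports quantify recovery by log-scale
Pearson correlation and the geometric standard deviation of residuals.

## Worked example

```r
library(modelbalance)

net <- example_network("chain", 5)          # Xin <-> M1 ... <-> Xout
ds  <- make_scenario_dataset(net, "S1K", n_states = 6,
                             state_gsd = 1.2, kinetic_gsd = 1.5, seed = 3)
prob <- mb_problem(net, ds$fluxes, ds$data, alpha = 0.5)
res  <- balance(prob)
build_report(ds$truth, res, "S1K")$metrics
```

Output printed by this exact run:

```
                  quantity     r_log       gsd  n      role
1 metabolite concentration 0.9961331  1.178982 36    fitted
2     enzyme concentration 0.9935532  1.216985 30    fitted
3                      Keq 0.9925319  1.195931  5    fitted
4                     kcat 0.3881150 10.493822 10 predicted
5                       KM 0.1286665 11.397741 10 predicted
```

Reading: quantities with data (concentrations, enzymes, Keq) are *fitted*
and recovered to roughly the noise level (gsd ≈ 1.2 against injected noise
of 1.2/1.5).  kcat and KM carry no data in scenario S1K and are *predicted*
from state data alone: kcat values retain some signal (r ≈ 0.39), KM values
are predicted poorly (r ≈ 0.13) — noisy omics data constrain saturation
states only weakly.  With noise-free complete data (scenario S1,
`state_gsd = 1`, `kinetic_gsd = 1`) every quantity is recovered with
r ≥ 0.99 and gsd ≤ 1.01.

A command-line interface covers the same pipeline (the script is installed
at `system.file("exec", "modelbalance", package = "modelbalance")`, or call
`Rscript -e 'modelbalance::run_cli()' <subcommand> ...`):

```sh
modelbalance simulate --network net.tsv --metabolites mets.tsv \
    --scenario S1K --n-states 6 --seed 1 --out sim/
modelbalance balance  --network net.tsv --metabolites mets.tsv \
    --fluxes sim/fluxes.tsv --data sim/data.tsv --alpha 0.5 --out res/
modelbalance report   --network net.tsv --metabolites mets.tsv \
    --truth sim/ --result res/ --out report.tsv
```

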
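# omgsim

Simulated Design–Build–Test–Learn (DBTL) cycles for metabolic engineering,
entirely in silico. omgsim generates credible mock multiomics data from
constraint-based metabolic models and closes the loop around it: it
simulates a wild-type batch culture, derives proteomics / transcriptomics /
metabolomics / fluxomics time series, simulates the production phenotype of
categorically designed strains, trains a probabilistic surrogate on the
(design, production) pairs, and recommends the next round of strains — then
checks the recommendations against the simulator's own ground truth.

It is aimed at people who build or evaluate bioengineering data
infrastructure and recommendation algorithms: synthetic data is cheap,
mechanistically plausible, and comes with exhaustively computable ground
truth at toy scale.

## The models at the core

* **Flux balance analysis.** Wild-type fluxes solve
  `max V_biomass s.t. S V = 0, lb ≤ V ≤ ub`. Because the LP optimum is
  degenerate, omgsim returns the minimum-norm optimal flux vector via exact
  L2 regularization (a strictly convex quadratic program), making every
  downstream quantity deterministic.
* **MOMA.** An engineered strain's fluxes minimize `Σ_j (V_j − V_wt,j)²`
  subject to steady state and the design-modified bounds. Infeasible means
  lethal.
* **Batch dynamics.** Per time step `Δt`: `[cell] ← [cell]·exp(μΔt)` and
  `[met] ← [met] + v_EX · Δ[cell]/μ`, with exchange bounds capped so no
  concentration goes negative, until the carbon source is exhausted.
* **Mock omics.** `P_j = |V_j|/k + β` (k = 0.1), `T_j = P_j/q + γ`
  (q = 0.833), `M_i = Σ_j |S_ij V_j| / n_i`; β, γ are Gaussian with
  standard deviation 5% of the signal.
* **Designs.** Per target reaction: 0 = knockout, 1 = no modification,
  2 = double the wild-type flux of the same time point. Eight targets give
  a 3⁸ = 6561-design space; training batches are 96-design Latin-hypercube
  samples (one plate, wild type included).
* **Recommender.** A 200-member bootstrap ensemble of regression trees on
  the categorical designs; candidates are scored by exhaustive enumeration
  and ranked by the ensemble median of predicted production, with
  uncertainty from the ensemble spread.

## A worked example

```r
library(omgsim)

model <- make_toy_model()                      # deterministic toy network
conditions <- batch_conditions(c(glc_e = 22, prod_e = 0, ac_e = 0),
                               primary_substrate = "glc_e")
cycle <- run_dbtl_cycle(model, conditions,
                        target_reactions = toy_design_targets(model),
                        target_metabolite = "prod_e",
                        n_designs = 96, k = 10, seed = 1, cv_folds = NULL)

max(cycle$productions)   # best production among the 96 training designs
#> [1] 1.744714
max(cycle$observed)      # best among the 10 recommended strains
#> [1] 2.016849
```

The 96 Latin-hypercube training strains reach at most 1.74 mM of the target
product; the surrogate, having seen only those, recommends ten unseen
designs whose best simulated production is 2.02 mM — a 15.6% improvement
discovered from 1.5% of the design space. The recommended optimum doubles
the first step of the product pathway and leaves the rest of the network
unmodified.

Individual stages are available separately: `run_wt_batch()`,
`omics_from_series()`, `latin_hypercube_designs()`,
`simulate_design_production()`, `fit_surrogate()` / `recommend()`, and the
`write_edd_generic()` / `read_edd_generic()` interchange layer (five-column
measurement CSV: line, typed identifier, time, value, unit). A thin command
line lives at `inst/scripts/omg` (`toy-model`, `simulate-wt`, `designs`,
`simulate-designs`, `recommend`).

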
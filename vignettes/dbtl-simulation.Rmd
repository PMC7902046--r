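---
title: "Simulating a Design-Build-Test-Learn cycle with omgsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a Design-Build-Test-Learn cycle with omgsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omgsim)
```

omgsim simulates, end to end and entirely in silico, the iterative loop at
the heart of modern metabolic engineering: *design* a set of genetic
modifications, *build* the strains, *test* their production, and *learn* a
predictive model that proposes the next, better round of designs. Every
stage — the host's metabolism, the culture, the measurements, and the
recommender — is a model, which makes the package a controlled test bed for
multiomics tooling and recommendation algorithms at a scale where exhaustive
ground truth is computable.

## The metabolic model and its two optimization primitives

The substrate of everything is a stoichiometric model: a matrix $S$
($m$ metabolites $\times$ $n$ reactions), flux bounds $lb_j \le V_j \le
ub_j$ (mmol/gDW/h), and a biomass objective. Two constrained-optimization
primitives act on it.

**Flux balance analysis (FBA)** predicts the wild-type flux distribution by
maximizing the biomass flux subject to steady state,
$$\max V_{biomass} \quad \text{s.t.}\quad S V = 0,\; lb \le V \le ub.$$
This linear program is underdetermined: the optimal face typically contains
infinitely many flux vectors. Downstream omics generation needs *one*
reproducible representative, so `solve_fba()` applies an exact L2
regularization: it minimizes $\tfrac{\varepsilon}{2}\lVert V\rVert^2 -
V_{biomass}$ for a small $\varepsilon$. For $\varepsilon$ below a
problem-dependent threshold this returns exactly the minimum-norm point of
the LP's optimal face (the exact-regularization property of linear
programs), so the objective value is the true LP optimum and the flux
vector is unique and deterministic. A decreasing ladder of $\varepsilon$
values (defaults `1e-4, 1e-6, 1e-8`) is solved until two successive weights
agree on the objective to `optimality_tol` ($10^{-8}$); each solve is a
strictly convex quadratic program handled by the Goldfarb–Idnani active-set
method. Two numerical details matter in practice and are part of the
contract. First, pinned fluxes ($lb_j = ub_j$, the encoding of knockouts and
forced doublings) are eliminated by substitution before the QP is formed —
active-set solvers treat a pair of opposing inequalities as degenerate — and
the consistency of the eliminated system is re-verified on every solution,
which is also how genuinely infeasible (lethal) pin sets are detected.
Second, heavily degenerate vertices (many coincident active bounds, typical
for starved or knocked-out networks) can make the active-set method report a
spurious inconsistency; the solver then retries once with each inequality
relaxed by a distinct $O(10^{-9})$ amount, which breaks the ties without
affecting any quantity above the feasibility tolerance.

**Minimization of metabolic adjustment (MOMA)** predicts how an engineered
strain behaves: rather than re-optimizing growth, the perturbed strain is
assumed to stay as close as possible to the wild-type flux state,
$$\min \sum_j (V_j - V^{wt}_j)^2 \quad \text{s.t.}\quad S V = 0,\;
lb' \le V \le ub',$$
where the primed bounds carry the design constraints. This is a strictly
convex QP with a unique minimizer. An infeasible MOMA problem means the
design admits no steady state at all; callers treat it as lethal.

The test suite checks both primitives against independent brute-force
oracles: FBA against exhaustive vertex enumeration of the flux polytope, and
MOMA against a null-space least-squares projection (and, with bounds
active, against an unrelated SQP optimizer), at $10^{-6}$ tolerance on
dozens of random instances.

## Batch-culture simulation

`run_wt_batch()` turns single-time-point FBA into a time series. At each
time $t_k$ the model is solved under the current extracellular conditions;
the cell density then grows exponentially, $[cell]_{k+1} = [cell]_k
e^{\mu\Delta t}$, and each tracked extracellular metabolite is updated by
$$[met]_{k+1} = [met]_k + v_{EX}\,\frac{\Delta[cell]}{\mu},$$
the exponential-growth form of the first-order update $v_{EX}\,\Delta
t\,[cell]$ (the two coincide as $\mu \to 0$, and below `mu_min` — default
$10^{-6}$/h — the linear form is used directly). For a constant-yield phase
this discrete scheme is *exact*: the simulated trajectory coincides with
the closed-form solution of the two-ODE batch system, which the test suite
verifies. The loop stops when the primary substrate falls below an
exhaustion threshold (default $10^{-3}$ mM), growth ceases, or `max_time`
is reached.

Because a flux solution is computed *before* the step it governs, uptake
could overshoot the available substrate near exhaustion. The simulator
therefore caps exchange lower bounds inside a small fixed-point iteration —
solve, project the step, tighten the offending exchange bound to
$-[met]\,\mu/\Delta[cell]$, re-solve — so concentrations can never go
negative. The defaults ($\Delta t = 1$ h, 24 h horizon, 0.01 gDW/L
inoculum, 22 mM glucose) describe a typical well-plate batch culture; all
are configurable in `batch_conditions()`.

Engineered strains are propagated *independently* on the wild-type time
grid (`run_designed_batch()`): at each time point MOMA is solved against
the wild-type flux vector of that same time point, but the engineered
strain's own density and concentrations evolve from its own fluxes. The
alternative reading — overlaying MOMA fluxes on the wild-type trajectory —
is available via `overlay_wt = TRUE`; independent propagation is the
default because a design that slows growth must also deplete substrate more
slowly.

## Synthetic omics

Three deliberately simple, transparent transformations turn a flux state
into mock measurement tables:

* proteomics: $P_j = |V_j|/k + \beta$, with $k = 0.1$ and
  $\beta \sim N(0, (f\,|V_j|/k)^2)$;
* transcriptomics: $T_j = P_j/q + \gamma$, with $q = 0.833$ and the same
  relative-noise construction;
* metabolomics: $M_i = \sum_j |S_{ij} V_j| / n_i$, the mean absolute
  stoichiometric flux through metabolite $i$ — no noise term.

The noise fraction $f$ defaults to 0.05 ("5% of the signal"); noise is
Gaussian with standard deviation proportional to the signal, so a zero flux
always yields exactly zero protein and transcript. The linear maps are
applied to $|V_j|$ rather than the signed flux — a reversible reaction
carrying negative flux still needs its enzyme — with `signed_fluxes = TRUE`
restoring the literal signed form. One shared seeded generator is consumed
in sorted reaction-id order, so row order can never change a value and
identical seeds reproduce identical tables bit for bit. These are mock
relationships by construction: no saturation kinetics, no $k_{cat}$, no
regulation. They produce data that is *plausibly shaped* (zeros where there
is no flux, proportionality elsewhere), which is what testing of pipelines
and repositories needs, not biological truth.

## The categorical design space

A strain design assigns each target reaction one of three categories:
knockout (0), no modification (1), or flux doubling (2). Knockouts pin the
flux to zero; doubling pins it to twice the wild-type flux *of the same
time point*, so the constraint tracks the batch trajectory. Doubling a
reaction with zero wild-type flux is a documented no-op pin ($0 = 2\cdot
0$). With eight targets the space holds $3^8 = 6561$ designs; a 96-design
initial batch (one microtiter plate, wild type included) covers 1.46% of
it.

Initial designs are drawn by Latin-hypercube sampling on $[0,1]^d$, mapped
to categories by $\lfloor 3x \rfloor$ (clipped to 2 at $x = 1$) — each
coordinate's range is evenly covered, so every category appears nearly
equally often per reaction. Collided rows are redrawn individually, keeping
the stratified rows that did not collide, and the wild-type design is
appended last.

## The probabilistic surrogate and its acquisition rule

The recommender is a bootstrap ensemble (default 200 members) over the
categorical design space; the spread of member predictions is the
predictive uncertainty. Two member families are built in: rank-safe linear
regression on one-hot category indicators (`member = "linear"`), suited to
additive landscapes, and regression trees (`member = "tree"`, the default),
which capture the strong interactions characteristic of knockout
landscapes — a modification that helps only while a competing pathway is
intact, or a combination that is jointly lethal. Trees are grown deep
(`minsplit = 5`, `cp = 0.002`); the ensemble, not pruning, supplies the
variance control. Training rows are canonicalized to lexicographic order
before fitting, so row order cannot change the model for a fixed seed.

Candidate designs are scored by exhaustive enumeration of the space
(bounded at $10^6$), training designs are excluded, and the top $k$ are
returned. The ranking statistic is the ensemble *median* rather than the
mean: on landscapes with lethal designs the member predictions for a
candidate are strongly bimodal (part of the ensemble classifies it as
non-viable), and the median is the more robust exploitation statistic — a
choice made after benchmarking mean, median, trimmed means, upper
quantiles, expected improvement, and Thompson-style batch selection on the
package's own synthetic landscape. Ties are broken by higher mean, then
lower predictive spread, then lexicographic order, so recommendations are
deterministic. Expected-improvement ranking remains available via
`surrogate_config(acquisition = "expected_improvement")`.

This surrogate reproduces the decision-relevant *interface* of heavier
Bayesian recommendation engines — probabilistic predictions, uncertainty
that shrinks with data, ranked recommendations — not any particular
posterior mathematics.

## The built-in toy system

`make_toy_model()` builds a deterministic, fully mass-balanced toy network
(17 metabolites, 26 reactions by default): glucose uptake, two parallel
glycolytic routes with different ATP yields, pyruvate dehydrogenase and a
pyruvate-formate-lyase alternative, anaplerosis (PPC) with a
carboxykinase-like reverse (PPCK) closing an ATP-dissipating futile cycle,
a citrate loop (CS/CITD) that is the cell's main ATP source, acetate and
lactate overflow routes, an ATP-maintenance sink, and a two-step
heterologous branch from acetyl-CoA to a secreted target product. Biomass
draws pyruvate, acetyl-CoA, oxaloacetate, ATP, and both the branch
intermediate and the product (isoprenoid intermediates are genuine biomass
components), so every design target except PPCK carries nonzero wild-type
flux and modifications have graded, distinguishable effects under MOMA.

Two properties are engineered exactly and exploited by the tests. First,
the biomass composition sums to precisely $2/Y$ pyruvate equivalents, so
the FBA growth optimum equals `uptake_max * biomass_yield` — closed-form
checks of the batch dynamics follow. Second, the ATP demand exceeds the
glycolytic supply, forcing the citrate loop to run at the wild-type
optimum; knocking it out redistributes flux into the product branch, the
toy-scale analogue of the production-improving knockouts that motivate the
whole workflow.

What the toy system does *not* emulate: genome-scale redundancy (thousands
of reactions and alternate routes), gene–protein–reaction logic,
regulation, kinetics, or quantitative agreement with any real organism.
Passing tests demonstrate that the machinery — solvers, propagation, omics,
sampling, learning, recommendation — behaves correctly and that the loop
closes at desk scale; they say nothing quantitative about *E. coli*. Users
with network access can rerun the workflow on a published genome-scale
reconstruction via `download_genome_scale_model()`; nothing in the test
suite requires it.

## A worked cycle

```{r cycle, eval = FALSE}
model <- make_toy_model()
conditions <- batch_conditions(c(glc_e = 22, prod_e = 0, ac_e = 0),
                               primary_substrate = "glc_e")
cycle <- run_dbtl_cycle(model, conditions,
                        target_reactions = toy_design_targets(model),
                        target_metabolite = "prod_e",
                        n_designs = 96, k = 10, seed = 1)
max(cycle$productions)        # best production in the training plate
max(cycle$observed)           # best among the 10 recommended strains
```

The stochastic end-to-end property asserted by the test suite: across ten
fixed seeds, the recommender proposes a strain whose simulated production
strictly exceeds the best training-set production in at least eight. The
two failure modes observed at this scale are instructive rather than
pathological: occasionally the 96-design sample already contains a
globally optimal design (no strict improvement exists — at toy scale the
optimum is a tiny equivalence class, e.g. the exact tie between knocking
out and "doubling" the zero-flux PPCK reaction), and occasionally the
training draw contains too little signal about the productive region of the
space. Both are properties of small design spaces, not of the method.

## Problem sizes and runtime

All shipped analyses are desk-scale by design: the toy network has 26
reactions, batch simulations run ~16 time points, the full 6561-design
space enumerates in under a minute, and one complete DBTL cycle (96 MOMA
production simulations, 200-member ensemble, 10 recommendations,
re-simulation) takes a few seconds. The oracle comparisons use 50 random
6-metabolite/10-reaction instances, small enough for exhaustive vertex
enumeration.

## Interchange format

All simulated measurements can be exported in the five-column generic
measurement CSV used by the Experiment Data Depot: line name, typed
measurement identifier (PubChem CID for metabolites, UniProt for proteins,
GenBank gene id for transcripts), time in hours, value, and a unit from the
closed vocabulary {FPKM, proteins/cell, mg/L, mM, ""} — optical density
carries no unit. The canonical identifier spelling is `CID:715`; the spaced
variant `CID: 715` is parsed tolerantly. Header strings are configurable
because live repository instances differ. Writers sort rows by (line,
measurement, time) and the reader is strict: wrong column counts,
unparseable numbers, unknown units, and CID identifiers paired with
non-metabolite units are all rejected with the offending row. Experiment
metadata (line name, strain-registry part id, culture conditions) travels
in a separate experiment-description CSV that deliberately contains no
measurement values.
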
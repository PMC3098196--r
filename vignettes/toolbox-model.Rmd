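---
title: "The toolbox model of metabolic network evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The toolbox model of metabolic network evolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toolboxevo)
```

## The model

Prokaryotic genomes show a quadratic relation between the number of
transcriptional regulators and the total number of protein-coding genes.
The toolbox model explains the metabolic part of this relation with a
single evolutionary mechanism: organisms gain new metabolic capabilities
by horizontal transfer of whole pathways drawn from a *universal network*
(the union of the metabolic repertoires of all potential donors), and
each acquired pathway is controlled by one dedicated regulator. A pathway
is only extended until it meets the organism's existing network, so a
larger toolbox needs fewer new genes per capability: the number of
pathways $N_L$ (equal to the number of regulators) grows faster than
linearly with the number of metabolites $N_M$, as $N_L \propto N_M^\alpha$.

This package implements the model at three levels of realism. The tree
variant is exactly solvable; the linearized variant connects it to real
reaction graphs; the branched variant drops the tree idealization
entirely and works on reaction hypergraphs with multi-substrate
reactions.

## Tree universes and the mean-field theory

The universal network is a rooted tree: the root is the metabolic core,
leaves are nutrients, internal nodes are intermediates, and each pathway
is the unique path from a leaf to the root. Trees are generated by a
two-child Galton--Watson process (`branching_params()`, `sample_tree()`):
each node independently has 0, 1 or 2 children with probabilities
$p_0, p_1, p_2$. The mean offspring number is $\Lambda = p_1 + 2p_2$; the
process is *critical* when $\Lambda = 1$ (equivalently $p_0 = p_2$).
Critical trees have algebraically growing layers and long branches
("large world"); supercritical trees grow exponentially and are shallow
("small world"). Supercritical processes never stop on their own, so
`mode = "fixed_depth"` truncates them at a chosen layer; critical trees
are conditioned on total size by rejection sampling
(`mode = "condition_on_size"`, default tolerance ±10%, attempt cap 1e5;
a node budget of 1e6 guards fixed-depth generation).

An organism that has acquired a fraction $x$ of all leaves holds, at
layer $d$ of the tree, $m_d$ of the $M_d$ universal metabolites,
$\lambda_d = x\Lambda_d$ of its $\Lambda_d$ leaves. Pathways merge at the
$B_d$ branch points, each of whose two downstream branches is occupied
independently with probability $p_{d+1} = m_{d+1}/M_{d+1}$. Counting
unique intermediates gives the recursion implemented by
`mean_field_iterate()`:

$$ m_d \;=\; x\,\Lambda_d \;+\; m_{d+1} \;-\; B_d\!\left(\frac{m_{d+1}}{M_{d+1}}\right)^{\!2}. $$

The recursion runs from the deepest layer toward the root. The boundary
condition is not dictated by the recursion itself; we use
$m_D = x\,\Lambda_D$ (the deepest layer contains only newly entering
leaves), which is the unique choice consistent with the leaf-entry term.
In the bulk the iteration settles on the fixed point of
`steady_state_fraction()`,

$$ p_2\,p^2 - (\Lambda - 1)\,p = x\,p_0 , $$

whose physical root in $[0,1]$ is taken. Two limits matter:

* **Critical** ($p_0 = p_2$): $p_\infty = \sqrt{x}$. Since
  $x = N_L/L_{tot}$ and $p_\infty \approx N_M/M_{tot}$, this *is* the
  quadratic law $N_L = L_{tot}(N_M/M_{tot})^2$, exact for two-child
  critical trees.
* **Supercritical** ($\Lambda > 1$): as $x \to 0^+$ the bulk occupation
  jumps to $p_\infty = 1 - p_0/p_2$, the analogue of a first-order phase
  transition. Because layer sizes grow exponentially, the *network
  average* occupation is dominated by the boundary layers and scales
  linearly in $x$ up to logarithmic corrections; we expose this
  numerically rather than through closed-form asymptotics (the same
  holds for the rate at which the critical layer ratio
  $\mu_d = M_{d+1}/M_d$ approaches 1 — `criticality_profile()` reports
  the measured profile next to the $1 + \theta/d$ reference curve,
  $\theta = 1$, rather than asserting a closed form).

The mean field factorizes $\langle m^2 \rangle \to \langle m \rangle^2$
at branch points and is therefore approximate on finite conditioned
trees: at size $\approx 2000$ and $x = 0.25$ the per-layer bias is about
1% (theory slightly below simulation), visible only once roughly thirty
paired realizations are averaged. The test suite checks per-layer
agreement within three standard errors for the overwhelming majority of
bulk layers, which is what the approximation supports.

## Simulation and scaling analysis

`simulate_full_trajectory()` acquires leaves uniformly at random without
replacement, each time adding the leaf's ancestors up to the first
already-acquired node, and records $(N_L, N_M)$ after every pathway. The
endpoint $(L_{tot}, M_{tot})$ is order-independent; connectivity of the
acquired subtree is an invariant.

Exponents are measured the way the scaling plots are drawn:
`log_bin()` bins trajectories geometrically along $N_M$ (default 10 bins
per decade; the reported abscissa is the within-bin geometric mean) and
`fit_power_law()` fits $\log_{10}$ bin means by least squares. Bins are
weighted by their point counts by default: bin means are heteroscedastic
with standard error $\propto 1/\sqrt{n}$, and an unweighted fit lets
almost-empty early bins — where $N_L$ is pinned at its floor of 1 —
dominate the slope. Zeros in $y$ are kept when averaging (bin means of
byproduct counts legitimately fall below 1) but bins with zero mean are
dropped from the log--log fit. Exponent estimates are stable across
5--20 bins per decade. `fit_power_law_ensemble()` reports both the
pooled fit and the mean ± SD of per-realization exponents.

Study conditions used by the scaling tests, chosen to mirror the
published experiments at desk scale: critical trees ($p_0 = p_2 = 0.25$)
conditioned to $\approx 2000$ nodes, 9 realizations — the pooled fitted
exponent is 1.86--1.96 across seeds. For the supercritical regime we use
$\Lambda = 1.1$ ($p_0 = 0.15, p_1 = 0.60, p_2 = 0.25$) with a depth cap
of 100 layers, so that layer sizes span four decades of exponential
growth and the bulk of the tree is genuinely in the supercritical
regime (shallower caps sit in the critical--supercritical crossover and
measurably steepen the fit), conditioned on survival (≥1000 nodes), with
30 realizations to tame seed-to-seed spread. The fit is restricted to
the first half of each trajectory because the supercritical linear law
is a small-$x$ statement; the saturation tail $x \to 1$ has a different
local slope. Under these conditions the exponent lands at 1.2--1.3,
clearly separated from the critical value 2.

## Linearized reaction universes

`parse_mapformula()` reads the KEGG map-formula dialect
(`RID: MAPID: C… + C… =>/<=/<=> C… + C…`). Directions written `<=` are
normalized by swapping sides; a reaction id seen with conflicting
directions on different maps, or with `<=>`, becomes reversible;
repeated observations merge side-wise. Stoichiometric coefficients are
ignored — the model is boolean, so multiplicity carries no information —
and metabolites appearing on both sides of one reaction are vacuous and
removed (from the substrate side; from both sides when reversible).

`project_simple_graph()` expands each directed reaction instance into
all substrate→product edges. On such simple graphs, ubiquitous currency
co-factors (water, ATP, NAD, …) create biochemically meaningless
shortcuts — e.g. apparent one-step conversions between unrelated carbon
skeletons through a shared co-factor — so `remove_currency()` deletes a
configurable id list (a default list ships in
`inst/extdata/currency_metabolites.txt`) and optionally any metabolite
above a degree threshold.

Two linearizations produce universal trees from the graph, with the
walker allowed to traverse reversible reactions in either direction:

* `random_spanning_tree()`: repeatedly pick an uncovered metabolite
  (uniformly among those with a directed path to the root) and extend a
  self-avoiding random walk until it merges with the tree or reaches the
  root. Dead-ended walks restart from the same metabolite (cap 100, then
  a shortest-path fallback for that metabolite, reported). This yields
  critical-like, deep trees.
* `shortest_path_tree()`: breadth-first tree of shortest directed
  distances to the root, parents drawn uniformly among equidistant
  neighbors (seeded). This yields supercritical, logarithmically shallow
  trees — shortest-path levels never exceed random-walk levels node by
  node.

The contrast between the two is the point: the toolbox model on the
former scales quadratically, on the latter near-linearly, and the layer
ratio $\mu_d$ tells the two topologies apart.

## The branched model

Real reactions have multiple substrates and products, and a reaction
cannot run until *all* substrates are present. This AND constraint is
what `expand_scope()` implements: starting from a metabolite core, layer
$n$ collects every directed reaction instance whose substrates all
became producible before step $n$; their products extend the core; the
process continues to a fixed point (or stops when a requested target
first appears). The expansion is deterministic and seed-independent.
The cumulative metabolite counts $S_n$ give `expansion_profile()`, the
hypergraph analogue of the criticality diagnostic: for the curated
reaction universes this ratio approaches 1 over roughly 40 layers —
AND semantics restores the "large world" that simple-graph shortcuts
destroy.

`backtrack_pathway()` converts an expansion into a minimal pathway: pick
uniformly among the target's producers in its first layer, then recurse
on every substrate not in the core, always strictly descending in
layers; each metabolite gets at most one producer (memoization prevents
duplicated sub-pathways and guarantees termination), and a pathway never
uses both directions of one reversible reaction (if every candidate
producer conflicts, the conflict is allowed with a warning rather than
aborting a long simulation). Backtracking alone yields a minimal *or
nearly minimal* set, so a pruning pass then removes redundant reactions:
feasibility is monotone in the reaction set, hence a set from which no
single reaction can be removed has no feasible proper subset at all, and
iterated single-removal with closure replay guarantees subset
minimality. Tie-breaks are uniform and seeded.

`pathway_geometry()` quantifies each pathway's position relative to the
core: `n_border_rxn` (reactions touching the core as substrate or
product), `n_base` (core metabolites consumed), `n_feedback` (core
metabolites produced), `n_byproduct` (terminal products that are neither
core, nor target, nor consumed within the pathway), `length` (expansion
layers from core to target — we use the target's first-layer index, also
when the expansion was truncated at the target), `N_M_path` (non-core
metabolites created) and `N_R_path`. A metabolite that is both a core
product and terminal counts as feedback, never as byproduct. Currency
metabolites are excluded from byproduct counts by default (they are
ubiquitously recycled); a flag restores them. The simple-graph baseline
`shortest_distance_to_core()` bounds pathway length from below; on
realistic universes AND-feasible pathways are severalfold longer than
the geometric distance, which is precisely why multi-substrate realism
restores criticality.

The evolutionary loop (`init_state()`, `acquire_target()`,
`simulate_evolution()`) starts from a seed core — for KEGG-style runs,
central carbohydrate metabolism plus currency metabolites — and
repeatedly: draws a target uniformly among scope metabolites the
organism cannot yet synthesize, expands from the current core until the
target, backtracks a minimal pathway, transfers its reactions, and adds
every newly producible metabolite to the core. Owning an enzyme makes
both directions of a reversible reaction available, so the core is kept
closed under the acquired reaction set (the incremental closure is
checked against a from-scratch recomputation in the tests). Metabolites
acquired as intermediates or byproducts leave the target pool without
incrementing $N_L$ — only deliberate acquisitions are pathways and earn
a regulator. $N_M$ counts all core metabolites including the seed by
default; the offset is constant and irrelevant to fitted exponents
(`include_seed_in_NM = FALSE` removes it).

`candidate_targets` optionally restricts the target pool. Its purpose is
cross-model consistency checks: with all multiplicities forced to (1,1)
a tree-shaped universe makes scope expansion plain reachability, and the
branched model with targets restricted to the tree's leaves is *exactly*
the tree toolbox model (`tree_to_universe()` builds the anabolic
universe). Without the restriction the two processes genuinely differ —
internal metabolites are legitimate targets in the branched model and
inflate the acquisition count — so the matched-pool comparison is the
meaningful one.

## The synthetic universe generator

`generate_synthetic_universe()` emulates the structural features of the
curated KEGG reaction set that drive the model's behavior, so that the
branched model can be exercised and tested without a database download:

* **Layered hypergraph.** Metabolites occupy layers $0..L$ (layer 0 is
  the seed set); every reaction produces metabolites of its own layer
  from substrates of strictly lower layers, at least one from the
  immediately preceding layer. Every non-seed metabolite has at least
  one producer, so the scope of the seed set is the whole universe and
  the expansion advances exactly one layer per step — the algebraic,
  critical-like growth seen in the real data ($S_{n+1}/S_n \to 1$ over
  $\approx 40$ layers).
* **Empirical multiplicities.** Substrate/product counts are drawn from
  the published KEGG joint distributions (`kegg_multiplicity_tables()`;
  e.g. weight 491 for 2-substrate/2-product irreversible reactions),
  with separate tables for irreversible and reversible reactions.
* **Currency bias.** Secondary substrates are currency metabolites with
  probability 0.8, reflecting that multi-substrate reactions
  overwhelmingly pair one pathway intermediate with a co-factor; this is
  what keeps minimal pathways thin and "conveyor-belt"-like rather than
  exponentially branching.
* **Defaults fixed at KEGG-like values**: 2000 metabolites, 40 layers,
  40 seed metabolites of which 10 currency, reversibility fraction 0.5
  (KEGG: 1417 of 2819), and twice as many extra (non-covering) reactions
  as covering ones, giving a reaction:metabolite ratio near the curated
  network's 1.5 and multiple alternative producers per metabolite.

What the generator does **not** emulate: products never sit in lower
layers than their reaction, so feedback into the core only appears once
the core has grown into a reaction's own layer, and early pathways have
more byproducts than real KEGG pathways (where ~97% of acquired pathways
are byproduct-free); there is no modular pathway structure, no atom
conservation, and cycles arise only through reversibility. Passing tests
on generated universes therefore demonstrate the scaling mechanism —
criticality of the expansion plus minimal pathways give $\alpha \approx
2$ (measured 1.94--2.02 pooled over 9 realizations) — but not the
byproduct statistics or regulon-size distributions of the real network,
which require the curated reaction database as input
(`parse_mapformula()` accepts it directly).

## Degenerate inputs and numerical conventions

Offspring probabilities must sum to 1 within 1e-9. `p2 = 0` makes the
fixed-point equation linear and `steady_state_fraction()` returns $x$
itself. Empty universes parse to empty objects; reactions emptied by
normalization or currency removal are dropped and reported. Expansion
from a core that can fire nothing has zero layers, and
`expansion_profile()` refuses it. Rejection sampling failures, node
budget overruns, unknown metabolite ids, unreachable targets and invalid
configurations raise errors with the offending field or id named. All
randomness flows through R's session RNG; every simulation entry point
takes an optional `seed`, recorded in its output, and
`run_experiment()` derives per-realization seeds as `seed + 0..n-1` so
bundles are byte-reproducible.

## Known limitations

The catabolic variant of the branched model (reversing all reactions) is
not simulated; target selection is uniform and the donor pool unlimited,
as in the published model; flux, stoichiometric yield and thermodynamics
are out of scope — byproducts are counted, not weighed. The mean-field
theory assumes at most two-fold branching; spanning trees of reaction
graphs may branch arbitrarily, for which the layer-conservation identity
generalizes but the closed forms do not.
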
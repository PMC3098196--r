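# toolboxevo

Toolbox models of metabolic network evolution in R.

In prokaryotes the number of transcriptional regulators grows roughly as
the **square** of the number of protein-coding genes. The toolbox model
explains this for metabolism: an organism evolves by horizontally
acquiring entire metabolic pathways from a *universal network* (the union
of all species' reaction repertoires), and each acquired pathway gets a
dedicated regulator. As the organism's enzyme toolbox grows, each new
nutrient or target needs fewer and fewer new genes, so the number of
pathways `N_L` grows faster than linearly with network size `N_M`:

    N_L ∝ N_M^α

`toolboxevo` implements the model on three families of universal networks
and the analysis that pins down the exponent α:

* **Galton–Watson trees** — nodes have 0/1/2 children with probabilities
  `p0, p1, p2` (mean offspring Λ = p1 + 2·p2). A mean-field
  layer-occupation theory iterates

      m_d = x·Λ_d + m_{d+1} − B_d·(m_{d+1}/M_{d+1})²

  whose bulk fixed point solves `p2·p² − (Λ−1)·p = x·p0`. On a *critical*
  tree (Λ = 1, i.e. `p0 = p2`) this gives `p∞ = √x`, hence the quadratic
  law `N_L = L_tot·(N_M/M_tot)²` — and criticality is exactly what makes
  α = 2. Supercritical trees (Λ > 1, "small world") instead give
  near-linear scaling with logarithmic corrections.
* **Linearized reaction graphs** — a metabolite graph (e.g. parsed from
  the KEGG `reaction_mapformula.lst` dialect, with currency co-factors
  removed) is linearized into a universal tree either by self-avoiding
  random walks to a root such as pyruvate, or by shortest paths; the
  layer-ratio profile `μ_d = M_{d+1}/M_d` diagnoses whether the result is
  critical (μ → 1) or supercritical.
* **Branched hypergraphs with multi-substrate reactions** — the realistic
  model: reactions fire only when *all* substrates are available (AND
  semantics), pathways are found by scope expansion from the current
  metabolic core followed by minimal-pathway backtracking, and each
  acquisition records pathway geometry (border reactions, base, feedback
  and byproduct metabolites, pathway length). A synthetic universe
  generator with KEGG-calibrated substrate/product multiplicities stands
  in for the curated reaction database.

## Worked example

```r
library(toolboxevo)

# critical universal tree of ~2000 metabolites
params <- branching_params(p0 = 0.25, p1 = 0.5, p2 = 0.25)
tree <- sample_tree(params, mode = "condition_on_size",
                    target_size = 2000, seed = 1)
tree
#> <layered_tree> 2075 nodes, 537 leaves, depth 224
steady_state_fraction(params, 0.16)   # bulk occupation at x = 0.16
#> [1] 0.4                              # = sqrt(x): the quadratic law

# toolbox trajectories on 9 such trees, pooled and fit on binned data
set.seed(1)
trajs <- lapply(1:9, function(r) {
  tr <- sample_tree(params, mode = "condition_on_size", target_size = 2000)
  simulate_full_trajectory(tr)
})
fit <- fit_power_law_ensemble(trajs)
fit$pooled
#> <power_law_fit> y = 0.0002084 * x^1.931  (alpha se 0.0306; 19 bins, 4499 points)
```

The fitted exponent 1.93 (1.96 ± 0.10 across single realizations) is the
quadratic scaling on a critical universal tree. The same analysis on the
realistic branched model:

```r
u <- generate_synthetic_universe(seed = 1)   # 2000 metabolites, 40 layers
ex <- expand_scope(u, attr(u, "seed_metabolites"))
ex
#> <scope_expansion> 41 layers, 4052 reactions, 2000/2000 metabolites reached
tail(expansion_profile(ex), 2)     # S_{n+1}/S_n -> 1: critical-like growth
#>    step    S    ratio     ref
#> 40   40 2000 1.025115 1.02500
#> 41   41 2000 1.000000 1.02439

res <- simulate_evolution(u, seed = 1)
tail(res$trajectory, 1)            # evolution ends when the scope is covered
#>     step N_L  N_M
#> 897  897 897 2000
fit_power_law(log_bin(res$trajectory$N_M, res$trajectory$N_L))
#> <power_law_fit> y = 0.0002787 * x^1.972  (alpha se 0.0317; 13 bins, 897 points)
head(res$pathways[, c("target", "N_R_path", "N_M_path", "length",
                      "n_border_rxn", "n_byproduct")], 3)
#>   target N_R_path N_M_path length n_border_rxn n_byproduct
#> 1 M01057       40      103     21           32          61
#> 2 M00990        1        2      1            1           1
#> 3 M01076        1        2      1            1           1
```

The first pathway, acquired when the organism owns only its seed
metabolites, needs 40 reactions spanning 21 expansion layers; later
pathways need one or two — the toolbox effect in action. The fitted
exponent stays near 2 even though this universe is a branched, partly
cyclic hypergraph rather than a tree.

A thin command-line driver wrapping these functions ships in
`inst/cli/toolboxevo` (subcommands `simulate-tree`, `simulate-branched`,
`linearize`, `scope`, `fit`, `synth-universe`); `run_experiment()` is the
equivalent programmatic entry point and writes self-describing,
byte-reproducible output bundles.

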
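# sirenet

Detecting dysregulated translation-control sub-pathways in signaling
networks from cell-type-resolved transcriptomics.

## The problem

Synaptic plasticity depends on tightly controlled local protein synthesis,
and the signaling that converges on the cap-binding machinery —
MAPK1/MKNK1/RPS6KA5 and MTOR acting on the EIF4EBP1–EIF4E pair — is a prime
suspect when translation control goes wrong in neurodevelopmental
conditions. Single-cell/nucleus RNA-seq measures these genes per cell type,
but expression differences alone do not say *which route through the
network* carries the dysregulation. sirenet is for researchers who have (a)
a curated signed, directed signal-transduction network and (b) a two
condition, multi-cell-type expression matrix, and want cell-type-specific,
causally consistent answers at the level of network routes.

## The method

1. **mSiReN construction** (`build_msiren()`): the protein/complex network
   is translated to gene level via offline mapping, pathway-annotation and
   interaction-table snapshots, pruned to input-to-terminal paths.
2. **Differential expression** (`differential_expression()`,
   `call_degs()`): per cell type, Welch t-tests with strict thresholds
   (|log2FC| > 0.3, p < 0.05) give each network gene a state in {-1, 0, +1}.
3. **Causal reasoning** (`build_ilp()`, `solve_network_inference()`): the
   smallest sign-consistent subnetwork explaining those states is found by
   exact branch and bound over the integer program

   min Σ α |x_j − c_j| + Σ β (x_j⁺ + x_j⁻),

   where every nonzero non-input node needs a sign-consistent cause
   (defaults α = 1, β = 0.1).
4. **Probabilistic contextualization** (`fit_weights()`,
   `contextualize_network()`): node activities X(i) ∈ [0,1] evolve by
   X_t(i) = (Σ k_j⁺ X_{t−1}(j⁺)) · (1 − Σ k_j⁻ X_{t−1}(j⁻)) with
   activating fan-ins summing to 1 and inhibiting fan-ins to at most 1;
   weights are fitted by multi-start constrained least squares so the
   clamped steady states match control and case expression.
5. **Sub-pathway scoring** (`compute_ssp()`, `compute_aisp()`,
   `classify_activation_patterns()`): SSP = 100 × Π k(i) over a route's
   edge weights; AISP additionally multiplies each step by |log2FC| of the
   upstream gene; routes are called active when every edge weight exceeds
   0.2. Edge reliability can be checked against STRING-style
   evidence-channel scores (`string_combined_score()`,
   `validate_edge_reliability()`).

## Worked example

Simulate two-condition expression from a known weighted version of the
packaged translation-control core network (MAPK1 activity raised from 0.3
to 0.9 in the case condition), then run the analysis stages:

```r
library(sirenet)

core <- core_network_fixture()          # 6 nodes, 7 signed edges
truth <- weighted_network(core, c(
  "MAPK1|MKNK1" = 1, "MKNK1|EIF4E" = 1, "MAPK1|RPS6KA5" = 1,
  "RPS6KA5|EIF4EBP1" = 0.5, "MAPK1|EIF4EBP1" = 0.2, "MTOR|EIF4EBP1" = 0.3,
  "EIF4EBP1|EIF4E" = 0.7))
sim <- simulate_expression(truth, simulation_config(
  n_genes = 50, n_cells_per_condition = 80, noise_sd = 0.05,
  clamp_control = c(MAPK1 = 0.3, MTOR = 0.6),
  clamp_case   = c(MAPK1 = 0.9, MTOR = 0.6), seed = 7))

degs <- call_degs(differential_expression(sim$matrix, "sim", log_base = 2))
subset(degs, direction != 0)
#>       gene cell_type     log2fc             p direction
#> 1    EIF4E       sim  0.6078647 5.155638e-128         1
#> 2 EIF4EBP1       sim -0.4018037 4.439376e-109        -1
#> 3    MAPK1       sim  0.6026361 4.350659e-123         1
#> 4    MKNK1       sim  0.5968453 3.877014e-130         1
#> 6  RPS6KA5       sim  0.5979972 1.041233e-122         1
```

Four genes are up (the activating cascade from MAPK1) and EIF4EBP1 is down
(its inhibitors rose). Causal reasoning recovers the activated subnetwork:

```r
meas <- discretize_measurements(degs, core$nodes)
res <- solve_network_inference(build_ilp(core, inputs = c(MAPK1 = 1),
                                         measurement = meas))
res$node_states
#>    EIF4E EIF4EBP1    MAPK1    MKNK1     MTOR  RPS6KA5
#>        1       -1        1        1        0        1
```

MTOR, which did not change, is correctly left out. Fitting the logic-model
weights and scoring the four canonical routes to EIF4E:

```r
fit <- contextualize_network(core, sim$matrix, "sim",
                             input_nodes = c("MAPK1", "MTOR"),
                             n_restarts = 10, seed = 42)
fit
#> fit_result: mse 1.12276e-09 after 10 restarts (best restart 3, converged)

score_subpathways(fit$weighted, degs, cell_type = "sim")
#>   cell_type SSP_I AISP_I SSP_II AISP_II  SSP_III AISP_III   SSP_IV  AISP_IV pattern
#> 1       sim   100     36   19.5    2.82 0.000659  0.00016 0.000156 5.48e-07       I
```

Route I (MAPK1 → MKNK1 → EIF4E) carries full weight and is the only called
pattern — exactly the perturbation the data were generated from. SSP is the
percent product of on-path weights; AISP scales each step by the upstream
gene's |log2FC|, so a perfectly wired route through unchanged genes still
scores 0.

Protein-interaction evidence for the core edges (packaged channel scores):

```r
validate_edge_reliability(core, core_string_scores())
#> reliability_report: 7/7 edges pass at threshold 0.90
#>   interactions outside the network: 6
```

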
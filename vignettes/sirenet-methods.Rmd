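---
title: "Methods: from signed signaling networks to cell-type-specific sub-pathway scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from signed signaling networks to cell-type-specific sub-pathway scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirenet)
```

# Overview

sirenet analyzes how a signed, directed signaling network is dysregulated
between two conditions (e.g. control vs. disease) in a cell-type-resolved
transcriptomic data set. The pipeline has five stages:

1. **mSiReN construction** — translate a protein/complex signal-transduction
   network to gene (precursor-mRNA) level using offline table snapshots.
2. **Differential expression and discretization** — per cell type, call
   up/down/unchanged states for every network gene.
3. **Causal reasoning (NIVaCaR)** — select the smallest sign-consistent
   subnetwork that explains the discretized states, by exact integer
   optimization.
4. **Probabilistic contextualization (ProComReN)** — fit per-edge weights of
   a probabilistic logic model so its quasi-steady states reproduce the
   observed two-condition expression.
5. **Sub-pathway scoring** — quantify candidate routes through the fitted
   network (SSP/AISP) and call active patterns; optionally validate edges
   against protein-interaction evidence.

This vignette explains each model, its assumptions, the tunable parameters,
and the numerical choices, in the package's own terms.

# Network translation (mSiReN)

Curated signaling networks mix proteins, complexes and families, while
expression data quantify mRNAs. `expand_protein_nodes()` replaces each node
by the genes its mapping table assigns: a family or complex with *k* mapped
members becomes *k* gene nodes, each inheriting every incident edge with its
original sign; a complex with no mapped member is dropped with its edges
(the pragmatic treatment of non-matching complexes), while an unmapped
plain-protein node is an error unless explicitly declared droppable — silent
loss of a mappable protein would bias everything downstream.

`filter_by_pathway_annotation()` then restricts to genes annotated to the
pathways of interest (plus a whitelist for designated input/terminal nodes),
and `infer_rna_edges()` keeps only gene–gene interactions documented in an
interaction-table snapshot, pruned to nodes on at least one directed path
from an input to a terminal node (reachability intersection, computed with
igraph). Pruning is idempotent. When annotation filtering and interaction
matching disagree, we filter first — the pipeline is defined as a sequence
and the annotation step is the coarser one; the alternative order would keep
interaction-supported genes that no selected pathway claims.

All database access is offline by design: inputs are user-supplied TSV
snapshots, so results are reproducible and never depend on a live service.
Default input nodes are the canonical growth-factor/RAS/PI3K/CAMK2 entry
points (BDNF, IGF1, HRAS/NRAS/KRAS, PIK3CA/PIK3CG, CAMK2A) and the default
terminal is EIF4E, the cap-binding endpoint of translation control; both are
overridable.

# Differential expression and discretization

Counts are depth-normalized and log-transformed (`normalize_log()`,
`log1p`-style with a 1e4 scale factor, natural log). Per cell type,
`differential_expression()` compares case against control cells per gene
with a two-sided Welch t-test on the per-cell values; effect sizes are
reported in log2 units (`log_base` rescales when the matrix is on a
different log scale). Welch's test is used deliberately instead of an
empirical-Bayes moderated t: moderation shifts p-values slightly but the
pipeline is driven by fixed thresholds, and an unmoderated test keeps the
statistic fully transparent. Zero-variance genes are handled by adding
eps = 1e-9 to the squared standard error, so a constant shift still yields a
finite, extremely significant statistic.

`call_degs()` applies strict thresholds — |log2FC| **>** 0.3 and p **<**
0.05, both strict inequalities, so boundary values are not DEGs. No
multiple-testing correction is applied by default (the thresholds are
calibrated on raw p-values); Benjamini–Hochberg is available behind
`adjust = TRUE`. `discretize_measurements()` maps DEG directions onto the
network nodes, giving the -1/0/+1 measurement vector consumed by the causal
step. Group comparisons of continuous node values use the rank-sum test
(`wilcoxon_two_group()`, mid-ranks for ties).

# Causal reasoning: the integer program and its exact solver

Node states $x_j \in \{-1, 0, +1\}$ are chosen to minimize

$$\sum_j \alpha\,|x_j - c_j| \;+\; \sum_j \beta\,(x_j^+ + x_j^-),$$

where $c_j$ is the measured discretized state, $\alpha$ the mismatch
penalty, and $\beta$ the node-inclusion penalty, subject to
*sign-consistency*: a nonzero non-input node must have at least one incoming
edge $(s \to j, \sigma)$ with $\sigma\,x_s = x_j$ — a state needs a cause.
Perturbed input nodes need no cause; they may take state 0 (left out of the
explanation) or their assigned sign, never the opposite sign, and they count
toward the $\beta$ term like any other included node. With both options
available, an input is only "switched on" when doing so buys a cheaper
explanation than absorbing the mismatch penalty.

Defaults are $\alpha = 1$, $\beta = 0.1$; the ratio $\beta/\alpha$ is
warned about outside $[0.03, 0.5]$ (too-low ratios stop penalizing network
size, too-high ratios suppress genuine signal). Cycles are allowed and no
loop-breaking constraints are added, so a feedback loop may sustain itself;
this is a modeling choice, not an approximation, and matches the objective,
which contains no loop terms.

`solve_network_inference()` solves the program **exactly** by depth-first
branch and bound over node states. Once node states are fixed, the per-edge
transmission variables of the underlying ILP are determined locally, so
branching on nodes is a complete search. Nodes are expanded in order of BFS
distance from the inputs so that parents tend to precede children and the
causal-support check fires as early as possible; partial assignments are
pruned against the incumbent with a per-node lower bound, and the always
feasible all-zero assignment seeds the incumbent. Ties between equal-cost
optima are broken deterministically by the depth-first expansion order
(state 0 tried before +1 before -1, nodes in BFS-from-input order). A
wall-clock limit returns the best incumbent flagged non-optimal.
`brute_force_oracle()` — plain enumeration of all state combinations — is an
independent check used by the test suite on networks of up to 12 free
nodes; solver and oracle agree exactly on 100 random instances there.
Exhaustive search is exponential in the worst case; the intended problem
sizes (tens of nodes after per-cell-type pruning) are handled comfortably,
but very large dense networks are out of scope.

The program is solved once per cell type, yielding per-cell-type activated
subnetworks whose intersection (`shared_subnetwork()`) exposes regulation
cores common to groups of cell types. A single joint program over all cell
types would couple them only through shared bookkeeping, not shared
constraints, so nothing is lost by solving separately.

# Probabilistic contextualization

The fitted model is a probabilistic logic network: node activities
$X(i) \in [0,1]$, and for node $i$ with activating parents $j^+$ (weights
$k_{j^+}(i)$) and inhibiting parents $j^-$ (weights $k_{j^-}(i)$),

$$X_t(i) = \Big(\sum_{j^+} k_{j^+}(i)\, X_{t-1}(j^+)\Big)\,
          \Big(1 - \sum_{j^-} k_{j^-}(i)\, X_{t-1}(j^-)\Big).$$

Weights obey the law of total probability: activating fan-ins sum to
exactly 1, inhibiting fan-ins to at most 1. Under these constraints the
update maps $[0,1]^n$ into itself (first factor is a convex combination,
second factor lies in $[0,1]$), which the test suite verifies on $10^5$
random draws. Two conventions complete the rule: a node with inhibitors but
no activators uses a basal first factor of 1 (otherwise inhibitor-only
nodes would be identically 0 and unfittable), and a node with no parents
keeps its current value. This is mean-field propagation of expected
activities — no sampling of the underlying distribution.

`steady_state()` iterates the synchronous update with input nodes clamped
until the largest change drops below `tol = 1e-6` (cap 1000 iterations). On
an acyclic network this converges exactly within the longest-path number of
updates; cyclic networks can oscillate, in which case the last state is
returned flagged.

`fit_weights()` minimizes the mean squared error between steady-state
activities and observed targets over all conditions. Control and case are
fitted as **two clamped steady-state problems sharing one weight set** —
each condition is an operating point of the same network. (A one-step
"transition" reading, where the case state is one update away from the
control state, is a plausible alternative; the steady-state convention is
the norm in logic-model training and is what the package implements.)
Observed targets come from `normalize_to_unit_interval()`: per gene, the
two condition means are min–max scaled so the lower condition maps to 0 and
the higher to 1 (equal means map to 0.5), putting expression on the
activity scale.

The constraints are enforced **by construction**: activating fan-ins are
parameterized by a softmax (a single activator is pinned at 1 and
contributes no free parameter), inhibiting fan-ins by a softmax with one
extra slack term, keeping each weight in (0,1) and the sum strictly below 1.
The resulting unconstrained problem is solved with L-BFGS-B (numeric
gradients), restarted from `n_restarts = 20` random draws by default, with
per-restart seeds derived reproducibly from one master seed; node values
are initialized per restart from N(0.5, 0.1) truncated to [0,1]. Multi-start
matters because the steady-state map makes the objective non-convex; with
nested seeds, the best-of-restarts error is nonincreasing in the restart
count. Objective tolerance is 1e-8 with a 2000-iteration cap per restart.

# Sub-pathway scoring

For an ordered route from an input node to an endpoint, the **strength of
the sub-pathway** is

$$\mathrm{SSP} = 100 \times \prod_i k(i),$$

the percent product over the path nodes (after the input) of the on-path
incoming edge weight. The per-node factor is the single on-path weight, not
the node's full activating fan-in sum: fan-in sums are 1 by construction
whenever a node has activators, which would make every score degenerate;
the on-path weight is what differentiates routes. (A `fan_in = TRUE` mode
exposes the sum variant.) Note the printed best-model weights of a *core
subnetwork* extracted from a larger fitted network need not satisfy the
fan-in constraints within the extract — `weighted_network(check = FALSE)`
admits such views for scoring.

The **abnormality index** scales each step by the differential expression
of the signal's source:

$$\mathrm{AISP} = 100 \times \prod_i k(i) \cdot f(\log_2 \mathrm{FC}_{\text{upstream}(i)}),$$

with $f = |\cdot|$ by default. The upstream (source) node's fold change is
used because each factor measures the signal arriving along the edge, and
the absolute value is the default because the index measures the magnitude
of dysregulation along the route regardless of direction; signed mode is
available (`absolute = FALSE`) and genes without a fold change contribute 0,
zeroing the route.

A pattern (route) is called **active** when every edge on it carries a
weight strictly above the activation threshold, default 0.2 — the weight
cutoff used when drawing activation diagrams. Pattern calls deliberately use
edge weights, not SSP: a product score has no single threshold that
separates routes of different lengths, whereas the per-edge rule does not
penalize longer routes.

The packaged core network (six translation-control genes, seven edges) and
its four canonical routes to EIF4E are available via
`core_network_fixture()` and `core_patterns()`.

# Edge-reliability validation

`string_combined_score()` combines per-channel protein-interaction evidence
(coexpression, experiments, curated databases, text mining) by removing the
prior probability 0.041 from each nonzero channel, combining corrected
channels as independent evidence (noisy-OR), restoring the prior, and
capping at 0.999. This reproduces the published combined scores of all
homology-free core-network pairs within ±0.002; pairs with a nonzero
homology channel are not recombined (the homology discount applied to
coexpression/text-mining is not reconstructible from the per-channel
scores) and fall back to their printed combined value. Matching in
`validate_edge_reliability()` is undirected and sign-blind — evidence
concerns the existence of an interaction, not its direction.

# Synthetic data: what it emulates and what it does not

`simulate_expression()` generates two-condition, multi-cell-type expression
from a known weighted logic network: condition means are the network's
clamped steady states, per-cell values add truncated Gaussian noise
(default sd 0.05) on the normalized activity scale, and off-network filler
genes are drawn identically in both conditions so every filler DEG call is
a false positive. Defaults (50 cells per condition per cell type, noise sd
0.05) give comfortable but not trivial power at the 0.3/0.05 DEG
thresholds. A master seed spawns per-component child seeds, so any slice of
the simulation is reproducible in isolation.

The generator operates on the *normalized* scale by design — both the DEG
step and the weight fitting consume normalized data, so a count-level
simulation would add machinery without exercising extra code paths. It
does **not** emulate UMI count distributions, dropout, batch structure, or
cell-type imbalance; passing tests demonstrate correctness of the inference
machinery under the stated noise model, not robustness to real snRNA-seq
artifacts.

Problem sizes used by the test suite are chosen to exercise every code
path while remaining quick: solver-vs-oracle equivalence on 100 random
networks of 4–8 nodes, weight recovery on an identifiable 4-node fan-in
topology over 30 noise replicates (noise sd 0.01, median absolute weight
error ≤ 0.05), end-to-end chain recovery across 10 simulation seeds, and
type-I calibration on 1000 null genes.

# Known limitations

- The exact solver is exponential in the worst case; for networks beyond a
  few dozen free nodes use the time limit and treat the result as an
  incumbent.
- Oscillating (cyclic) logic networks return a flagged non-converged state
  rather than a time average.
- Weight identifiability depends on the topology and the two operating
  points; two conditions constrain, but do not always pin down, every
  fan-in (the fit reports only the best restart's optimum).
- The DEG step assumes approximately normal per-cell values after
  log-normalization; it is not a count model.
- Pattern calls depend on the 0.2 weight threshold; product scores (SSP)
  additionally shrink with route length, so scores are comparable between
  routes of equal length only.
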
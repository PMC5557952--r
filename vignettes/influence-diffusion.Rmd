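---
title: "Influence diffusion on disease-specific miRNA interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Influence diffusion on disease-specific miRNA interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mircascade)
```

## The problem

MicroRNAs regulate each other indirectly through shared targets and
transcriptional programs, and in a disease state a perturbation of one
miRNA can cascade through this regulatory web. Given a disease-specific
miRNA–miRNA interaction network (a *DMIN*: a directed graph with
probabilistic edge confidences, typically produced by a consensus
network-inference pipeline) and a table of per-disease fold changes,
`mircascade` ranks miRNAs by how much of the network each one can
*activate* — its expected cascade *coverage* — under the Independent
Cascade (IC) model. Highly ranked miRNAs are candidate upstream drivers
of the disease network. "Activation" here is deliberately abstract: it
covers both up- and down-regulation, since either direction propagates a
perturbation.

## Network construction

Two inputs define a disease network:

1. an edge list `source, target, weight` with inferred confidence
   probabilities, and
2. an expression table `mirna, disease, fold_change` with possibly
   several rows per (miRNA, disease) pair when several studies report it.

Construction proceeds in three steps:

* **High-confidence filtering** (`filter_high_confidence()`, default
  cutoff **0.90**, boundary inclusive). Network inference from noisy
  expression data has low precision at low confidence, and the IC model
  itself degenerates on dense graphs — with many alternative paths nearly
  every node can activate everything, and the ranking collapses. After
  filtering, the confidence values have done their job and are demoted to
  metadata; downstream weighting replaces them.
* **Expression attachment** (`attach_expression()`). Each node receives
  the mean of `|log2(fold change)|` over its records for that disease
  (`aggregate_expression()`). Nodes with no record are *removed*, not
  imputed — the flow model below is undefined without a node score, and
  imputation would invent data. Duplicate directed edges keep the
  maximum confidence, which is conservative toward retention at the 0.90
  cutoff.
* **Edge weighting**: either the expression-driven linear program or
  constant rescoring, described next.

### The sign policy, and the order of averaging

Fold changes below 1 (down-regulation) have negative log2 scores. Two
choices are genuinely open here and are made explicitly:

* The node score is the **magnitude** `|log2 fc|`, averaged per record.
  The flow formulation needs nonnegative scores, and the influence notion
  is direction-agnostic. Averaging magnitudes (rather than taking the
  magnitude of the average) keeps studies that disagree in direction from
  cancelling to a spurious zero; the signed mean is retained as node
  metadata (`signed_log2fc`) so no information is lost.
* Averaging happens on the **log scale** — replicates `{2, 8}` give
  `mean(1, 3) = 2` — which weights up- and down-regulation symmetrically
  where averaging raw fold changes would not.

## Edge weighting

### The slack-minimizing linear program

`optimize_edge_weights()` turns node expression into per-edge influence.
With expression scores $e_i \ge 0$ and flow variables $X_{ij} \ge 0$ on
the existing edges only:

$$
\begin{aligned}
\text{minimize} \quad & \textstyle\sum_i |s_i| \\
\text{subject to} \quad
& \textstyle\sum_j e_j X_{ji} = e_i && \text{(Incoming, for in-degree} \ge 1\text{)}\\
& \textstyle e_i \sum_j X_{ij} + s_i = e_i && \text{(Outgoing, all nodes, } s_i \text{ free)}
\end{aligned}
$$

The Incoming equality encodes "a miRNA's expression is the cumulative
result of its regulators' expression flowing in"; the Outgoing equality
ties a node's total outgoing influence to its own expression, relaxed by
a slack without which the system is overdetermined. Minimizing total
absolute slack yields the flow pattern most consistent with the observed
expression.

Numerical and modelling choices:

* $|s_i|$ is linearized exactly as $s_i = s_i^+ - s_i^-$,
  $s_i^\pm \ge 0$, objective $\sum (s_i^+ + s_i^-)$ — the standard LP
  reformulation, solved with the two-phase simplex in the `boot` package
  at feasibility tolerance `1e-8`. The simplex is deterministic, so
  repeated runs return identical solutions; where alternative optima
  exist, the verified constraint residuals — not the particular flow
  vector — are the contract, and `verify_lp_solution()` recomputes every
  residual independently of the solver.
* **In-degree-0 relaxation.** As written, the Incoming equality reads
  `0 = e_i` at a node with no regulators, so any expressed source node
  would be infeasible. Source nodes are therefore treated as exogenous
  drivers: their Incoming constraint is dropped and they are listed in
  the solution's `relaxed_nodes`.
* **Clipping.** The formulation does not bound $X_{ij}$ above, but the
  IC simulation needs probabilities, so flows above 1 are clipped to 1 at
  export and the count is reported. Zero-expression nodes are legal;
  their out-edges simply carry no influence (a warning notes them).
* The constraints are homogeneous in $e$, so rescaling all expression by
  $c > 0$ leaves the optimal flows unchanged and scales slacks by $c$ —
  a property the test suite checks.

### Constant rescoring

`rescore_constant()` (default **0.01**) discards expression entirely and
probes purely topological pressure points. Low constants are the right
regime: on a dense high-confidence network, large uniform probabilities
let nearly every node activate the whole graph. This mode is also the
fallback when expression cannot be reduced to one score per node (e.g.
longitudinal designs whose samples are not comparable replicates).

## Coverage under the Independent Cascade model

`simulate_cascade()` seeds one active node; each newly activated node
performs one biased coin toss per out-edge (success probability = edge
weight), activating the target on success, until no new activation is
possible. Semantics worth stating:

* each edge is attempted **at most once** per realization — a failed
  edge is never retried, though its target may still be activated later
  through a different edge;
* the seed itself is **excluded** from its coverage count;
* the frontier is processed FIFO, but since edges fire independently the
  final activated set is order-independent — only the attempt trace
  depends on order.

`compute_coverage()` averages the activated count over `n_sim = 10000`
Monte-Carlo cycles in compiled code. `rank_all_nodes()` does this for
every node and sorts by decreasing coverage, breaking ties
lexicographically on the miRNA id so output is reproducible.
`coverage_percentage()` divides by the network's full node count $n$
(not $n - 1$): a percentage of 70 means influence over 70% of the nodes
*of the network*, which is the natural reading even though the seed can
never cover itself.

### Reproducibility

Cascade sampling uses a self-contained 64-bit generator
(splitmix64-seeded xorshift family) rather than R's global RNG stream:
each `(master seed, node id)` pair gets its own substream, so a node's
coverage estimate is bit-identical whether it is evaluated alone or as
part of a full ranking, across platforms, and independent of evaluation
order.

### The exact oracle

The IC process is distributionally equivalent to the *live-edge* view:
declare each edge independently live with probability equal to its
weight; the activated set is whatever the seed reaches through live
edges. `exact_expected_coverage()` enumerates all $2^{|E|}$
configurations, weights each by its product probability, and sums
reachable counts — reachability by boolean-matrix transitive closure, a
code path sharing nothing with the simulation engine. Enumeration cost
doubles per edge; a guard refuses networks with more than 20 edges
(about $10^6$ configurations). The oracle exists to *test* the
simulator: the suite checks agreement within four standard errors on
hundreds of random small graphs.

```{r oracle}
chain <- dmin(data.frame(source = c("1", "2"), target = c("2", "3"),
                         weight = 0.5))
exact_expected_coverage(chain, "1")          # 0.5 + 0.25
compute_coverage(chain, "1", n_sim = 10000, seed = 7)
```

## Category aggregation

Related diseases are grouped into categories of up to five networks
(`category_spec()`; the cap mirrors the published tool and is an
argument, not a constant):

* **Intersection / logical AND** (`intersect_category()`): keep only
  edges present in *every* member network (exact endpoint identity — no
  fuzzy matching of miRNA name variants), with weight equal to the
  product of the member weights, i.e. the probability the interaction
  fires in all diseases at once. Ranking then runs on the merged
  network, and all miRNAs with positive mean coverage are reported —
  the least arbitrary cutoff for what is usually a short list.
* **Cumulative union** (`cumulative_union()`): rank within each member
  network, convert to percentages using *each network's own* node count
  (so diseases of different sizes are comparable), average each miRNA's
  percentages over the diseases where it occurs (absent diseases are not
  zero-filled), and report the top 10 by default.

Intersection weight can never exceed the smallest member weight;
a union score always lies between the miRNA's per-disease extremes;
with one member network, union reduces exactly to `rank_all_nodes()`.
All three properties are tested.

## Synthetic data

The package generates every test input itself:

* `fig4_fixture()` — a five-node didactic network (edges 1→2 at 0.5,
  1→3 at 0.9, then 3→4, 3→5, 5→4). The last three weights are not fixed
  by the construction and default to 0.5; tests that need one specific
  cascade realization force the coin tosses rather than rely on them.
* `generate_random_dmin()` — directed Erdős–Rényi graphs; node scores
  are `|log2|` of log-normal fold changes (`meanlog = 0`, `sdlog = 1`),
  giving a symmetric mix of up- and down-regulation like curated
  fold-change databases show.
* `planted_influencer_network()` — one hub with 15 out-edges at
  probability 0.9 over a sparse background at 0.05: its expected spread
  dominates by construction, so recovering it at rank 1 is a functional
  test of the whole estimator (the suite requires 19/20 seeded runs).
* `generate_expression_table()` — fold-change tables with a configurable
  fraction of replicated (miRNA, disease) pairs.

What the generators do *not* emulate: correlated edge errors from a real
inference pipeline, hub-heavy degree distributions of real regulatory
networks, batch structure across studies, or longitudinal designs.
Passing tests demonstrate the machinery is correct under the stated
model, not that a particular biological ranking is right.

## Problem sizes and runtime

Defaults target desk-scale reproducibility: 10000 Monte-Carlo cycles per
node, oracle comparisons on graphs of ≤ 6 nodes / ≤ 10 edges (200 graphs
in the equivalence suite), LP verification on 100 layered random
feasible instances, and 20-node planted-influencer recovery over 20
seeds. The compiled cascade core makes the full suite run in well under
a minute on one CPU; `n_sim` scales linearly.

## Known limitations

* Edge weights are static: steady-state influence only, no time-varying
  kinetics. Rate constants of the underlying interactions are unknown,
  so an edge's influence is driven by the source's (steady-state)
  expression alone.
* The LP can be infeasible when a node's only regulators have zero
  expression; the error names the node, but the modelling answer
  (drop the node, or relax the constraint) is the user's.
* Monte-Carlo error is the usual $O(n_{\text{sim}}^{-1/2})$; rank
  stability between nearly tied nodes needs more cycles than the
  default.
* Influence *maximization* (optimal seed sets) and threshold-based
  diffusion models are out of scope; only single-seed coverage under IC
  is implemented.
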
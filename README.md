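# mircascade

Influence-diffusion analysis of disease-specific miRNA–miRNA interaction
networks (DMINs). Given a directed network of inferred miRNA–miRNA
regulatory edges with confidence probabilities and a table of per-disease
fold changes, `mircascade` ranks miRNAs by their expected cascading
influence — how much of the network a perturbation seeded at each miRNA
would activate — and aggregates those rankings across the diseases of a
category. It is aimed at systems-biology researchers prioritizing
candidate driver miRNAs from network-inference output.

## The method in brief

1. **High-confidence network.** Edges with confidence ≥ 0.90 are kept
   (DMIN_HC); confidences are then discarded as weights.
2. **Expression scores.** Each node gets
   `e_i = mean(|log2 fold-change|)` over its records for the disease;
   replicated study entries are averaged (DMIN_HCE).
3. **Edge weights.** Either by the slack-minimizing linear program

   ```
   minimize   Σᵢ |sᵢ|
   s.t.       Σⱼ eⱼ·Xⱼᵢ        = eᵢ   (incoming flow, in-degree ≥ 1)
              eᵢ·Σⱼ Xᵢⱼ + sᵢ  = eᵢ   (outgoing flow, sᵢ free)
              Xᵢⱼ ≥ 0, i ≠ j
   ```

   whose optimal flows `X` become activation probabilities (clipped at
   1), or by rescoring every edge to a constant (default 0.01) to probe
   purely topological pressure points.
4. **Coverage.** Under the Independent Cascade model, each newly
   activated node gets one biased coin toss per out-edge. A node's
   coverage `COV(u)` is the expected number of other nodes it activates,
   estimated over 10,000 Monte-Carlo cycles (exactly computable by
   live-edge enumeration on small networks), mapped to a percentage of
   the network's node count, and ranked.
5. **Categories.** Across 1–5 related disease networks: *intersection*
   keeps edges present in every disease with weight `P₁ × P₂ × … × Pₙ`
   and ranks the merged network; *cumulative union* averages each
   miRNA's per-disease coverage percentages and reports the top 10.

## Worked example

```r
library(mircascade)

g <- fig4_fixture()     # 5 nodes; edges 1→2 (0.5), 1→3 (0.9), 3→4, 3→5, 5→4
g
#> DMIN 'toy': 5 nodes (0 with expression), 5 directed edges

rank_all_nodes(g, n_sim = 10000, seed = 1)
#>   mirna mean_coverage coverage_percentage rank
#> 1     1        2.4087              48.174    1
#> 3     3        1.1266              22.532    2
#> 5     5        0.4895               9.790    3
#> 2     2        0.0000               0.000    4
#> 4     4        0.0000               0.000    5

exact_expected_coverage(g, "1")
#> [1] 2.4125
```

Node 1 is the most influential: a cascade seeded there activates on
average about 2.41 of the other 4 nodes (48% of the 5-node network), and
the Monte-Carlo estimate (2.4087) sits within sampling error of the
exact live-edge expectation (2.4125 = 0.5 + 0.9 + 0.5625 + 0.45). Nodes
2 and 4 have no outgoing edges, so their coverage is exactly zero.

The full pipeline (read → filter → annotate → weight → rank) is
`run_pipeline()`; a thin command-line wrapper with subcommands `build`,
`weights`, `coverage`, `category` and `fixtures` is installed at
`inst/cli/mircascade.R`:

```sh
Rscript inst/cli/mircascade.R fixtures --preset fig4 --out fig4.csv
Rscript inst/cli/mircascade.R coverage --network fig4.csv --nsim 10000 \
    --seed 1 --out ranks.csv
```

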
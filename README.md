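# triadnet

Network-based prioritization of drug targets for complex disease via the
**module triad**: three regions of a protein–protein interaction network
that together describe how a disease forms and how it is successfully
treated.

- **Genotype module** — the largest connected component (LCC) formed by
  the protein products of disease-associated genes;
- **Response module** — the LCC of genes whose expression is *reverted*
  in patients who respond to treatment (the "responders before/after"
  set, derived by paired differential expression);
- **Treatment module** — the LCC of the protein targets of compounds
  whose perturbation signatures revert the Response signature, selected
  by weighted connectivity scoring of perturbation experiments.

Given the Genotype and Treatment modules, every node *v* of the
interactome is scored on two axes:

- **proximity** to the Genotype module,
  `proximity(v) = (d̄(v) − μ_p) / σ_p`,
  where `d̄(v)` is the mean shortest-path length from *v* to the module
  and `(μ_p, σ_p)` summarize the same statistic over 500 random
  *connected* subgraphs of equal size;
- **selectivity** to the Treatment module,
  `selectivity(v) = (DSD̄(v) − μ_s) / σ_s`,
  the analogous Z-score of the mean **diffusion state distance**
  `DSD(u, v) = ‖He(u) − He(v)‖₁`, with `He(u)` the vector of expected
  visit counts of a k-step random walk started at *u*.

More negative is better on both axes.  Nodes are ranked on each axis and
combined by the rank product `r = √(r_p · r_s)`.  Cohesion of each
module is tested with the LCC Z-score
`Z_LCC = (S_LCC − μ_LCC) / σ_LCC` against degree-matched random gene
sets, and the null modules for proximity/selectivity are drawn
approximately uniformly from all connected subgraphs of the given size
by a Metropolis swap chain.  Reference prioritizers (local radiality,
random walk with restart, embedding cosine similarity) and
target-recovery evaluation (ROC/AUC, PR/AUPR, precision/recall at K,
leave-one-in DSD recovery with interpolated curve averaging) are
included, as are seeded synthetic-data generators that plant a full
triad with known true targets so the whole pipeline can be validated
without any external data.

## Worked example

```r
library(triadnet)

g     <- generate_graph(300, model = "scale_free", seed = 42)
triad <- plant_triad(g, seed = 43)   # plants genotype/treatment/response + 5 true targets

genotype <- build_module(g, triad$genotype_genes, label = "genotype",
                         n_samples = 1000, seed = 44)
print(genotype)
#> Network module 'genotype': 15 input genes, 15 mapped, LCC of 15
#> LCC significance: S_LCC = 15, mu = 6.404, sigma = 2.194, Z = 3.918, p < 0.001 (1000 samples)

tab <- prioritize(g, genotype, triad$treatment_targets, dsd_k = 5,
                  n_modules = 500, seed = 45)
head(tab[, c("node", "proximity_z", "selectivity_z", "rank_p", "rank_s",
             "combined_rank")])
#>    node proximity_z selectivity_z rank_p rank_s combined_rank
#> 1 g0288      -1.630       -1.3364      1     23          4.80
#> 2 g0109      -0.616       -4.4774     72      1          8.49
#> 3 g0234      -1.599       -0.1963      2     73         12.08
#> 4 g0094      -1.372       -0.6993      6     40         15.49
#> 5 g0171      -1.488        0.0646      4     92         19.18
#> 6 g0002      -1.556        0.3563      3    138         20.35

r <- labeled_ranking(setNames(-tab$combined_rank, tab$node), triad$true_targets)
roc_auc(r)$auc
#> planted-target ROC AUC: 0.974
```

The planted genotype set is 2.5 times more interconnected than its
degree-matched null (Z ≈ 3.9, no null draw reached the observed LCC in
1000 samples), and the rank-product ordering places the five planted
true targets near the top of all 300 nodes (AUC 0.974).  The top-ranked
nodes illustrate the synergy: `g0288` is strong on both axes, while the
best single-axis nodes (`g0234` on proximity, `g0109` on selectivity)
sit lower in the combined order.

A complete pipeline — simulation, module discovery from expression data,
WTCS scoring of perturbation profiles, prioritization with baseline
columns, and evaluation — is scriptable through `triad_run()` or the
thin command-line wrapper:

```sh
Rscript inst/cli/triad.R simulate   --out-dir scenario --seed 11
Rscript inst/cli/triad.R build-modules --in-dir scenario --out-dir run
Rscript inst/cli/triad.R wtcs          --in-dir scenario --out-dir run
Rscript inst/cli/triad.R prioritize    --in-dir scenario --out-dir run
Rscript inst/cli/triad.R evaluate      --in-dir scenario --out-dir run
```

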
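---
title: "The module triad: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The module triad: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadnet)
```

# The model

triadnet treats a complex disease as three interacting regions of a
protein–protein interaction (PPI) network, all defined as largest
connected components (LCCs) of induced subgraphs:

* the **Genotype module**, the LCC of the disease-associated genes —
  where the disease *forms*;
* the **Response module**, the LCC of the genes whose expression is
  reverted in treatment responders (paired pre/post differential
  expression, the "responders before/after" set) — what successful
  treatment *changes*;
* the **Treatment module**, the LCC of the protein targets of compounds
  whose perturbation profiles revert the Response signature — what
  needs to be *hit* to change it.

The working hypothesis is that a feasible target is simultaneously
**topologically relevant** to the Genotype module and **functionally
similar** to the Treatment module.  Both notions are operationalized as
Z-scores against null modules:

$$\textit{proximity}(v) = \frac{\bar d(v) - \mu_p}{\sigma_p}, \qquad
  \textit{selectivity}(v) = \frac{\overline{DSD}(v) - \mu_s}{\sigma_s},$$

where $\bar d(v)$ is the mean unweighted shortest-path length from $v$
to the Genotype module, $\overline{DSD}(v)$ is the mean diffusion state
distance from $v$ to the Treatment module, and $(\mu, \sigma)$ are the
mean and standard deviation of the same statistic over random
*connected* subgraphs of the same size as the respective module.  More
negative is better on both axes.  Per-axis ranks (ascending Z) are
combined by the rank product $r = \sqrt{r_p \cdot r_s}$.

## Diffusion state distance

For walk length $k$, $He(u, w)$ is the expected number of time points
$t = 0, \dots, k$ at which a simple random walk from $u$ occupies $w$;
in matrix form $\sum_{t=0}^{k} P^t$ with $P$ the degree-normalized
adjacency.  The DSD is the $L_1$ distance between visit vectors,
$DSD(u, v) = \lVert He(u) - He(v)\rVert_1$, a metric for every fixed
$k$.  Two conventions are fixed here and verified by the test suite:

* the $t = 0$ term is **included**, so every row of $He$ sums to
  $k + 1$ exactly — a cheap invariant that catches normalization bugs;
* the default walk length is $k = 5$, following common practice in the
  DSD literature.  The distance converges as $k \to \infty$ but no
  finite $k$ is canonical; DSD *values* are therefore comparable only
  within a fixed $k$, and all defaults keep $k$ explicit in the
  results.  Cost is $O(k n^2)$ dense multiplications.

## Module cohesion: LCC significance

A gene set's interconnectedness is measured by
$Z_{LCC} = (S_{LCC} - \mu_{LCC}) / \sigma_{LCC}$, where the null draws
degree-matched random gene sets and reduces each to its LCC size.
Degree matching uses logarithmic bins (bin $j$ holds degrees in
$[2^j, 2^{j+1})$), because exact-degree matching is infeasible for
high-degree hubs; a bin with fewer than twice the requested count is
merged upward and reported.  On degree-regular graphs the binning
degenerates to uniform sampling, which the suite verifies.  The
empirical p-value counts null draws with LCC size $\ge$ the observed
one; a zero count is reported as bounded, `"< 1/n_samples"`, with the
raw count retained.

## Null modules: uniform connected subgraphs

Proximity and selectivity compare against *connected* random modules —
scattered node sets would bias both statistics.  Sampling connected
$m$-subsets uniformly is nontrivial; triadnet uses a Metropolis swap
chain: from a connected seed set, propose swapping a uniformly chosen
boundary vertex in and a uniformly chosen member out, reject proposals
that disconnect the set, and accept the rest with probability
$\min(1, |N(S)| / |N(S')|)$, which makes the uniform distribution over
connected $m$-subsets stationary.  Each draw runs an independent chain
for a burn-in of $20\,|V|$ steps (the `iterations` knob).  That default
was chosen so the empirical distribution over 100,000 draws stays
within total-variation distance 0.05 of the exact uniform distribution
(by exhaustive enumeration) on every small fixture graph in the test
suite; measured values are around 0.01.  The chain is implemented in
C++ and driven by R's RNG, so draws are reproducible under
`set.seed()`.

A single pool of 500 random modules per module size is drawn once and
reused for every node.  Because the pooled statistic varies over
modules, not nodes, sharing the pool leaves each node's null
distribution unchanged while making full-graph scoring tractable
(~18k nodes at interactome scale); the suite checks that a per-node
null with the same seed reproduces the pooled Z exactly.  Nodes
belonging to the scored module are ranked like any other node, with
their zero self-distances included — the alternative (excluding them)
would leave module members unranked and is not what a screening tool
wants.

## Signature reversal: WTCS

Perturbation experiments are scored against the Response signature
(up/down query sets) with the weighted Kolmogorov–Smirnov enrichment
score: genes ranked by perturbation z descending, hits weighted by
$|z|^w$ (default $w = 1$; $w = 0$ recovers the classic unweighted
statistic), misses by $1/(N - N_h)$, score = signed extremum of the
running sum.  Ties in $z$ are broken by gene symbol; ties between
equal-magnitude positive and negative extrema resolve positive.  The
connectivity score is

$$WTCS = \tfrac12 (ES_{up} - ES_{down}) \text{ if } \mathrm{sign}(ES_{up})
  \ne \mathrm{sign}(ES_{down}), \quad 0 \text{ otherwise},$$

so a negative WTCS means the perturbation pushes up-query genes down
and down-query genes up — signature reversal.  Significance uses 1000
uniform query-set permutations.  The one-sided p-value is normalized
by the **same-sign portion** of the null (for positive ES, the fraction
of positive null scores at least as large), the convention used for
signed extremum statistics in gene-set enrichment analysis.  With the
full null as denominator the p-values of null queries would concentrate
below 0.5 (a mixture of $U[0, q]$ and $U[0, 1-q]$ with
$q = P(ES > 0)$); the same-sign normalization makes them uniform, which
the suite verifies by a Kolmogorov–Smirnov test over 2000 replicates.

Experiments are kept when $WTCS < 0$ **and** $p_{up} < 0.05$ **and**
$p_{down} < 0.05$ — the conjunctive form; the union of the kept
compounds' protein targets, mapped to the network, seeds the Treatment
module.

## Differential expression

The expression contrast is a per-gene t-test (Welch unpaired, or paired
for pre/post designs) on log2-scale data with Benjamini–Hochberg
adjustment.  Fold change is the difference of group means on the log2
scale, thresholded on the linear scale: a gene is labelled up or down
only when $|FC|$ exceeds the threshold (2.5 is conventional for
case/control contrasts, 1.8 for pre/post-treatment contrasts) *and*
$p_{adj} < 0.05$.  Genes constant across samples get $p = 1$.  When two
drug-specific signatures are merged, a gene up in one and down in the
other is contradictory and is dropped from both sets, with a message —
there is no principled way to keep it.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `dsd_k` | 5 | random-walk length (steps) for DSD |
| `n_modules` | 500 | random connected modules per null pool |
| `n_samples` (LCC) | 10,000 at scale; smaller on small graphs | degree-matched null draws |
| `n_perm` | 1000 | permutations per WTCS p-value |
| `weight_exponent` | 1 | hit weighting $|z|^w$ in the enrichment score |
| `fc_threshold` | 1.8 (pre/post), 2.5 (case/control) | linear fold-change gate |
| `alpha` | 0.05 | adjusted-p / permutation-p threshold |
| `damping` | 0.85 | RWR continuation probability |
| `tol` | 1e-8 | RWR L1 convergence tolerance |
| `iterations` | 20·\|V\| | sampler burn-in steps per draw |
| `k_values` | 500 | precision/recall cutoffs |

# Numerical conventions and degenerate inputs

* **$\sigma = 0$ sentinels.**  A degenerate null (constant statistic)
  yields $Z = 0$ when the observation equals the null mean, otherwise a
  signed-infinity sentinel with a warning; consumers must handle the
  marker explicitly rather than receive a silent `NaN`.
* **Ties in ranking.**  Score ranks use average ties (tied values share
  the mean of their positions).  Evaluation metrics treat a tie group
  as a single threshold step, which makes the trapezoidal ROC area
  equal the Mann–Whitney statistic exactly; precision@K uses a
  deterministic order with ties broken by node name.
* **Curve averaging.**  Leave-one-in DSD recovery averages per-target
  curves on a fixed 101-point grid — linear interpolation for ROC,
  right-continuous step interpolation for precision–recall (AUPR is
  interpolation-sensitive, so the convention is fixed and documented).
* **LCC ties.**  Among equally sized components the one containing the
  lexicographically smallest vertex wins, making results deterministic.
* **Reproducibility.**  Every stochastic operation takes a seed and is
  bit-reproducible; `seed = NULL` composes under an enclosing
  `withr::with_seed()`, which is how the scenario generator derives all
  of its parts from one seed.

# The synthetic generator

`simulate_scenario()` produces every input the pipeline consumes, with
planted ground truth: a scale-free (preferential-attachment) graph —
mimicking the degree heterogeneity of real interactomes — with
connected Genotype/Treatment/Response sets drawn approximately
uniformly; a paired pre/post expression matrix in which the planted
response genes are shifted by ±2 log2 units against Gaussian noise
(sd 0.3, 20 subjects per group); and perturbation z-score profiles in
which 8 "reverting" experiments place response-up genes at strongly
negative z and response-down genes at strongly positive z (|mean z| =
4), among 40 i.i.d.-normal neutral experiments.  Compounds of reverting
experiments partition the planted Treatment targets, so perfect
filtering recovers exactly the planted union; neutral compounds map to
decoy targets.

**True targets** are planted to satisfy both ranking hypotheses at
once: candidates are the one-hop neighbors of the Genotype set outside
both modules, screened by the same null-normalized statistics the
framework ranks with (using a small 150-module pool at generation
time), and the top candidates by rank product are selected.  Raw
distances would not do: a hub is close to *every* module, so closeness
that survives the null comparison is what must be planted.  The
construction rule is recorded in the scenario parameters.

The default "smoke scenario" (300-node graph, 15/10/25 modules, 5 true
targets) runs the entire pipeline — expression → signature → WTCS →
Treatment module → prioritization → evaluation — in about a minute on
one CPU; the test suite and the acceptance script use these sizes,
chosen to keep full-pipeline checks fast while leaving all statistics
well away from small-sample degeneracy.

What the generator does **not** emulate: correlated transcriptome
structure (genes are independent given the planted shifts), batch
effects, identifier-mapping noise, the moderated-z construction of real
perturbation resources, or literature-bias in interaction maps.
Passing tests therefore demonstrate that the machinery recovers planted
structure under clean conditions, not that it overcomes the biases of
real data.

# Known limitations

* DSD values are $k$-dependent; cross-study numeric comparability of
  selectivity values is not attempted (ranks are comparable).
* The degree-binned LCC null matches binned degree sequences, not exact
  ones; for templates dominated by one enormous hub the null is
  conservative.
* Embedding-based scoring consumes externally trained embeddings; the
  built-in spectral embedding is deterministic and convenient for
  testing but is not a substitute for a trained neighborhood embedding
  on large graphs.
* Druggability, toxicity and identifier mapping are out of scope; node
  identity is the gene symbol string.
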
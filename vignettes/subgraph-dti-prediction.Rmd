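---
title: "Predicting drug-target interactions from enclosing subgraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions from enclosing subgraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtiwl)
```

## The problem and the model

Experimentally mapping which chemical compounds bind which protein targets
is slow and expensive, so computational screening of candidate drug-target
interactions (DTIs) is used to prioritise laboratory work. The data
available for this task typically comes as three matrices: a very sparse
binary matrix $Y \in \{0,1\}^{m \times n}$ of known interactions between
$m$ drugs and $n$ targets, a drug-drug chemical-structure similarity matrix
$S^D \in [0,1]^{m \times m}$, and a target-target protein-sequence
similarity matrix $S^T \in [0,1]^{n \times n}$. dtiwl treats these jointly
as one undirected *semi-bipartite* graph: interaction edges run between the
two sides, and the similarity values weight edges within each side. The
working assumption is *guilt by association* — similar drugs tend to share
targets, and similar targets tend to share drugs.

Instead of hand-crafting features, the package classifies each candidate
pair $(d_i, t_j)$ by the local graph topology around it:

1. **Enclosing subgraph.** A subgraph of exactly $K$ vertex slots is grown
   around the anchor pair: first both anchors, then all their interaction
   neighbours, then further interaction neighbours admitted in decreasing
   similarity to the anchors (drugs ranked by $S^D_{i\cdot}$, targets by
   $S^T_{j\cdot}$, jointly on the shared $[0,1]$ scale). If the first hop
   alone overshoots $K$, the Palette-WL ranks (below) decide which vertices
   are discarded; anchors are never discarded. Small environments are
   padded with empty slots so every pair maps to the same dimension.
2. **Vertex ordering.** A fully-connected classifier has no notion of
   vertex identity, so vertices must be presented in a canonical order
   that places structurally similar vertices from *different* subgraphs at
   similar positions. The package uses Palette-WL colour refinement: each
   vertex starts from the dense rank of its geometric mean hop distance
   $\sqrt{d(v, d_i)\, d(v, t_j)}$ to the two anchors, and colours are
   refined by the order-preserving hash
   $h(v) = c(v) + \sum_{u \in \Gamma(v)} \log p(c(u)) \big/
   \bigl(1 + \sum_{u \in V} \log p(c(u))\bigr)$,
   where $p(c)$ is the $c$-th prime. The fractional part is strictly below
   one, so refinement can only split colour classes, never reorder them;
   residual ties are broken deterministically (initial colour, drug before
   target, identifier) to obtain a bijective ranking with the anchors at
   ranks 1 and 2.
3. **Encoding.** The subgraph becomes a $K \times K$ symmetric matrix in
   rank order — 1 for interaction edges, similarity values within sides,
   zeros for padding — and the strict upper triangle is flattened column by
   column into a vector of length $K(K-1)/2$.
4. **Classification.** A small multilayer perceptron (three ReLU hidden
   layers of 32, 32 and 16 units, 2-way softmax output) maps the vector to
   an interaction probability.

Because only interactions are labelled, negatives must be manufactured
from the unknown pairs. The package ranks every unknown pair by the
reliability score
$s_{ij} = \exp\!\bigl(-(s^{DT}_{ij} + s^{TD}_{ji})\bigr)$, where
$s^{DT}_{ij} = \sum_{t_k \in T_{d_i}} S^T_{j k}$ sums the similarity of
$t_j$ to the targets known for $d_i$, and $s^{TD}_{ji}$ does the mirror-image
sum over the drugs known for $t_j$. A pair dissimilar to everything its
partners are known to bind scores near $e^0 = 1$ and is taken as a
*reliable negative*; training sets take the deterministic top of this
ranking (ties broken by identifier so runs are reproducible).

## Leakage control

Two places could trivially leak the label into the features, and both are
closed off:

* the anchor pair's own edge is removed from the subgraph at extraction,
  and the (rank 1, rank 2) cell of the encoded matrix is forced to zero,
  so positive and negative pairs differ only through their neighbourhoods;
* during cross-validation, the positive edges of the current test fold are
  removed from the network before the *test* subgraphs are extracted, so
  test labels cannot be read back off the topology. The same edge-removal
  protocol is applied when the heuristic baselines are evaluated
  (`heuristic_cv()`); scoring, say, preferential attachment on the full
  network would let it read each test pair's own edge off the degrees.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `K` | 10 | subgraph size (vertex slots); embedding length is $K(K-1)/2$. Larger $K$ reaches further into the graph (higher-order structure) at quadratic feature cost and eventual overfitting. |
| `ratio_alpha` | 1 | positive:negative ratio of assembled samples; `0.1` mimics realistic imbalance, `"all_unknown"` uses the full complement. |
| `mode` | `"reliable"` | negative selection: reliability-ranked prefix or uniform draw. |
| `hidden` | 32, 32, 16 | classifier layer widths (ReLU), softmax output. |
| `learning_rate`, `batch_size`, `epochs`, `patience` | 1e-3, 32, 100, 10 | Adam optimisation with early stopping on a 10% validation split; conventional values, all overridable — only the layer sizes and activations are considered part of the method, the optimiser settings are implementation choices. |
| `beta`, `l_max` | 0.01, 6 | Katz damping and path-length cap for the baseline; `beta` is far below the reciprocal spectral radius of typical sparse inputs, so the truncated sum is effectively converged. |

Indices are 1-based throughout the R API; all file formats are keyed by
string identifiers, so no off-by-one ambiguity crosses the I/O boundary.

## Numerical choices

* The refinement hash is computed in double precision; new colours are
  assigned by dense-ranking $h$ with a $10^{-9}$ tolerance so that equal
  colour multisets summed in different orders still collapse to one
  colour. Refinement stops at the first fixed point and is capped at
  $2|V|$ iterations (a warning notes the rare non-convergent case, which
  then falls back on the deterministic tie-break).
* Unreachable vertices (the anchor edge is removed, so one anchor may be
  cut off) enter the geometric mean with their hop distance capped at
  $2K$, ranking them after every reachable vertex.
* Similarity matrices are validated on construction: asymmetries up to
  $10^{-6}$ are symmetrised with a warning (exact symmetry is accepted to
  $10^{-9}$), the diagonal is forced to 1, and out-of-range values are
  errors. Matrix TSVs are written with shortest-round-trip formatting, so
  write/read cycles are bit-exact.
* Softmax and cross-entropy are computed with max-subtraction and a
  $10^{-12}$ probability floor.

## The synthetic benchmark

Real DTI releases cannot be bundled, and a generator is more useful for
testing anyway: it provides ground truth. `simulate_dti_network()` plants
the exact structure the method assumes. Drugs and targets get latent
Gaussian vectors; similarities are latent cosines mapped through
$(1+\cos)/2$; interactions are Bernoulli draws from
$\operatorname{logit}^{-1}(b + \text{strength} \cdot \text{affinity} +
\text{noise})$. The intercept $b$ is calibrated by bisection *against the
fixed uniform draw*, so the realised edge count matches the requested
density exactly rather than only in expectation. A held-out fraction of
true links is zeroed in $Y$ and returned separately.

The default conditions — 60 drugs, 80 targets, 2% density, association
strength 4, noise 0.1 — give roughly 96 interactions, mean degrees below
2, and a strongly recoverable signal: the scale mirrors the sparsity of
curated DTI data while keeping a full 10-fold cross-validation run in the
seconds range. These sizes are also what the test suite and the
reproduction script use.

What the generator does *not* emulate: real chemical similarity
distributions (Morgan-fingerprint dice scores are heavily right-skewed,
latent cosines are not), hub drugs/promiscuous targets beyond what the
logistic model produces, and biases of curation (interactions discovered
because a similar interaction was already known). Passing tests on
synthetic data therefore demonstrate the machinery recovers planted
guilt-by-association structure, not a particular benchmark number on any
real dataset.

## Design choices on genuinely open points

* **Pool ranking in extraction.** Candidate drugs (scored by similarity to
  the anchor drug) and targets (to the anchor target) compete in a single
  merged ranking on the common $[0,1]$ scale, drugs first on ties. Ranking
  the two roles jointly is the simplest reading of "sort the pool by
  similarity to the anchors"; alternating between roles would be equally
  defensible but needs an extra convention.
* **Refinement neighbourhoods use interaction edges only.** Similarity
  information already enters twice (pool ranking and the encoded matrix);
  thresholding it into discrete refinement edges would add a parameter the
  method does not otherwise need.
* **Anchor-edge masking.** Keeping the anchor cell in the vector but
  forcing it to zero preserves the stated $K(K-1)/2$ dimension while
  removing the label from the features. Leaving it in would let the
  classifier score training positives by reading their own label.
* **Deterministic negative prefix.** Reliable negatives are the exact top
  of the ranking rather than a draw from a top fraction: reproducible, and
  any stochastic variant is recovered by `mode = "random"` at the other
  extreme.
* **Chance-level null control with uniform negatives.** The no-signal
  check (association strength 0 must give AUROC $\approx 0.5$) is run with
  `mode = "random"`. The reliability ranking conditions on degree —
  completely isolated pairs score exactly 1 — so with reliable negatives a
  classifier can separate classes through a degree shortcut even when the
  similarities carry no information; uniform negatives isolate the
  similarity-signal pathway that the null is meant to probe.
* **Class weighting off by default.** In the imbalanced regimes the
  point is to measure the degradation, not to correct it; weighting is
  available as a flag.

## Evaluation protocol

`cross_validate()` performs stratified 10-fold cross-validation over the
assembled sample (stratification guarantees positives in every test fold
even at $\alpha = 10\%$ or below) and reports AUROC and AUPR per fold and
as mean $\pm$ SD. AUROC is the Mann-Whitney statistic with ties counting
one half; AUPR is the step-wise non-interpolated estimator, preferable
under imbalance because it ignores true negatives. Both are cross-checked
in the tests against brute-force pair-counting and threshold-enumeration
oracles.

A worked example on the default synthetic conditions:

```{r example, eval = FALSE}
sim <- simulate_dti_network(m = 60, n = 80, density = 0.02,
                            assoc_strength = 4, seed = 1)
cv <- cross_validate(sim$net, K = 10, ratio_alpha = 1,
                     mode = "reliable", folds = 10, seed = 1)
glance(cv)
heuristic_cv(sim$net, cv$samples, "PA", seed = 1)$mean_auroc
autoplot(cv)
```

The test suite runs this family of experiments in four directions, each a
qualitative claim about the method rather than a benchmark number: planted
signal is recovered (mean AUROC well above chance and above the
preferential-attachment baseline), reliable negatives beat random
negatives on AUPR at $\alpha = 10\%$, the full semi-bipartite input beats
the interactions-only ablation, and zero planted signal yields chance
performance.

## Known limitations

* The classifier is a plain fully-connected network on a flattened
  triangle: it cannot exploit permutation symmetries a graph neural
  network would, and subgraphs larger than $K$ are truncated, so very
  high-order structure is only partially visible.
* Palette-WL's hash is order-preserving but not collision-free in theory;
  in practice prime-log sums separate distinct colour multisets at the
  $10^{-9}$ tolerance on subgraphs of the sizes used here.
* Reliability-ranked negatives concentrate on sparsely connected nodes;
  models trained on them are partly degree-aware. This mirrors the
  sampling scheme's definition, but means reported performance under
  reliable sampling is not directly comparable to uniform-negative
  benchmarks (the package exposes both).
* The heuristic baselines are the similarity-weighted bipartite
  adaptations of common neighbours and Jaccard described above; other
  weightings exist, and the baselines are comparison points, not
  contributions.
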
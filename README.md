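# dtiwl

Drug-target interaction (DTI) prediction as link prediction on a
semi-bipartite graph. Given a sparse binary interaction matrix
*Y* (m drugs × n targets), a drug-drug similarity matrix *S<sup>D</sup>*
and a target-target similarity matrix *S<sup>T</sup>* (both in [0, 1]),
the package scores any candidate pair (d<sub>i</sub>, t<sub>j</sub>) by
classifying the *enclosing subgraph* of the pair — its K-vertex local
topological environment — rather than hand-crafted features.

The pipeline, for each candidate pair:

1. **Extract** a K-vertex enclosing subgraph: both anchors, their
   interaction neighbours, then further neighbours admitted in decreasing
   similarity to the anchors.
2. **Order** its vertices with Palette-WL colour refinement: initial
   colours are the dense ranks of each vertex's geometric mean hop
   distance √(d(v,d<sub>i</sub>)·d(v,t<sub>j</sub>)) to the anchors,
   refined by an order-preserving prime-logarithm hash to a bijective
   ranking (anchors at ranks 1–2).
3. **Encode** the subgraph as the column-major strict upper triangle of
   its K×K rank-ordered adjacency matrix — interaction edges as 1,
   within-side cells as similarity values — giving a K(K−1)/2 vector.
   The anchor cell is masked to zero so the label never leaks into the
   features.
4. **Classify** with a small multilayer perceptron (ReLU layers of
   32/32/16 units, softmax output) that outputs an interaction
   probability.

Training negatives are *reliable negatives*: unknown pairs ranked by
s<sub>ij</sub> = exp(−(s<sup>DT</sup><sub>ij</sub> + s<sup>TD</sup><sub>ji</sub>)),
where the two sums measure how similar t<sub>j</sub> is to the targets
known for d<sub>i</sub> and how similar d<sub>i</sub> is to the drugs
known for t<sub>j</sub>; pairs dissimilar to everything their partners
bind score near 1. Classical link-prediction heuristics (preferential
attachment, similarity-weighted common neighbours and Jaccard, Katz) are
included as baselines, evaluated under the same fold protocol. A seeded
synthetic-network generator with planted guilt-by-association structure
makes every stage testable without external data.

Audience: computational chemists / bioinformaticians prototyping DTI
screening pipelines, and anyone who wants a compact, fully reproducible
implementation of enclosing-subgraph link prediction with WL vertex
ordering.

## Worked example

```r
library(dtiwl)

sim <- simulate_dti_network(m = 60, n = 80, density = 0.02,
                            assoc_strength = 4, seed = 1)
sim$net
#> <dti_network> 60 drugs x 80 targets, 87 known interactions

cv <- cross_validate(sim$net, K = 10, ratio_alpha = 1,
                     mode = "reliable", folds = 10, seed = 1)
cv
#> <dti_cv> 10-fold cross-validation (K = 10, mode = reliable)
#>   AUROC 0.935 +/- 0.064   AUPR 0.941 +/- 0.056

heuristic_cv(sim$net, cv$samples, "PA", seed = 1)$mean_auroc
#> [1] 0.7284722
```

The simulated network plants the guilt-by-association structure the
method assumes (interaction probability increases with latent affinity,
similarities reflect latent closeness). The cross-validation holds out
each fold's positive edges before extracting its test subgraphs, so the
0.935 mean AUROC means the classifier recovers held-out links from the
surrounding topology alone — and clearly beats the degree-based
preferential-attachment baseline (0.728) under the identical protocol.
`tidy(cv)` gives per-fold metrics, `glance(cv)` the one-row summary,
`autoplot(cv)` a per-fold metric plot.

Real data goes in the same way via three TSV files:

```r
net <- read_dti_network("interactions.tsv",
                        "drug_similarity.tsv", "target_similarity.tsv")
samples <- assemble_samples(net, ratio_alpha = 0.1, mode = "reliable", seed = 1)
emb <- embed_pairs(net, samples, K = 10)
fit <- mlp_train(emb, seed = 1)
predict_pairs(fit, emb)
```

A thin CLI over the same functions lives at `inst/cli/dti-wlnet.R`
(subcommands `simulate`, `sample`, `embed`, `evaluate`, `run`), and
`run_pipeline()` orchestrates the whole flow from a YAML/JSON config.

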
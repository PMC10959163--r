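# mdpgcn

Predicting miRNA–disease associations with a **regular pair graph**, a
**degree-weighted edge sampler**, and a **graph convolutional network**.

## What problem this solves, and for whom

Curated catalogues of experimentally supported miRNA–disease associations
(MDAs) are sparse; most pairs are simply unlabeled. For computational
biologists prioritising candidate miRNAs for a disease (or candidate
diseases for a miRNA), `mdpgcn` turns the catalogue plus miRNA/disease
similarity information into calibrated association scores and ranked
candidate lists — and it evaluates honestly across four association-novelty
regimes: new links between known entities (**Tp**), new diseases (**Td**),
new miRNAs (**Tm**), and both new (**Tn**).

## The method

Link prediction is recast as transductive node classification. Each
miRNA–disease pair (MDP) is a node with feature vector

```
x(m, d) = [ IMSM[m, ] ∥ IDSM[d, ] ]
```

where IMSM/IDSM are integrated similarity matrices: functional (best-match
average over gene sets, S(g,G) = max_{g'∈G} S(g,g')) or semantic
similarity, with exact zeros filled from a Gaussian interaction profile
(GIP) kernel

```
K(i, j) = exp(−γ ‖P_i − P_j‖²),   γ = γ′ / mean_i ‖P_i‖² ,
```

computed on training association profiles only. Nodes are wired into an
**exactly k-regular** graph by mutual k-nearest neighbours plus a
deterministic regularity repair (default k = 5); non-regular (k-means
cliques) and heterogeneous (entity-block) contrast graphs are included.
A GCN `H^{l+1} = σ(D̃^{−1/2} Ã D̃^{−1/2} H^l W^l)` with a single-logit head
is trained on minibatch subgraphs induced by edges drawn with probability

```
p(e_uv) ∝ 1/deg(u) + 1/deg(v)
```

(uniform on a regular graph), de-biased by empirical normalization
coefficients λ_v = C_v/N (loss weights 1/λ) and α_uv = C_uv/C_v
(aggregation rescaling). Metrics: accuracy, precision, recall, F1 at a 0.5
cutoff and rank-statistic AUC, with repeated-seed experiments and paired
t-tests between configurations.

A planted-block synthetic generator emulates all required inputs, so the
entire pipeline runs and is tested without any download.

## Worked example

```r
library(mdpgcn)

data <- generate_synthetic(synthetic_spec(n_mirna = 80, n_disease = 60,
                                          n_blocks = 3, seed = 1))
data
#> synthetic miRNA-disease dataset: 80 miRNAs x 60 diseases, 567 positives, 3 blocks
#> new entities held out: 8 miRNAs, 6 diseases

fit <- run_mda_experiment(data, tasks = c("tp", "td"),
  config = gcn_config(hidden = c(32, 16), epochs = 60, batches_per_epoch = 5),
  seed = 1)
fit
#> mda_fit (regular graph, seed 1)
#>  task  accuracy precision    recall        f1       auc   n
#>    tp 0.7802198 0.7428571 0.8571429 0.7959184 0.8265306 182
#>    td 0.8061224 0.8125000 0.7959184 0.8041237 0.8113286  98

rank_candidates(fit$model, fit$graph, fit$nodes, "dis001", top_k = 5)
#> # A tibble: 5 × 4
#>    rank mirna  disease score
#>   <int> <chr>  <chr>   <dbl>
#> 1     1 mir073 dis001  0.871
#> 2     2 mir003 dis001  0.863
#> 3     3 mir014 dis001  0.841
#> 4     4 mir023 dis001  0.825
#> 5     5 mir070 dis001  0.721
```

Reading the output: each `metrics` row is one novelty regime scored on
masked test nodes (`n` pairs, half positive). The Tp AUC of 0.83 is at the
information ceiling of this fixture — given block assignments, held-out
links are independent coin flips, so the best possible ranker is the
same-block indicator (see the methods vignette). The ranked list contains
only pairs that are *not* known training positives; here all five top
candidates share the disease's latent block, i.e. the planted signal was
recovered.

The same pipeline runs from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mdpgcn.R", package = "mdpgcn"))') \
  run-all --seed=1 --out=results/demo
```

with subcommands `simulate`, `similarity`, `build-graph`, `train`,
`evaluate`, `rank`, `run-all`, all accepting `--seed`, `--config` (YAML)
and `--out`.

## Package layout

| | |
|---|---|
| `similarity_matrix()`, `gene_network()`, `mirna_functional_similarity()`, `gip_kernel_similarity()`, `average_semantic_similarity()`, `integrate_similarity()`, `disease_semantic_similarity()` | node-feature construction |
| `sample_negatives()`, `build_mdp_nodes()`, `knn_regular_graph()`, `kmeans_graph()`, `hetero_graph()` | pair-node and graph construction |
| `edge_probabilities()`, `sample_subgraph()`, `estimate_normalization()` | the random edge sampler |
| `gcn_config()`, `gcn_train()`, `predict_scores()`, `save_gcn_model()` | the classifier |
| `make_task_splits()`, `compute_metrics()`, `auc_score()`, `repeat_experiment()`, `paired_metric_test()`, `rank_candidates()` | evaluation and case studies |
| `synthetic_spec()`, `generate_synthetic()` | the planted-block generator |
| `read_*()` / `write_*()`, `read_run_config()`, `inst/cli/mdpgcn.R` | interchange formats and the CLI |

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; the methods vignette
(`vignettes/mdpgcn-methods.Rmd`) documents the model, its assumptions,
every tunable default, and known limitations.
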
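# perturbbench

Benchmarking machinery for **post-perturbation RNA-seq prediction** on
Perturb-seq-style data: pseudo-bulk delta profiles, the Pearson-delta metric
family, strong simple baselines, dataset-heterogeneity diagnostics, and a
derangement-permutation test for the pathway coherence of gene embeddings —
plus a synthetic Perturb-seq generator so the whole pipeline runs and is
tested without external data.

It is written for people who evaluate perturbation-response models
(foundation models, GNNs, classical regressors) and want to know whether a
reported win is real: whether the metric is informative, whether the
baseline is strong enough, and whether the dataset has any dynamic range at
all.

## The core quantities

For a perturbation *p* with observed pseudo-bulk profile
*y_p* (mean log-normalized expression over its cells), control profile
*y_c*, and model prediction *ŷ_p*:

- **Delta profile:** Δ_p = y_p − y_c (log space).
- **Pearson Delta:** r(ŷ_p − y_c, y_p − y_c) — the headline metric.
  Raw-space r(ŷ_p, y_p) is also computed but is saturated (> 0.95 for
  nearly any plausible prediction) by baseline expression magnitudes.
- **Pearson Delta DE / without target genes:** the same correlation
  restricted to the perturbation's top-20 differentially expressed genes
  (Welch t or Wilcoxon ranking), optionally excluding the CRISPR target
  gene(s), whose movement is trivially predictable.
- **Train Mean baseline:** predicts the mean of training pseudo-bulk
  profiles for every test perturbation.
- **Dynamic range:** best model minus Train Mean, aggregate Pearson Delta.
  A dataset whose perturbations all respond alike (high median pairwise
  delta correlation) leaves models indistinguishable from Train Mean.
- **Embedding coherence:** mean within-gene-set pairwise correlation of
  embedding vectors versus a fixed-point-free permutation (derangement)
  null, summarised as mean delta across sets with a 95% CI.

## Worked example

```r
library(perturbbench)

cfg <- sim_config(n_genes = 300, n_perturbations = 60,
                  cells_per_condition = 30, control_cells = 200,
                  shared_fraction = 0.40,   # expected pairwise delta correlation
                  embedding_noise = 0.05, seed = 102)
run <- run_benchmark(sim = cfg, models = c("train_mean", "rf", "en", "knn"),
                     seed = 102)
print(run)
```

```
benchmark_result: 4 model(s), 9 test perturbation(s), DE = ttest, k = 20
      model pearson pearson_delta pearson_delta_de pearson_delta_no_target
         en   0.984         0.735            0.790                   0.859
        knn   0.980         0.677            0.752                   0.813
         rf   0.983         0.727            0.788                   0.859
 train_mean   0.977         0.606            0.656                   0.719
median pairwise delta correlation: 0.359; dynamic range gap: 0.129 (en)
```

Reading this: every model, including the constant Train Mean prediction,
scores ≈ 0.98 raw-space Pearson — that column cannot rank models. Pearson
Delta separates them: the regressors over PCA-reduced embedding features
beat Train Mean by ≈ 0.13 at this heterogeneity level. Rerunning at
`shared_fraction = 0.66` (homogeneous, like pathway-focused screens) shrinks
the gap to ≈ 0.06; at 0.12 (diverse, genome-wide-like) it grows to ≈ 0.26 —
the dynamic-range diagnostic in action.

## The analysis scripts

Numbered drivers under `analysis/` reproduce the study end to end, writing
tables and figures under `results/`:

1. `01_simulate.R` — three synthetic instances spanning the observed
   heterogeneity range (median delta correlation ≈ 0.66 / 0.40 / 0.12),
   exported as CSV/TSV/GMT.
2. `02_benchmark.R` — Train Mean, RF, elastic net and kNN on each instance,
   scored with all four metrics under a perturbation-exclusive split.
3. `03_heterogeneity.R` — benchmark across a `shared_fraction` grid;
   relates median intra-dataset correlation to the dynamic-range gap
   (Spearman = −1 on the grid).
4. `04_coherence.R` — embedding-pathway coherence for noise-free, noisy and
   random embeddings against the derangement null.

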
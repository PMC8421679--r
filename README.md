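# thncdf

Drug–target interaction (DTI) prediction from a tripartite
drug–target–disease network, for computational pharmacologists doing drug
repositioning: given known interactions, chemical fingerprints and
target–disease associations, score the unobserved drug–target pairs.

## Method

Two similarity views are fused per entity class. Drugs combine the
Tanimoto coefficient over 166-bit structural-key fingerprints,

    SIM_chem(x, y) = |f_x AND f_y| / (|f_x| + |f_y| - |f_x AND f_y|),

with a Gaussian interaction-profile (GIP) kernel over adjacency rows;
targets combine GIP kernels over adjacency columns and over target–disease
profiles:

    K_GIP(i, j) = exp(-gamma * ||p_i - p_j||^2),
    gamma = gamma' / mean_i ||p_i||^2,          gamma' = 1

    SIM_drug = (1 - alpha) * K_GIP,d + alpha * SIM_chem     (alpha = 0.5)
    SIM_tar  = (1 - alpha) * K_GIP,t + alpha * K_GIP,S

A pair (i, j) is encoded as drug i's fused similarity row concatenated
with target j's fused similarity row, and classified by a **cascade deep
forest**: stacked levels of six tree ensembles (2 completely-random, 2
gradient-boosted, 2 extremely-randomized; 1,000 trees each by default).
Every forest emits out-of-fold class-probability vectors via stratified
10-fold CV; those vectors augment the next level's input, and the cascade
deepens while the out-of-fold AUPR improves. Evaluation is AUC and
average-precision AUPR under stratified 10-fold CV over pairs. Details,
assumptions and limitations: `vignettes/methods.Rmd`.

## Worked example

```r
library(thncdf)

data <- generate_synthetic(synth_config(seed = 7))   # planted 3-cluster network
data$interactions
#> interaction_matrix: 40 drugs x 50 targets, 316 interactions

sims <- similarity_pipeline(data$interactions, data$fingerprints, data$diseases)
sims$sim_drug
#> similarity_matrix: 40 x 40, off-diagonal mean 0.2533 (range 0.0897-0.6040)

sp  <- sample_pairs(data$interactions, negative_ratio = 1, seed = 7)
X   <- build_pair_features(sims$sim_drug, sims$sim_tar, sp$pairs)
cfg <- cascade_config(trees_per_forest = 50, cv_folds = 5, seed = 7)
model <- fit_cascade(X, sp$labels, cfg)
model
#> cascade_model: 2 level(s) retained (of 3 trained), 6 forests x 50 trees per level
#>   out-of-fold aupr by level: 0.8769, 0.8851, 0.8798
```

The out-of-fold AUPR line is the honest per-level validation score: level
2 improved on level 1 (0.877 → 0.885), level 3 did not (0.880), so the
cascade kept two levels. Scoring the training pairs themselves
(`predict(model, X, type = "score")`) gives AUC/AUPR ≈ 0.999 — purity-grown
trees memorize training data, which is why all reported numbers come from
held-out folds (`cross_validate()`), not resubstitution.

The same pipeline from the shell, reading/writing the TSV dialects:

```sh
inst/exec/thncdf simulate --seed 7 -o demo/
inst/exec/thncdf cv --interactions demo/interactions.tsv \
  --fingerprints demo/fingerprints.tsv --target-disease demo/target_disease.tsv \
  --trees 50 --folds 10 --seed 7 -o demo/
```

Every run writes a `manifest.json` with the resolved options, seeds and
input/output digests.

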
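---
title: "Methods: similarity fusion and the cascade deep forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity fusion and the cascade deep forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Given a binary drug–target adjacency matrix $Y \in \{0,1\}^{m \times n}$,
per-drug chemical fingerprints, and target–disease associations, the task is
to score unobserved drug–target pairs by their probability of interacting.
The package treats this as supervised bipartite link prediction on a
tripartite drug–target–disease network: similarities among drugs and among
targets are the features, and a layered tree ensemble is the classifier.

## The model

### Similarity layer

Three similarity sources are combined.

**Chemical structure.** Each drug carries a 166-bit structural-key
fingerprint (MACCS-style). Similarity between drugs $x$ and $y$ is the
Tanimoto coefficient
$$\mathrm{SIM}_{chem}(x,y) = \frac{|f_x \wedge f_y|}{|f_x| + |f_y| - |f_x \wedge f_y|},$$
the ratio of shared to total set bits. The 0/0 case (two empty
fingerprints) is defined as 0 off-diagonal and 1 on the diagonal: absence
of substructure evidence is not evidence of similarity, and this avoids
NaNs propagating into the feature matrix.

**Interaction profiles.** The Gaussian interaction-profile (GIP) kernel
compares rows (drugs) or columns (targets) of $Y$, and rows of the
target–disease matrix:
$$K_{GIP}(i,j) = \exp\left(-\gamma \, \lVert p_i - p_j \rVert^2\right),
\qquad
\gamma = \gamma' \Big/ \frac{1}{N}\sum_{i=1}^{N} \lVert p_i \rVert^2 .$$
The bandwidth normalization by the mean squared profile norm makes the
kernel scale-free in the network density; $\gamma' = 1$ for all three
kernels by default (`gamma_prime_*` arguments expose them individually).
If every profile is all-zero the bandwidth is undefined and the kernel
errors rather than guessing.

A literal reading of the kernel gives similarity 1 between two entities
that both lack any associations (distance 0 between zero profiles). That
is faithful but arguably an artifact, so `zero_profile_policy` offers both
readings: `"formula"` (default, literal) and `"zero"` (such off-diagonal
pairs scored 0). The discrepancy matters mainly for targets missing from
the disease layer, which are padded with all-zero disease profiles; the
disease-kernel bandwidth is computed over this padded, target-aligned
matrix so that the kernel is defined on the same index set as the target
GIP kernel.

**Fusion.** Drug and target similarities are convex combinations
$$\mathrm{SIM}_{drug} = (1-\alpha) K_{GIP,d} + \alpha\, \mathrm{SIM}_{chem},
\qquad
\mathrm{SIM}_{tar} = (1-\alpha) K_{GIP,t} + \alpha\, K_{GIP,S},$$
with $\alpha = 0.5$ by default — equal weight to both sources. The same
symbol governs both equations in the source method; the implementation
exposes `alpha_drug` and `alpha_target` separately but defaults both to
0.5. The fused matrices are symmetric with entries in $[0,1]$ but are not
guaranteed positive definite; no spectral correction is applied because
the downstream classifier is a tree ensemble, not a kernel machine.

### Pair encoding

A pair $(i, j)$ is encoded as the concatenation of drug $i$'s full fused
similarity row ($m$ values) and target $j$'s full fused similarity row
($n$ values). This similarity-profile encoding is the standard choice when
the fused similarity matrices are the sole classifier input; it is the one
genuine reconstruction in the pipeline (the source method states only that
the fused matrix is the cascade's input) and is flagged as such here.

Negative sampling: all positive pairs are kept, and non-interacting cells
are sampled uniformly without replacement at a stated ratio (default 1:1,
`"all"` available). Real DTI matrices are extremely imbalanced, and
evaluation numbers are only comparable under a disclosed ratio — the ratio
is therefore an explicit parameter recorded in the CV result rather than a
hidden protocol choice.

### Cascade deep forest

Each cascade level holds six forests: two completely-random tree forests
(each node splits on one uniformly chosen feature at a uniform threshold,
grown until leaves are pure), two gradient-boosted tree forests (depth-3
randomized regression trees on logistic gradients, Newton leaf values,
shrinkage 0.1), and two extremely-randomized tree forests
($\sqrt{p}$ random candidate features, one random threshold each, best
Gini gain). The published operating point is 1,000 trees per forest —
6,000 per level; tests run a documented 50-tree profile, and depth, not
tree count, is the behaviourally important dimension.

Each forest emits a *class vector* per instance — its class-probability
estimate, averaged over trees. During training these are produced by
stratified k-fold cross-validation (default k = 10): an instance's vector
comes only from fold models that never saw it. Level $\ell > 1$ consumes
the raw features concatenated with the previous level's out-of-fold class
vectors (width $p + 6 \times 2$). The mean out-of-fold positive-class
probability gives an honest per-level metric (AUPR by default); levels are
added while that metric improves by more than `early_stop_tolerance`
(default 0) up to `max_levels` (default 10), and the model is truncated to
the best level, earliest on ties. At prediction time a forest's class
vector is the average over its k fold models, so inference matches the
training-time semantics without refitting.

All randomness derives from one root seed through a splitmix-style mixing
function: per-forest, per-fold streams are independent, so changing the
forest count or fold count never silently reseeds earlier forests, and
fits are bit-reproducible.

### Evaluation

AUC is the Mann–Whitney statistic (ties counted half). AUPR is step-wise
average precision — precision averaged at the rank of each positive, ties
broken by ascending input index — not trapezoidal PR interpolation; the
two dialects differ, and average precision is the one reported here
throughout. Cross-validation is stratified over pairs (k = 10 by
default). By default the GIP kernels are computed from the full adjacency
matrix before splitting, mirroring the common protocol in this literature;
this leaks held-out interactions into the features, so
`mask_test_interactions = TRUE` recomputes the kernels per fold with the
held-out positives zeroed, for honest (and typically lower) numbers.

## The synthetic world

The generator plants co-cluster structure: drugs and targets are assigned
round-robin to `n_clusters` clusters; $Y_{ij} \sim \mathrm{Bern}(p_{in})$
within co-clustered blocks and $\mathrm{Bern}(p_{out})$ elsewhere; each
drug cluster has a prototype fingerprint (bit density 0.25, typical of
structural keys) whose members are independent $\varepsilon$-bit-flipped
copies; each target cluster maps to its own disease subset with edge
probability 0.5 inside it. An independent-uniform $Y$ would make every
similarity-propagation method uninformative, so the block model is the
minimal world in which the method's signal exists and is testable.

Defaults: m = 40 drugs, n = 50 targets, k = 20 diseases, 3 clusters,
$p_{in} = 0.4$, $p_{out} = 0.03$, $\varepsilon = 0.1$, 166-bit
fingerprints. That yields ~330 positives at ~15% density — denser than the
public benchmarks (1–3%) because stratified 10-fold CV needs tens of
positives per fold at desk scale. These values were fixed once, before any
acceptance measurement, and are not tuned.

What a green synthetic test establishes: the pipeline recovers planted
block structure well above the prevalence baseline, deterministically, at
stated parameters. What it does not establish: performance on real
pharmacological networks, whose degree heterogeneity, cold-start drugs,
and biased annotation the block model does not emulate.

## Numerical choices

- Distances in double precision; negative squared distances from
  cancellation are clamped to 0 before exponentiation.
- Similarity containers enforce symmetry to 1e-12 and re-symmetrize by
  averaging with the transpose.
- Similarity TSVs print 17 significant digits; round trips are lossless to
  1e-12.
- Tree RNG is a private mt19937_64 fed 53-bit uniforms; no
  implementation-defined `std::` distributions, so results are identical
  across platforms and compilers.
- Boosting clamps hessians at 1e-12 and the base rate into
  [1e-6, 1 − 1e-6].
- Ties: AUPR sorts by (descending score, ascending index); the early-stop
  rule prefers the shallowest of tied best levels (cheaper inference).

## Known limitations

- Pairwise random CV only; cold-start (unseen drug / unseen target) splits
  are out of scope and scores here do not transfer to that regime.
- The default evaluation inherits the literature's kernel-leakage
  protocol; the masking mode exists but is not the default.
- The negative-sampling protocol behind published benchmark figures is not
  recoverable; numbers from this package are comparable only under a
  stated ratio.
- No learned kernel weights, no additional similarity sources, no
  multi-grained scanning — the cascade alone is the classifier.
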
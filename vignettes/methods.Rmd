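---
title: "Consensus co-expression modules and causal discovery for paired omics"
author: "pcmods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus co-expression modules and causal discovery for paired omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmods)
```

## The problem

Matched transcriptomic and proteomic profiles of the same genes across a
small panel of samples (tissues, developmental stages) carry two partially
redundant views of the same regulatory programs. `pcmods` implements a
four-stage inference chain over such paired data:

1. **Filtering** — keep gene/protein pairs quantified in every sample at
   both levels, expressed above a minimal abundance in enough samples, and
   informative (no missing values, nonzero variance).
2. **Consensus module detection** — build a weighted co-expression network
   in each layer, combine them into a consensus topological overlap, and
   cluster it into modules supported by *both* layers simultaneously.
3. **Eigengene networks** — summarize each module by its eigengene (first
   principal component of the standardized module submatrix), relate
   modules through eigengene correlations, and quantify how well the
   inter-module structure is preserved between the two layers.
4. **Causal discovery** — treat the module eigengenes as variables and
   estimate the completed partially directed acyclic graph (CPDAG) of
   their causal structure with the PC algorithm under Gaussian
   conditional-independence testing.

Because real paired-omics compendia are external resources, the package
ships a synthetic-data module that plants known consensus modules and a
known causal DAG between the module latents, so that every stage can be
validated against ground truth. The acceptance checks in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` are built
entirely on this generator.

## The synthetic-data model

`generate_paired_omics()` draws module-level latent variables from a linear
Gaussian structural equation model over a user-supplied DAG
(`simulate_sem()`): each latent equals the weighted sum of its parents plus
N(0, `latent_noise_sd`^2) noise, evaluated in topological order. Every
member feature of module *m* in each layer is

    feature = loading * latent_m + N(0, feature_noise_sd^2),

with loadings drawn uniformly from `loading_range`. A fraction
`1 - layer_agreement` of protein-layer module features is rewired to a
private latent, which degrades the cross-layer consensus without changing
either layer's marginal co-expression structure. Background features are
i.i.d. noise in each layer — they emulate the unassigned "module 0" mass —
and a configurable fraction of them is squeezed below the abundance
threshold so the expression filter has genuine work.

Default conditions emulate a desk-scale paired-omics study: 15 samples,
module sizes of tens of features, `loading_range = c(0.7, 1)`,
`feature_noise_sd = 0.5`. The last value makes within-module feature
correlations around 0.6–0.8, which is what tight, biologically coherent
co-expression modules look like; smaller values give near-noiseless blocks
used by the unit tests to pin exact identities. `random_dag()` bounds edge
weights away from zero (magnitudes in [0.5, 1.5]) so that planted causal
effects are statistically detectable, and signs are random.

The abundance map is `x - min(x) + 1` per feature (shift-to-positive),
which preserves all correlation structure exactly, making recovery
behavior analyzable; `exponentiate = TRUE` provides a skewed FPKM-like
marginal instead. One master seed drives layered sub-seeds (DAG, latents,
loadings/noise, missingness) so components can be regenerated
independently.

What the generator does *not* model: tissue-specific biology,
normalization artifacts, mass-spectrometry censoring, heavy-tailed counts.
Passing the planted-recovery tests therefore demonstrates correctness of
the algorithms under the stated model, not performance on any particular
real compendium.

## Filtering rules

`filter_complete_pairs()` keeps features with no missing value in any
sample at either level. `filter_min_expression()` keeps features whose
abundance is strictly greater than `threshold` (default 1) in at least
`min_samples` samples in *both* layers; the default `min_samples` is one
third of the samples, rounded up — 5 of 15, 3 of 8. The strict inequality
and the one-out-of-three default are deliberate, configurable choices.
Zeros are valid observations; only `NA` is missing. `good_features()`
additionally drops zero-variance profiles, which carry no correlation
information and would break standardization downstream.

## Consensus module detection

Per layer, the adjacency between features is `|cor|^beta` (unsigned,
default) or `((1 + cor)/2)^beta` (signed). The soft-thresholding power
`beta` is chosen by `pick_soft_threshold()` as the smallest candidate for
which the *minimum* signed scale-free fit index across the two layers
reaches `r2_cut = 0.85`; when no candidate qualifies the pipeline falls
back to a configured default (9 for 15-sample runs). The fit index bins
the connectivity distribution into 10 equal-width bins and regresses
log-frequency on log-mean-connectivity; the sign encodes whether the
distribution decays.

The topological overlap `TOM_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 - a_ij)`
rewards shared neighborhoods. Layers are put on a common scale before the
consensus by matching the 0.95 off-diagonal quantile of each TOM to the
first (transcript) layer's — without calibration the weaker-scale layer
would dominate the element-wise minimum that defines the consensus.

`detect_modules()` clusters `1 - consensusTOM` by average linkage. The
dendrogram is cut at a single static height chosen adaptively: among all
candidate heights (midpoints between consecutive merge heights above the
0.05 height quantile), the ones producing the largest number of clusters
of at least `min_module_size = 30` members form a plateau, and the
sensitivity parameter `deep_split` (0–4, default 2, mapped to factors
0.95/0.90/0.80/0.70/0.55) positions the cut within that plateau — smaller
factors cut lower and give tighter cores. This plateau rule replaced a
fixed quantile-anchored cut during development: with heterogeneous module
tightness a single pre-registered fraction of the height range regularly
dissolved a valid module whose internal merges happened high in the tree,
while the plateau criterion finds every cut level at which the full
complement of admissible modules exists. It remains a static cut — the
full hybrid dynamic tree cut with its PAM stage is intentionally out of
scope.

Modules whose eigengenes correlate above `1 - merge_cut_height = 0.75` in
*every* layer are merged iteratively (`merge_close_modules()`, cut height
0.25, average linkage on the consensus eigengene dissimilarity).

Finally, `assign_unlabeled_features()` runs a module-membership (kME)
rescue: core modules define per-layer eigengenes, and each unassigned
feature is correlated with them on the *stacked* standardized observations
(transcript and protein sample vectors concatenated, doubling the
effective observation count). A feature joins its best module when that
correlation reaches `kme_threshold = 0.5`, with eigengenes recomputed
between the two passes. Stacking is what makes rescue reliable at small
sample counts: with 15 samples a single-layer correlation estimate has a
standard error near 0.27, so genuinely strong members routinely fall below
any sensible one-layer threshold, while the stacked estimate halves the
variance and cleanly separates members from background.

### Validation conditions for module recovery

The planted-recovery acceptance check uses five modules of 60 features,
50 background features, 15 samples, the default moderate noise, and
*independent* module latents (an edgeless DAG). The last choice is
deliberate: with a non-trivial planted DAG, latents of connected modules
can correlate above 0.75 (an edge weight of 1.2 alone gives a latent
correlation of 0.77), at which point the merge rule *correctly* fuses the
corresponding modules and the planted partition stops being the right
reference. Independent latents isolate what the check is about —
cluster-structure recovery — while causal-structure recovery is validated
separately on the SEM outputs directly. With full layer agreement the
adjusted Rand index against the planted labels exceeds 0.9 across seeds;
halving `layer_agreement` must strictly decrease it, confirming that the
consensus construction actually uses both layers.

## Eigengene networks and preservation

Module eigengenes are unit-norm first principal components of the
standardized module submatrix, sign-aligned to correlate nonnegatively
with the mean member profile (otherwise the arbitrary sign of a singular
vector would corrupt cross-layer comparisons — flipping one eigengene maps
its adjacencies `A` to `1 - A`). The eigengene network is
`A_pq = (1 + cor(e_p, e_q)) / 2`; cross-layer preservation is
`P = 1 - |A_transcript - A_protein|`, and a module's mean preservation is
its column mean excluding the diagonal. Z-score trend profiles average the
per-feature z-scores of a module's members per sample. Tissue heatmap row
ordering uses complete-linkage clustering of eigengene rows under
Euclidean distance; columns are never reordered.

## Causal discovery over eigengenes

The sufficient statistic for Gaussian conditional-independence testing is
the correlation matrix of the eigengene observations plus their count.
By default the pipeline stacks the transcript-layer and protein-layer
eigengene sample vectors (n = 2 x samples); single-layer modes are
available. Stacking is a pragmatic response to a real identifiability
constraint: with more modules than samples a single-layer correlation
matrix is rank-deficient, and no mode here claims to replicate any
specific published graph.

`partial_correlation()` inverts the sub-correlation matrix on
`{i, j} ∪ S`; `fisher_z_test()` uses `z = atanh(rho)` with statistic
`sqrt(n - |S| - 3) |z|` against the standard normal. The skeleton search
is the order-independent ("stable") variant: adjacency sets are
snapshotted per level, all subsets of the snapshot neighborhood are tested
in lexicographic order, and the first separating set removes the edge and
is recorded. The conditioning size is capped at `n - 5` by default so the
Fisher-z precondition `n - |S| - 3 >= 1` cannot be violated at small
sample sizes. Unshielded triples `x - y - z` are oriented as colliders
exactly when `y` is absent from the recorded separating set; conflicting
orientations resolve last-writer-wins with a logged warning. Meek's rules
R1–R4 then complete the graph to the CPDAG. `alpha` defaults to the
conventional 0.05 and is surfaced prominently in the pipeline
configuration because the choice materially shapes the graph.

Two oracles guard this machinery. `d_separation_oracle()` turns a DAG into
an exact conditional-independence test (ancestral moralization), and
`dag_to_cpdag()` computes the true equivalence class; `pc_with_test()`
under the oracle must reproduce `dag_to_cpdag()` exactly — verified
exhaustively over all 568 labeled DAGs on 3–4 nodes and 200 random 5–6
node DAGs. `dag_to_cpdag()` itself is checked in the test suite against a
brute-force enumeration of each DAG's Markov equivalence class. Degenerate
and numerical edge cases: correlations are clamped to `(-1, 1)` before the
Fisher transform; a singular conditioning sub-matrix raises an error
naming the offending set; pairs never separated because the conditioning
cap was hit keep their edge.

### Finite-sample recovery and its limit

On simulated SEM data (8 nodes, edge probability 0.3, n = 2000,
alpha = 0.01) the mean structural Hamming distance between the estimated
and true CPDAG is around 3 over 50 replicates. This is essentially the
information-theoretic floor for these generation conditions, not
estimation slack: running the identical algorithm on the *population*
correlation matrix gives nearly the same mean SHD, because random-sign
path weights produce cancellations that push some population partial
correlations below the detection threshold implied by alpha and n
(|rho| around 0.058). The Fisher-z test itself is calibrated (type-I rate
0.049 at alpha = 0.05 over 2000 replicates), and the structural machinery
is exactly oracle-consistent, so residual SHD reflects near-unfaithful
parameter draws rather than implementation error.

## The pipeline

`run_pipeline()` executes simulate/load → filter → soft threshold →
consensus modules → eigengene networks → PC, writing every stage's output
as self-describing TSV before the next stage runs, and finishing with a
key-value manifest (feature counts per filter step, chosen power, module
count and sizes, CPDAG summary, and — when the input was simulated — the
ARI against planted labels and, when module counts allow an unambiguous
mapping, the SHD against the planted CPDAG). No timestamps or
machine-dependent values are written, so identical configuration and seed
give byte-identical artifacts. Configurations load from flat YAML files
(`read_pipeline_config()`); every statistical parameter is explicit in the
config with no hidden defaults in the runner, and the run log echoes them
at start for provenance.

Problem sizes used by the validation suite — a few hundred features, 8–15
samples, 3–8 node DAGs, 50–2000 observations — were chosen so the whole
chain remains a desk-scale computation while every statistical property
under test (calibration, recovery, determinism) is measurable with
comfortable margins.

## Known limitations

- Causal sufficiency is assumed; no latent-confounder machinery (FCI) or
  score-based search is provided.
- The consensus clustering is single-block: feature counts must fit in
  memory as a dense TOM. Block-wise decomposition is out of scope.
- The Gaussian-loading generative model is a stand-in for real
  proteogenomic noise, which is uncharacterized here; absolute recovery
  numbers do not transfer to real compendia.
- With more modules than stacked observations the eigengene correlation
  matrix approaches singularity; the PC stage then depends on the
  conditioning cap to stay defined.
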
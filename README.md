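# pcmods

Consensus co-expression modules and causal discovery for paired
transcript/protein expression data.

## What it does

Given matched transcriptomic and proteomic abundance matrices for the same
genes across a small sample panel, `pcmods` runs a four-stage inference
chain:

1. **Filter** gene/protein pairs: complete observations in both layers,
   abundance strictly above a threshold (default 1) in at least one third
   of the samples at both levels, nonzero variance.
2. **Consensus modules**: per-layer weighted co-expression networks
   (`|cor|^beta`, soft threshold chosen by the scale-free topology
   criterion), topological overlap matrices, a quantile-calibrated
   element-wise-minimum consensus, average-linkage clustering with a
   minimum module size of 30 and eigengene-based merging at cut height
   0.25 — modules must be supported by both omics layers simultaneously.
3. **Eigengene networks**: each module is summarized by its eigengene (the
   unit-norm first principal component of the standardized module
   submatrix); inter-module adjacency is `(1 + cor)/2`, and cross-layer
   preservation is `1 - |A_transcript - A_protein|`.
4. **Causal discovery**: the PC algorithm with Fisher-z
   conditional-independence tests estimates the completed partially
   directed acyclic graph (CPDAG) over the module eigengenes — directed
   edges are causal directions identifiable from the data; undirected
   edges are ambiguous within the Markov equivalence class.

A synthetic-data generator plants known modules and a known causal DAG
(linear Gaussian structural equation model over module latents), so the
whole chain is validated against ground truth: exhaustive
equivalence-class oracle checks for PC, calibration checks for the CI
test, and adjusted-Rand-index checks for module recovery. See
`vignettes/methods.Rmd` for the model and all design decisions.

## Worked example

Simulate a study with four planted modules of 50 gene/protein pairs whose
latents follow the causal chain `M4 -> M2 -> M1` (plus an isolated `M3`),
40 background features, and 15 samples; then run the stages:

```r
library(pcmods)

truth_dag <- random_dag(4, 0.5, seed = 8)
truth_dag$edges
#>   parent child     weight
#> 1     M4    M2 -0.5893010
#> 2     M2    M1 -0.9323914

sim  <- generate_paired_omics(rep(50, 4), n_background = 40,
                              dag = truth_dag, n_samples = 15, seed = 8)
filt <- filter_paired_omics(sim$data)
filt$report
#>             step n_features
#> 1          input        240
#> 2 complete_pairs        240
#> 3 min_expression        228
#> 4  good_features        228

pair_spearman_summary(filt$data)
#> pair_correlation_summary: 228 pairs, mean rho 0.651, 210 positive (92.1%)

st    <- pick_soft_threshold(list(filt$data$transcript, filt$data$protein))
power <- if (is.na(st$chosen_power)) 9 else st$chosen_power
cm    <- consensus_modules(filt$data, power = power)
cm$partition
#> module_partition: 228 features, 4 modules (sizes 51, 50, 50, 50), 27 unassigned

eig_t <- eigengene_matrix(filt$data$transcript, cm$partition, "transcript")
eig_p <- eigengene_matrix(filt$data$protein,    cm$partition, "protein")
pres  <- preservation_network(eigengene_adjacency(eig_t), eigengene_adjacency(eig_p))
round(mean_preservation(pres), 3)
#>   ME1   ME2   ME3   ME4
#> 0.990 0.987 0.987 0.989

obs <- cbind(eig_t$values, eig_p$values)   # stack layers: n = 30 observations
g   <- pc(ci_suff_stat(cor(t(obs)), ncol(obs)), alpha = 0.05)
summarize_cpdag(g)
#> cpdag_summary: 0 directed, 2 undirected edges, 1 subgraphs; effect-only: none
g$undirected_edges
#>     a   b
#> 1 ME1 ME2
#> 2 ME2 ME4

truth <- sim$truth$module_labels[names(cm$partition$labels)]
module_recovery_ari(cm$partition$labels, truth)
#> [1] 0.9908515
```

Reading the output: the 12 low-abundance background features are filtered
away; RNA–protein pairs correlate positively (mean Spearman rho 0.651); all
four planted modules are recovered (ARI vs truth 0.99, with the 27 pure
noise features left unassigned as "module 0"); cross-layer preservation of
the eigengene network is near 1 because both layers share the same planted
structure. The CPDAG recovers exactly the skeleton of the planted chain
`M4 - M2 - M1` — undirected, which is correct: a three-node chain has no
v-structure, so its causal directions are not identifiable from
observational data, and all DAGs in its equivalence class are admissible.

The same chain runs end-to-end with provenance via

```r
cfg <- pipeline_config(output_dir = "run", seed = 8,
                       simulate = list(module_sizes = rep(50, 4), n_background = 40,
                                       dag_nodes = 4, dag_edge_prob = 0.5, n_samples = 15))
run_pipeline(cfg)   # writes TSVs for every stage plus manifest.tsv
```

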
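#' Build a pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one validated record.
#' Either `transcript_path`/`protein_path` point at TSV inputs, or
#' `simulate` carries the arguments of [generate_paired_omics()] (minus the
#' seed, which is the pipeline seed).
#'
#' @param output_dir directory for all stage artifacts (created if absent).
#' @param seed master seed for simulation.
#' @param transcript_path,protein_path optional TSV inputs (mutually
#'   exclusive with `simulate`).
#' @param simulate optional named list of [generate_paired_omics()]
#'   arguments.
#' @param filter_threshold,filter_min_samples expression filter settings;
#'   `filter_min_samples = NA` means `ceiling(n_samples / 3)`.
#' @param network_type "unsigned" or "signed".
#' @param powers candidate soft-threshold powers.
#' @param r2_cut scale-free fit cutoff.
#' @param fallback_power power used when no candidate reaches `r2_cut`
#'   (default 9, suitable for 15-sample two-layer runs).
#' @param min_module_size,deep_split,merge_cut_height module detection
#'   settings.
#' @param calibration_quantile consensus TOM calibration quantile.
#' @param alpha significance level of the Fisher-z tests (required choice;
#'   conventional default 0.05).
#' @param eigengene_stacking "stacked" (default): transcript and protein
#'   eigengene observations are concatenated, so the CI tests see
#'   `2 * n_samples` observations; "transcript" or "protein" use a single
#'   layer.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            seed = 1,
                            transcript_path = NULL,
                            protein_path = NULL,
                            simulate = NULL,
                            filter_threshold = 1,
                            filter_min_samples = NA,
                            network_type = "unsigned",
                            powers = c(1:10, 12, 14, 16, 18, 20),
                            r2_cut = 0.85,
                            fallback_power = 9,
                            min_module_size = 30,
                            deep_split = 2,
                            merge_cut_height = 0.25,
                            calibration_quantile = 0.95,
                            alpha = 0.05,
                            eigengene_stacking = c("stacked", "transcript", "protein")) {
  eigengene_stacking <- match.arg(eigengene_stacking)
  if (is.null(simulate) && (is.null(transcript_path) || is.null(protein_path)))
    stop("provide either input paths or simulation parameters")
  if (!is.null(simulate) && !is.null(transcript_path))
    stop("input paths and simulation parameters are mutually exclusive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (merge_cut_height <= 0 || merge_cut_height >= 1)
    stop("merge_cut_height must be in (0, 1)")
  structure(list(output_dir = output_dir, seed = seed,
                 transcript_path = transcript_path, protein_path = protein_path,
                 simulate = simulate,
                 filter_threshold = filter_threshold,
                 filter_min_samples = filter_min_samples,
                 network_type = network_type, powers = powers,
                 r2_cut = r2_cut, fallback_power = fallback_power,
                 min_module_size = min_module_size, deep_split = deep_split,
                 merge_cut_height = merge_cut_height,
                 calibration_quantile = calibration_quantile,
                 alpha = alpha, eigengene_stacking = eigengene_stacking),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; simulation parameters
#' live under the `simulate` mapping. `simulate$dag_nodes` /
#' `simulate$dag_edge_prob` request a random DAG over the modules.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full inference pipeline
#'
#' Stage order: simulate (or load) paired omics; filter (complete pairs,
#' minimum expression, good features); pick the soft-thresholding power;
#' consensus module detection (adjacency, TOM, calibrated consensus,
#' clustering, merging); eigengene networks, preservation and z-score
#' profiles; PC-based CPDAG over the module eigengenes. Every stage's
#' output is written as TSV into `output_dir` before the next stage runs,
#' and the run manifest records the headline numbers of every stage.
#' Identical configuration and seed produce byte-identical artifacts.
#'
#' When fewer than two modules are detected, the eigengene-network and
#' causal stages are skipped with a warning (a single module supports no
#' inter-module inference).
#'
#' @param config a [pipeline_config()].
#' @return named list (the manifest), invisibly also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output_dir, name)
  manifest <- list(seed = config$seed, alpha = config$alpha,
                   network_type = config$network_type,
                   min_module_size = config$min_module_size,
                   deep_split = config$deep_split,
                   merge_cut_height = config$merge_cut_height,
                   eigengene_stacking = config$eigengene_stacking)
  message(sprintf("[pipeline] alpha=%g network_type=%s min_module_size=%d deep_split=%d merge_cut=%g",
                  config$alpha, config$network_type, config$min_module_size,
                  config$deep_split, config$merge_cut_height))

  # -- stage: input ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(sim_args$dag_nodes)) {
      seeds <- derive_seeds(config$seed, 2)
      sim_args$dag <- random_dag(sim_args$dag_nodes,
                                 sim_args$dag_edge_prob %||% 0.3, seeds[1])
      sim_args$dag_nodes <- NULL
      sim_args$dag_edge_prob <- NULL
      sim_args$seed <- seeds[2]
    } else {
      sim_args$seed <- sim_args$seed %||% config$seed
    }
    sim <- do.call(generate_paired_omics, sim_args)
    data <- sim$data
    truth <- sim$truth
    write_paired_omics(data, out("transcript_raw.tsv"), out("protein_raw.tsv"))
    write_synthetic_truth(truth, out("truth_modules.tsv"), out("truth_dag.tsv"))
  } else {
    data <- read_paired_omics(config$transcript_path, config$protein_path)
  }
  manifest$n_features_input <- n_features(data)
  manifest$n_samples <- n_samples(data)

  # -- stage: filtering -----------------------------------------------------
  min_samp <- if (is.na(config$filter_min_samples))
    ceiling(n_samples(data) / 3) else config$filter_min_samples
  filt <- filter_paired_omics(data, config$filter_threshold, min_samp)
  data <- filt$data
  utils::write.table(filt$report, out("filter_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_paired_omics(data, out("transcript_filtered.tsv"), out("protein_filtered.tsv"))
  for (i in seq_len(nrow(filt$report)))
    manifest[[paste0("n_features_", filt$report$step[i])]] <- filt$report$n_features[i]
  if (n_features(data) == 0) stop("pipeline_error:filtering: no features survive the filters")
  spear <- pair_spearman_summary(data)
  manifest$mean_pair_spearman <- round(spear$mean_rho, 6)
  manifest$frac_positive_spearman <- round(spear$n_positive / spear$n_total, 6)

  # -- stage: soft threshold ------------------------------------------------
  layers <- list(transcript = data$transcript, protein = data$protein)
  st <- pick_soft_threshold(layers, config$powers, config$r2_cut,
                            config$network_type)
  write_soft_threshold_tsv(st, out("soft_threshold.tsv"))
  power <- if (is.na(st$chosen_power)) config$fallback_power else st$chosen_power
  manifest$chosen_power <- power
  manifest$power_from_fallback <- is.na(st$chosen_power)

  # -- stage: consensus modules --------------------------------------------
  cm <- consensus_modules(data, power, config$network_type,
                          config$calibration_quantile,
                          config$min_module_size, config$deep_split,
                          config$merge_cut_height)
  part <- cm$partition
  write_partition_tsv(part, out("module_labels.tsv"))
  manifest$n_modules <- length(part$module_ids)
  manifest$module_sizes <- paste(part$sizes, collapse = ",")
  manifest$n_unassigned <- sum(part$labels == 0)
  if (!is.null(truth)) {
    truth_labels <- truth$module_labels[names(part$labels)]
    manifest$ari_vs_truth <- round(module_recovery_ari(part$labels, truth_labels), 6)
  }

  if (length(part$module_ids) < 2) {
    warning("fewer than 2 modules detected; eigengene and causal stages skipped")
    manifest$causal_stage <- "skipped"
    write_manifest(manifest, out("manifest.tsv"))
    return(invisible(manifest))
  }

  # -- stage: eigengene networks -------------------------------------------
  eig_t <- eigengene_matrix(data$transcript, part, layer = "transcript")
  eig_p <- eigengene_matrix(data$protein, part, layer = "protein")
  write_eigengene_tsv(eig_t, out("eigengenes_transcript.tsv"))
  write_eigengene_tsv(eig_p, out("eigengenes_protein.tsv"))
  net_t <- eigengene_adjacency(eig_t)
  net_p <- eigengene_adjacency(eig_p)
  write_module_matrix_tsv(net_t$adjacency, out("eigengene_network_transcript.tsv"))
  write_module_matrix_tsv(net_p$adjacency, out("eigengene_network_protein.tsv"))
  pres <- preservation_network(net_t, net_p)
  write_module_matrix_tsv(pres, out("preservation.tsv"))
  mp <- mean_preservation(pres)
  utils::write.table(data.frame(module = names(mp), mean_preservation = round(mp, 6)),
                     out("mean_preservation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$mean_preservation_overall <- round(mean(mp), 6)
  write_omics_tsv(module_zscore_profiles(data$transcript, part),
                  out("zscore_profiles_transcript.tsv"), id_column = "module")
  write_omics_tsv(module_zscore_profiles(data$protein, part),
                  out("zscore_profiles_protein.tsv"), id_column = "module")
  ord <- eigengene_tissue_clustering(eig_t)
  writeLines(ord$order, out("eigengene_row_order.txt"))

  # -- stage: causal discovery ---------------------------------------------
  obs <- switch(config$eigengene_stacking,
                stacked = cbind(eig_t$values, eig_p$values),
                transcript = eig_t$values,
                protein = eig_p$values)
  suff <- ci_suff_stat(stats::cor(t(obs)), ncol(obs))
  g <- pc(suff, config$alpha)
  write_cpdag_tsv(g, out("cpdag_edges.tsv"))
  write_cpdag_dot(g, out("cpdag.dot"))
  s <- summarize_cpdag(g)
  manifest$n_directed_edges <- s$n_directed
  manifest$n_undirected_edges <- s$n_undirected
  manifest$n_connected_subgraphs <- s$n_connected_subgraphs
  manifest$effect_only_modules <- paste(s$effect_only_nodes, collapse = ",")
  manifest$ci_sample_size <- suff$n

  if (!is.null(truth) &&
      length(part$module_ids) == length(truth$dag$nodes)) {
    # planted and detected module counts agree: map detected label k to the
    # planted module its members predominantly carry, then compare graphs
    map <- vapply(part$module_ids, function(k) {
      members <- names(part$labels)[part$labels == k]
      tl <- truth$module_labels[members]
      tl <- tl[tl > 0]
      if (length(tl) == 0) NA_character_ else truth$dag$nodes[as.integer(names(sort(table(tl), decreasing = TRUE))[1])]
    }, character(1))
    if (!anyNA(map) && !anyDuplicated(map)) {
      relabel <- stats::setNames(map, paste0("ME", part$module_ids))
      g2 <- cpdag(unname(relabel[g$nodes]),
                  data.frame(from = unname(relabel[g$directed_edges$from]),
                             to = unname(relabel[g$directed_edges$to])),
                  data.frame(a = unname(relabel[g$undirected_edges$a]),
                             b = unname(relabel[g$undirected_edges$b])))
      manifest$shd_vs_truth <- shd_to_truth(g2, truth$dag)
    }
  }

  write_manifest(manifest, out("manifest.tsv"))
  invisible(manifest)
}

# deterministic key/value manifest writer (sorted keys would hide stage
# order; insertion order is kept instead)
write_manifest <- function(manifest, path) {
  df <- data.frame(key = names(manifest),
                   value = vapply(manifest, function(v) paste(format(v, trim = TRUE), collapse = ","),
                                  character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
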
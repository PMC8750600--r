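#' Generate paired omics data with planted modules and a planted causal DAG
#'
#' Emulates a two-layer (transcript + protein) expression study: module-level
#' latent variables follow a linear Gaussian structural equation model over a
#' known DAG; each member feature is `loading * latent + noise`; a fraction
#' `1 - layer_agreement` of protein-layer module features is rewired to an
#' independent latent, degrading cross-layer consistency. Background features
#' are i.i.d. noise (the unassigned "module 0" concept), and a fraction of
#' them is forced below the minimum-expression filter threshold so the
#' filtering stage has work to do. Values are shifted per feature to a
#' nonnegative abundance scale (`x - min(x) + 1`), which preserves all
#' correlation structure; `exponentiate = TRUE` instead maps through
#' `exp(x / 2)` for a skewed FPKM-like marginal.
#'
#' @param module_sizes integer vector; one planted module per entry, its
#'   length must equal the number of DAG nodes.
#' @param n_background number of unassigned noise features.
#' @param dag a [dag()] over the module latents (one node per module).
#' @param n_samples number of samples (tissues); at least 4. Default 15.
#' @param loading_range length-2 interval from which feature loadings are
#'   drawn uniformly; must not contain 0 in its interior (the sign of the
#'   within-module correlation would be ambiguous). Default `c(0.7, 1)`.
#' @param feature_noise_sd standard deviation of per-feature noise around
#'   `loading * latent`. Default 0.5 (moderate: within-module correlations
#'   around 0.6-0.8 when latent variance is 1).
#' @param layer_agreement fraction of protein-layer module features driven
#'   by their own module's latent; the rest get independent latents.
#' @param low_expression_fraction fraction of background features rescaled
#'   to lie below the default abundance threshold of 1 in every sample.
#' @param latent_noise_sd noise standard deviation of the module-latent SEM.
#' @param na_fraction fraction of cells set to `NA` in each layer
#'   (default 0 = complete data), for exercising the complete-pairs filter.
#' @param exponentiate use `exp(x / 2)` instead of the shift-to-positive map.
#' @param seed master integer seed; drives layered sub-seeds for the latent
#'   SEM, the loadings, the feature noise and the missingness mask.
#' @return list with `data` (a [paired_omics()]) and `truth` (class
#'   `synthetic_truth`: `module_labels` -- named integer vector, 0 =
#'   background; `dag`; `latents` -- samples x modules matrix;
#'   `generation_params`).
#' @export
generate_paired_omics <- function(module_sizes, n_background, dag, n_samples = 15,
                                  loading_range = c(0.7, 1),
                                  feature_noise_sd = 0.5,
                                  layer_agreement = 1,
                                  low_expression_fraction = 0.3,
                                  latent_noise_sd = 1,
                                  na_fraction = 0,
                                  exponentiate = FALSE,
                                  seed = 1) {
  stopifnot(inherits(dag, "dag"))
  if (length(module_sizes) != length(dag$nodes))
    stop("module_sizes must have one entry per DAG node")
  if (any(module_sizes < 1)) stop("module sizes must be positive")
  if (n_samples < 4) stop("n_samples must be at least 4")
  if (length(loading_range) != 2 || loading_range[1] > loading_range[2])
    stop("loading_range must be an ordered interval")
  if (loading_range[1] < 0 && loading_range[2] > 0)
    stop("loading_range must not contain 0 in its interior")
  if (layer_agreement < 0 || layer_agreement > 1)
    stop("layer_agreement must be in [0, 1]")

  seeds <- derive_seeds(seed, 4)
  n_modules <- length(module_sizes)
  p <- sum(module_sizes) + n_background
  samples <- sprintf("S%02d", seq_len(n_samples))
  features <- sprintf("F%05d", seq_len(p))
  labels <- c(rep(seq_len(n_modules), module_sizes), rep(0L, n_background))
  names(labels) <- features

  # module latents from the planted SEM (samples x modules)
  latents <- simulate_sem(dag, n_samples, noise_sd = latent_noise_sd,
                          seed = seeds[1])

  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })

  set.seed(seeds[2])
  load_t <- stats::runif(p, loading_range[1], loading_range[2])
  load_p <- stats::runif(p, loading_range[1], loading_range[2])
  n_module_feats <- sum(module_sizes)
  rewired <- stats::runif(p) > layer_agreement  # protein layer only
  rewired[labels == 0] <- FALSE
  private_latents <- matrix(stats::rnorm(n_samples * p), n_samples, p)

  set.seed(seeds[3])
  make_layer <- function(loadings, use_private) {
    vals <- matrix(stats::rnorm(p * n_samples, 0, feature_noise_sd), p, n_samples)
    for (i in seq_len(p)) {
      if (labels[i] == 0) {
        # background: i.i.d. noise, independent between layers
        vals[i, ] <- stats::rnorm(n_samples)
      } else {
        base <- if (use_private && rewired[i]) private_latents[, i]
                else latents[, labels[i]]
        vals[i, ] <- vals[i, ] + loadings[i] * base
      }
    }
    dimnames(vals) <- list(features, samples)
    vals
  }
  tr <- make_layer(load_t, use_private = FALSE)
  pr <- make_layer(load_p, use_private = TRUE)

  to_abundance <- function(m) {
    if (exponentiate) return(exp(m / 2))
    t(apply(m, 1, function(x) x - min(x) + 1))
  }
  tr <- to_abundance(tr)
  pr <- to_abundance(pr)
  dimnames(tr) <- dimnames(pr) <- list(features, samples)

  set.seed(seeds[4])
  # background features forced below the expression filter threshold
  if (n_background > 0 && low_expression_fraction > 0) {
    bg <- which(labels == 0)
    n_low <- round(low_expression_fraction * length(bg))
    if (n_low > 0) {
      low <- sample(bg, n_low)
      tr[low, ] <- matrix(stats::runif(n_low * n_samples, 0.01, 0.95),
                          n_low, n_samples)
      pr[low, ] <- matrix(stats::runif(n_low * n_samples, 0.01, 0.95),
                          n_low, n_samples)
    }
  }
  if (na_fraction > 0) {
    poke <- function(m) {
      idx <- which(stats::runif(length(m)) < na_fraction)
      m[idx] <- NA_real_
      m
    }
    tr <- poke(tr); pr <- poke(pr)
  }

  truth <- structure(list(
    module_labels = labels,
    dag = dag,
    latents = latents,
    generation_params = list(module_sizes = module_sizes,
                             n_background = n_background,
                             n_samples = n_samples,
                             loading_range = loading_range,
                             feature_noise_sd = feature_noise_sd,
                             layer_agreement = layer_agreement,
                             low_expression_fraction = low_expression_fraction,
                             latent_noise_sd = latent_noise_sd,
                             na_fraction = na_fraction,
                             exponentiate = exponentiate,
                             seed = seed)),
    class = "synthetic_truth")
  list(data = paired_omics(tr, pr), truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d features, %d planted modules, DAG with %d edges\n",
              length(x$module_labels),
              length(x$generation_params$module_sizes),
              nrow(x$dag$edges)))
  invisible(x)
}

#' Write planted truth to TSV files
#'
#' Emits the per-feature module labels (feature_id, module) and the planted
#' DAG edge list (parent, child, weight).
#'
#' @param truth a `synthetic_truth`.
#' @param labels_path,dag_path output paths.
#' @export
write_synthetic_truth <- function(truth, labels_path, dag_path) {
  utils::write.table(
    data.frame(feature_id = names(truth$module_labels),
               module = as.integer(truth$module_labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_dag_tsv(truth$dag, dag_path)
  invisible(truth)
}
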
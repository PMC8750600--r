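#' Weighted co-expression adjacency from an expression matrix
#'
#' Pearson correlation between feature profiles across samples, raised to a
#' soft-thresholding power. Unsigned networks use `|r|^beta`; signed
#' networks use `((1 + r) / 2)^beta` so that anticorrelated features end up
#' unconnected instead of strongly connected.
#'
#' @param expr features x samples numeric matrix, no missing values, at
#'   least 3 samples, no zero-variance feature.
#' @param power soft-thresholding exponent beta (>= 1).
#' @param network_type "unsigned" (default) or "signed".
#' @return symmetric features x features adjacency matrix in `[0, 1]` with
#'   unit diagonal.
#' @export
adjacency_from_expression <- function(expr, power, network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  if (length(power) != 1 || is.na(power) || power < 1)
    stop("power must be a single value >= 1 (did soft-threshold selection return NA?)")
  if (ncol(expr) < 3) stop("at least 3 samples are required")
  if (anyNA(expr)) stop("missing values present; filter first")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) stop("zero-variance feature(s): ",
                        paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  r <- stats::cor(t(expr))
  a <- if (network_type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Per-node connectivity of a weighted network
#'
#' @param adjacency symmetric adjacency matrix with unit diagonal.
#' @return vector `k` with `k_i = sum_{u != i} a_iu`.
#' @export
connectivity <- function(adjacency) {
  rowSums(adjacency) - diag(adjacency)
}

#' Signed scale-free topology fit index
#'
#' Bins the connectivity distribution into `n_bins` equal-width bins and
#' regresses `log10(p(k))` on `log10(mean k)` over the non-empty bins; a
#' scale-free network gives a straight decaying line. Returns
#' `sign(-slope) * R^2`, so the index is positive when the degree
#' distribution decays and negative when it grows.
#'
#' @param k per-node connectivities (only `k > 0` nodes are used).
#' @param n_bins number of equal-width bins; default 10.
#' @return signed R-squared in `[-1, 1]`; 0 (with a warning) when the
#'   connectivities are degenerate.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2 || max(k) == min(k)) {
    warning("degenerate connectivity distribution; returning fit index 0")
    return(0)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mean_k <- vapply(seq_len(n_bins), function(b) {
    if (counts[b] > 0) mean(k[as.integer(bin) == b]) else NA_real_
  }, numeric(1))
  ok <- counts > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 2) {
    warning("fewer than 2 usable connectivity bins; returning fit index 0")
    return(0)
  }
  freq <- counts[ok] / length(k)
  if (stats::var(log10(freq)) == 0) return(0)  # flat p(k): no decay signal
  fit <- stats::lm(log10(freq) ~ log10(mean_k[ok]))
  slope <- stats::coef(fit)[2]
  # a perfect log-log line triggers summary.lm's "essentially perfect fit"
  r2 <- suppressWarnings(summary(fit)$r.squared)
  unname(sign(-slope) * r2)
}

#' Choose a soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power, builds the per-layer adjacency, computes the
#' signed scale-free fit index and the mean connectivity, and records the
#' minimum fit index across layers. The chosen power is the smallest
#' candidate whose cross-layer minimum reaches `r2_cut`; `NA` when no
#' candidate qualifies (callers fall back to a configured default).
#'
#' @param expr_layers list of features x samples matrices sharing a feature
#'   set (e.g. transcript and protein layers).
#' @param powers candidate beta values; default `c(1:10, 12, 14, 16, 18, 20)`.
#' @param r2_cut minimum acceptable signed fit index; default 0.85.
#' @param network_type passed to [adjacency_from_expression()].
#' @param n_bins bins for [scale_free_fit()].
#' @return object of class `soft_threshold_report`: `powers`, `signed_r2`
#'   (powers x layers), `mean_connectivity` (powers x layers), `min_r2`,
#'   `chosen_power` (may be `NA`).
#' @export
pick_soft_threshold <- function(expr_layers, powers = c(1:10, 12, 14, 16, 18, 20),
                                r2_cut = 0.85,
                                network_type = c("unsigned", "signed"),
                                n_bins = 10) {
  network_type <- match.arg(network_type)
  if (length(powers) == 0) stop("empty candidate power list")
  if (!is.list(expr_layers)) expr_layers <- list(expr_layers)
  n_layers <- length(expr_layers)
  r2 <- matrix(NA_real_, length(powers), n_layers,
               dimnames = list(powers, names(expr_layers) %||% paste0("layer", seq_len(n_layers))))
  mk <- r2
  for (li in seq_len(n_layers)) {
    # correlations computed once per layer; powers only re-exponentiate
    base <- adjacency_from_expression(expr_layers[[li]], power = 1,
                                      network_type = network_type)
    for (pi in seq_along(powers)) {
      a <- base^powers[pi]
      diag(a) <- 1
      k <- connectivity(a)
      r2[pi, li] <- suppressWarnings(scale_free_fit(k, n_bins = n_bins))
      mk[pi, li] <- mean(k)
    }
  }
  min_r2 <- apply(r2, 1, min)
  qual <- which(min_r2 >= r2_cut)
  chosen <- if (length(qual) > 0) powers[min(qual)] else NA_real_
  structure(list(powers = powers, signed_r2 = r2, mean_connectivity = mk,
                 min_r2 = unname(min_r2), r2_cut = r2_cut,
                 chosen_power = chosen),
            class = "soft_threshold_report")
}

#' @export
print.soft_threshold_report <- function(x, ...) {
  cat("soft_threshold_report\n")
  print(data.frame(power = x$powers, min_signed_r2 = round(x$min_r2, 3),
                   mean_connectivity = round(rowMeans(x$mean_connectivity), 2)))
  cat(sprintf("chosen power (r2 >= %.2f): %s\n", x$r2_cut,
              ifelse(is.na(x$chosen_power), "none", x$chosen_power)))
  invisible(x)
}

#' Topological overlap matrix from an adjacency matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` counts shared neighborhood weight;
#' diagonal is 1. Two nodes overlap strongly when they are connected and
#' share the same neighbors, which is the dissimilarity basis for module
#' detection (`1 - TOM`).
#'
#' @param adjacency symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
tom_from_adjacency <- function(adjacency) {
  a <- adjacency
  k <- connectivity(a)
  # (A %*% A)_ij includes u = i and u = j: subtract a_ii*a_ij + a_ij*a_jj = 2 a_ij
  l <- a %*% a - 2 * a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Consensus topological overlap across layers
#'
#' Layers can differ in overall TOM scale (e.g. proteomic correlations run
#' weaker than transcriptomic ones), so each TOM after the first is first
#' calibrated by scaling it so that its off-diagonal `calibration_quantile`
#' quantile matches the reference (first) TOM's, capped at 1. The consensus
#' is then the element-wise minimum: an overlap only counts when both layers
#' support it.
#'
#' @param toms list of TOM matrices of identical shape; the first is the
#'   calibration reference.
#' @param calibration_quantile quantile used for scale matching; default
#'   0.95. Calibration is skipped (with a warning) when the reference
#'   quantile is zero.
#' @return consensus TOM with unit diagonal.
#' @export
consensus_tom <- function(toms, calibration_quantile = 0.95) {
  stopifnot(is.list(toms), length(toms) >= 1)
  dims <- lapply(toms, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all TOM matrices must have the same shape")
  q_ref <- stats::quantile(offdiag(toms[[1]]), calibration_quantile, names = FALSE)
  cons <- toms[[1]]
  for (t in toms[-1]) {
    q_t <- stats::quantile(offdiag(t), calibration_quantile, names = FALSE)
    if (q_ref <= 0 || q_t <= 0) {
      warning("calibration quantile is zero; skipping scale calibration")
    } else {
      t <- pmin(t * (q_ref / q_t), 1)
    }
    cons <- pmin(cons, t)
  }
  diag(cons) <- 1
  cons
}

# deep-split sensitivity -> fraction of the (max - q) height range at which
# the dendrogram is cut; smaller fraction = deeper cut = more, smaller clusters
deep_split_factor <- function(deep_split) {
  factors <- c(0.95, 0.90, 0.80, 0.70, 0.55)
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4")
  factors[deep_split + 1]
}

#' Detect modules by clustering a consensus dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - consensus TOM`. The
#' dendrogram is cut at a static height chosen adaptively: among all
#' candidate cut heights (midpoints between consecutive merge heights at or
#' above the 0.05 quantile `q`), those yielding the largest number of
#' clusters of size `min_module_size` or more form a plateau, and the
#' sensitivity factor `f(deep_split)` (0..4 mapping to
#' `0.95, 0.90, 0.80, 0.70, 0.55`) positions the cut within that plateau --
#' smaller factors cut lower, giving tighter module cores. Clusters smaller
#' than `min_module_size` are dissolved into label 0 (unassigned);
#' survivors are relabeled 1..m by decreasing size.
#'
#' @param dissimilarity square symmetric matrix (e.g. `1 - consensus_tom`),
#'   zero diagonal.
#' @param min_module_size smallest admissible module; default 30.
#' @param deep_split detection sensitivity in 0..4; default 2.
#' @return object of class `module_partition`: `labels` (named integer
#'   vector, 0 = unassigned), `module_ids`, `sizes`, `cut_height`.
#' @export
detect_modules <- function(dissimilarity, min_module_size = 30, deep_split = 2) {
  p <- nrow(dissimilarity)
  ids <- rownames(dissimilarity) %||% paste0("F", seq_len(p))
  if (p < min_module_size) {
    return(module_partition(stats::setNames(rep(0L, p), ids)))
  }
  hc <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  heights <- sort(unique(hc$height))
  q <- stats::quantile(hc$height, 0.05, names = FALSE)
  cand <- heights[heights >= q]
  cand <- (cand[-length(cand)] + cand[-1]) / 2  # midpoints between merges
  if (length(cand) == 0) cand <- max(hc$height) / 2
  n_mods <- vapply(cand, function(h) {
    sum(table(stats::cutree(hc, h = h)) >= min_module_size)
  }, numeric(1))
  if (max(n_mods) == 0) {
    return(module_partition(stats::setNames(rep(0L, p), ids)))
  }
  plateau <- cand[n_mods == max(n_mods)]
  f <- deep_split_factor(deep_split)
  h_star <- min(plateau) + f * (max(plateau) - min(plateau))
  raw <- stats::cutree(hc, h = h_star)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- ifelse(raw %in% keep, raw, 0L)
  names(labels) <- ids
  module_partition(relabel_by_size(labels), cut_height = h_star)
}

#' Assign unlabeled features to modules by module-membership correlation
#'
#' The kME rescue stage run after core module detection: the tight module
#' cores found by cutting the consensus dendrogram define per-layer
#' eigengenes, and every still-unassigned feature is measured against them
#' on the *stacked* standardized observations (transcript and protein
#' sample vectors concatenated, doubling the effective observation count
#' and averaging out single-layer estimation noise). A feature joins the
#' module with the highest absolute stacked eigengene correlation when that
#' correlation reaches `kme_threshold`; otherwise it stays unassigned.
#' Already-labeled features are never moved; eigengenes are recomputed
#' between rounds so late joiners can use the enlarged cores.
#'
#' @param data a [paired_omics()] (complete, nonzero variance).
#' @param partition a `module_partition` with at least one module.
#' @param kme_threshold minimum absolute stacked eigengene correlation for
#'   assignment; default 0.5.
#' @param rounds number of assign-and-recompute passes; default 2.
#' @return updated `module_partition` (relabeled by decreasing size).
#' @export
assign_unlabeled_features <- function(data, partition, kme_threshold = 0.5,
                                      rounds = 2) {
  stopifnot(inherits(data, "paired_omics"), inherits(partition, "module_partition"))
  if (length(partition$module_ids) == 0) return(partition)
  stacked <- cbind(t(scale(t(data$transcript))), t(scale(t(data$protein))))
  labels <- partition$labels
  for (r in seq_len(rounds)) {
    part <- module_partition(labels, cut_height = partition$cut_height)
    unassigned <- names(labels)[labels == 0]
    if (length(unassigned) == 0) break
    eg <- cbind(eigengene_matrix(data$transcript, part)$values,
                eigengene_matrix(data$protein, part)$values)
    kme <- abs(stats::cor(t(stacked[unassigned, , drop = FALSE]), t(eg)))
    best <- apply(kme, 1, which.max)
    best_val <- kme[cbind(seq_along(best), best)]
    join <- best_val >= kme_threshold
    if (!any(join)) break
    labels[unassigned[join]] <- part$module_ids[best[join]]
  }
  module_partition(relabel_by_size(labels), cut_height = partition$cut_height)
}

#' Construct / validate a module partition
#'
#' @param labels named nonnegative integer vector; 0 marks unassigned
#'   features.
#' @param cut_height optional dendrogram cut height used to produce it.
#' @return object of class `module_partition`.
#' @export
module_partition <- function(labels, cut_height = NA_real_) {
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (any(labels < 0)) stop("module labels must be nonnegative")
  ids <- sort(unique(labels[labels > 0]))
  sizes <- vapply(ids, function(m) sum(labels == m), integer(1))
  structure(list(labels = labels, module_ids = ids,
                 sizes = stats::setNames(sizes, ids),
                 cut_height = cut_height),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d features, %d modules (sizes %s), %d unassigned\n",
              length(x$labels), length(x$module_ids),
              paste(x$sizes, collapse = ", "), sum(x$labels == 0)))
  invisible(x)
}

# relabel nonzero modules 1..m by decreasing size (ties: lower old label first)
relabel_by_size <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  sizes <- vapply(ids, function(m) sum(labels == m), integer(1))
  ord <- ids[order(-sizes, ids)]
  map <- stats::setNames(seq_along(ord), ord)
  out <- labels
  nz <- labels > 0
  out[nz] <- map[as.character(labels[nz])]
  out
}

#' Module eigengene: first principal component of a module's expression
#'
#' Member features are standardized to zero mean and unit variance across
#' samples; the eigengene is the first right-singular vector of the
#' standardized features x samples matrix, i.e. the per-sample scores of the
#' leading principal component, scaled to unit Euclidean norm. Its sign is
#' aligned so that it correlates nonnegatively with the mean standardized
#' member profile, making eigengenes comparable across layers.
#'
#' @param expr features x samples matrix.
#' @param member_ids identifiers (or indices) of the module's features.
#' @return numeric vector of length `n_samples`, unit norm.
#' @export
module_eigengene <- function(expr, member_ids) {
  x <- expr[member_ids, , drop = FALSE]
  if (nrow(x) < 1) stop("module has no members")
  if (ncol(x) < 3) stop("at least 3 samples are required")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) stop("zero-variance member feature")
  xs <- t(scale(t(x)))  # standardize each feature across samples
  sv <- svd(xs)
  e <- sv$v[, 1]
  e <- e / sqrt(sum(e^2))
  mean_profile <- colMeans(xs)
  if (sum(e * (mean_profile - mean(mean_profile))) < 0) e <- -e
  stats::setNames(e, colnames(expr))
}

#' Eigengene matrix for all modules of a partition
#'
#' @param expr features x samples matrix for one layer.
#' @param partition a `module_partition` over the rows of `expr`.
#' @param layer optional layer tag stored on the result.
#' @return object of class `eigengene_matrix`: `values` (modules x samples,
#'   unit-norm rows), `module_ids`, `layer`.
#' @export
eigengene_matrix <- function(expr, partition, layer = "layer") {
  stopifnot(inherits(partition, "module_partition"))
  ids <- partition$module_ids
  if (length(ids) == 0) stop("partition has no modules")
  vals <- t(vapply(ids, function(m) {
    module_eigengene(expr, names(partition$labels)[partition$labels == m])
  }, numeric(ncol(expr))))
  rownames(vals) <- paste0("ME", ids)
  colnames(vals) <- colnames(expr)
  structure(list(values = vals, module_ids = ids, layer = layer),
            class = "eigengene_matrix")
}

#' Merge modules whose eigengenes are close in every layer
#'
#' The consensus dissimilarity between two modules is the maximum over
#' layers of `1 - cor(eigengene_p, eigengene_q)`. Modules are clustered by
#' average linkage on this dissimilarity and any group joined below
#' `cut_height` is merged; the procedure iterates until no merge occurs.
#' Labels are finally renumbered 1..m by decreasing size.
#'
#' @param expr_layers list of features x samples matrices (shared rows).
#' @param partition a `module_partition`.
#' @param cut_height eigengene-dissimilarity threshold for merging;
#'   default 0.25 (eigengene correlation above 0.75 in every layer).
#' @return merged `module_partition`.
#' @export
merge_close_modules <- function(expr_layers, partition, cut_height = 0.25) {
  stopifnot(inherits(partition, "module_partition"))
  if (!is.list(expr_layers)) expr_layers <- list(expr_layers)
  labels <- partition$labels
  repeat {
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids) < 2) break
    part <- module_partition(labels)
    diss <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (expr in expr_layers) {
      eg <- eigengene_matrix(expr, part)$values
      d <- 1 - stats::cor(t(eg))
      diss <- pmax(diss, d)
    }
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    groups <- stats::cutree(hc, h = cut_height)
    if (max(table(groups)) == 1) break
    remap <- stats::setNames(ids[match(groups, groups)], ids)  # first id of each group
    labels[labels > 0] <- remap[as.character(labels[labels > 0])]
  }
  module_partition(relabel_by_size(labels), cut_height = partition$cut_height)
}

#' Consensus module detection across two omics layers
#'
#' Convenience wrapper running the network stage end-to-end: per-layer
#' adjacency at the given power, per-layer TOM, quantile-calibrated
#' consensus TOM, module detection on `1 - consensus`, and eigengene-based
#' merging of close modules.
#'
#' @param data a filtered [paired_omics()] (complete, nonzero variance).
#' @param power soft-thresholding power.
#' @param network_type "unsigned" or "signed".
#' @param calibration_quantile see [consensus_tom()].
#' @param min_module_size,deep_split see [detect_modules()].
#' @param merge_cut_height see [merge_close_modules()].
#' @param kme_threshold see [assign_unlabeled_features()]; `NA` disables
#'   the rescue stage.
#' @return list with `partition` (`module_partition`), `consensus`
#'   (consensus TOM), `toms` (per-layer TOMs).
#' @export
consensus_modules <- function(data, power, network_type = "unsigned",
                              calibration_quantile = 0.95,
                              min_module_size = 30, deep_split = 2,
                              merge_cut_height = 0.25,
                              kme_threshold = 0.5) {
  stopifnot(inherits(data, "paired_omics"))
  layers <- list(transcript = data$transcript, protein = data$protein)
  toms <- lapply(layers, function(x)
    tom_from_adjacency(adjacency_from_expression(x, power, network_type)))
  cons <- consensus_tom(toms, calibration_quantile)
  part <- detect_modules(1 - cons, min_module_size, deep_split)
  if (length(part$module_ids) > 1)
    part <- merge_close_modules(layers, part, merge_cut_height)
  if (!is.na(kme_threshold) && length(part$module_ids) > 0)
    part <- assign_unlabeled_features(data, part, kme_threshold)
  list(partition = part, consensus = cons, toms = toms)
}

#' Write a module partition as TSV (feature_id, module)
#' @param partition a `module_partition`.
#' @param path output path.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(
    data.frame(feature_id = names(partition$labels),
               module = as.integer(partition$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a soft-threshold report as TSV
#' @param report a `soft_threshold_report`.
#' @param path output path.
#' @export
write_soft_threshold_tsv <- function(report, path) {
  df <- data.frame(power = report$powers,
                   report$signed_r2,
                   min_signed_r2 = report$min_r2,
                   report$mean_connectivity, check.names = FALSE)
  colnames(df) <- c("power",
                    paste0("signed_r2_", colnames(report$signed_r2)),
                    "min_signed_r2",
                    paste0("mean_connectivity_", colnames(report$mean_connectivity)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
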
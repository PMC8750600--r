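#' Eigengene network adjacency
#'
#' Inter-module relationships in one layer: `A_pq = (1 + cor(e_p, e_q)) / 2`,
#' mapping correlation -1, 0, 1 to adjacency 0, 0.5, 1.
#'
#' @param eig an [eigengene_matrix()].
#' @return object of class `eigengene_network`: `adjacency` (modules x
#'   modules, symmetric, unit diagonal), `module_ids`, `layer`.
#' @export
eigengene_adjacency <- function(eig) {
  stopifnot(inherits(eig, "eigengene_matrix"))
  if (ncol(eig$values) < 3) stop("at least 3 samples are required")
  v <- apply(eig$values, 1, stats::var)
  if (any(v == 0)) stop("zero-variance eigengene")
  a <- (1 + stats::cor(t(eig$values))) / 2
  diag(a) <- 1
  structure(list(adjacency = a, module_ids = eig$module_ids, layer = eig$layer),
            class = "eigengene_network")
}

#' Cross-layer preservation of two eigengene networks
#'
#' `P_pq = 1 - |A_pq - B_pq|`: 1 where the two layers agree exactly on the
#' inter-module adjacency, smaller where they diverge.
#'
#' @param net_a,net_b `eigengene_network`s over the same module set and
#'   order.
#' @return modules x modules preservation matrix in `[0, 1]`.
#' @export
preservation_network <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "eigengene_network"),
            inherits(net_b, "eigengene_network"))
  if (!identical(net_a$module_ids, net_b$module_ids))
    stop("networks cover different module sets")
  1 - abs(net_a$adjacency - net_b$adjacency)
}

#' Mean preservation per module
#'
#' Column means of the preservation matrix, excluding the diagonal entry:
#' the average preservation of a module's adjacency to all other modules.
#'
#' @param pres square preservation matrix.
#' @return named numeric vector, one mean per module.
#' @export
mean_preservation <- function(pres) {
  p <- nrow(pres)
  if (p < 2) stop("at least 2 modules are required")
  out <- vapply(seq_len(p), function(j) mean(pres[-j, j]), numeric(1))
  stats::setNames(out, colnames(pres))
}

#' Per-module z-score expression profiles
#'
#' Every feature is z-scored across samples (zero-variance features get an
#' all-zero row); a module's profile is the per-sample mean of its members'
#' z rows. Used for trend-line plots of module behavior across tissues or
#' developmental stages.
#'
#' @param expr features x samples matrix, no missing values.
#' @param partition a `module_partition` over the rows of `expr`.
#' @return modules x samples matrix of mean z-scores.
#' @export
module_zscore_profiles <- function(expr, partition) {
  stopifnot(inherits(partition, "module_partition"))
  if (anyNA(expr)) stop("missing values present")
  ids <- partition$module_ids
  if (length(ids) == 0) stop("partition has no modules")
  z <- t(apply(expr, 1, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  prof <- t(vapply(ids, function(m) {
    members <- names(partition$labels)[partition$labels == m]
    if (length(members) == 0) stop("empty module ", m)
    colMeans(z[members, , drop = FALSE])
  }, numeric(ncol(expr))))
  dimnames(prof) <- list(paste0("ME", ids), colnames(expr))
  prof
}

#' Hierarchical clustering of eigengenes over tissues
#'
#' Complete-linkage clustering of module eigengene rows under Euclidean
#' distance, as used to order module rows in tissue-by-module heatmaps;
#' samples (columns) are never reordered.
#'
#' @param eig an [eigengene_matrix()] with at least 2 modules.
#' @return list with `order` (module row names in dendrogram leaf order)
#'   and `hclust` (the merge tree).
#' @export
eigengene_tissue_clustering <- function(eig) {
  stopifnot(inherits(eig, "eigengene_matrix"))
  if (nrow(eig$values) < 2) stop("at least 2 modules are required")
  hc <- stats::hclust(stats::dist(eig$values, method = "euclidean"),
                      method = "complete")
  list(order = rownames(eig$values)[hc$order], hclust = hc)
}

#' Write an eigengene matrix as TSV
#' @param eig an `eigengene_matrix`.
#' @param path output path.
#' @export
write_eigengene_tsv <- function(eig, path) {
  write_omics_tsv(eig$values, path, id_column = "module")
  invisible(path)
}

#' Write a square module x module matrix (adjacency / preservation) as TSV
#' @param m square matrix with dimnames.
#' @param path output path.
#' @export
write_module_matrix_tsv <- function(m, path) {
  write_omics_tsv(m, path, id_column = "module")
  invisible(path)
}

#' Heatmap helper for module matrices
#'
#' Thin optional wrapper around [pheatmap::pheatmap] semantics using base
#' graphics (`image`), writing a PNG. All plotted quantities are emitted as
#' TSV by the writers above, so downstream consumers never parse images.
#'
#' @param m square numeric matrix.
#' @param path output PNG path.
#' @param main plot title.
#' @export
plot_module_heatmap <- function(m, path, main = "") {
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  invisible(path)
}
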
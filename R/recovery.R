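#' Adjusted Rand index between two feature partitions
#'
#' Chance-corrected agreement between the detected module labels and a
#' reference labeling (e.g. planted truth). Label names are matched by
#' feature identifier when both vectors are named; otherwise positionally.
#'
#' @param labels_a,labels_b integer label vectors (0 allowed as a class).
#' @return ARI in `[-1, 1]`; 1 = identical partitions up to renaming.
#' @export
module_recovery_ari <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (length(common) == 0) stop("no shared feature identifiers")
    labels_a <- labels_a[common]
    labels_b <- labels_b[common]
  }
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' SHD between an estimated CPDAG and the CPDAG of a true DAG
#'
#' @param estimated a [cpdag()].
#' @param truth_dag a [dag()]; its Markov equivalence class CPDAG is the
#'   comparison target.
#' @return nonnegative integer.
#' @export
shd_to_truth <- function(estimated, truth_dag) {
  structural_hamming_distance(estimated, dag_to_cpdag(truth_dag))
}
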
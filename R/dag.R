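#' Construct a weighted directed acyclic graph
#'
#' A `dag` stores an ordered node set, a directed edge list and one real
#' coefficient per edge. It is the ground-truth causal structure used by the
#' structural equation model simulator and the recovery metrics.
#'
#' @param nodes character vector of unique node identifiers.
#' @param edges data frame with columns `parent`, `child` and `weight`
#'   (numeric); may have zero rows.
#' @return object of class `dag`.
#' @export
dag <- function(nodes, edges = data.frame(parent = character(), child = character(),
                                          weight = numeric())) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    edges$parent <- as.character(edges$parent)
    edges$child <- as.character(edges$child)
    edges$weight <- as.numeric(edges$weight)
    if (!all(edges$parent %in% nodes) || !all(edges$child %in% nodes))
      stop("edge endpoint not in node set")
    if (any(edges$parent == edges$child)) stop("self-loop not allowed")
    if (anyDuplicated(edges[c("parent", "child")])) stop("duplicate edge")
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "dag")
  if (is.null(topological_order(g))) stop("edge set contains a cycle")
  g
}

#' @export
print.dag <- function(x, ...) {
  cat(sprintf("dag: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Weighted adjacency matrix of a DAG
#'
#' @param g a `dag`.
#' @return square numeric matrix `W` with `W[parent, child]` equal to the
#'   edge weight and 0 elsewhere, rows/columns in node order.
#' @export
dag_weight_matrix <- function(g) {
  p <- length(g$nodes)
  W <- matrix(0, p, p, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0)
    W[cbind(g$edges$parent, g$edges$child)] <- g$edges$weight
  W
}

#' Topological order of a DAG
#'
#' Kahn's algorithm. Returns `NULL` when the edge set contains a cycle,
#' which callers use as the acyclicity check.
#'
#' @param g a `dag` (or a list with `nodes` and an `edges` data frame).
#' @return character vector of nodes in topological order, or `NULL`.
#' @export
topological_order <- function(g) {
  nodes <- g$nodes
  edges <- g$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges) > 0) {
    tab <- table(edges$child)
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  avail <- nodes[indeg == 0]
  indeg <- indeg
  remaining <- edges
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    if (nrow(remaining) > 0) {
      kids <- remaining$child[remaining$parent == v]
      remaining <- remaining[remaining$parent != v, , drop = FALSE]
      for (k in kids) {
        indeg[k] <- indeg[k] - 1L
        if (indeg[k] == 0L) avail <- c(avail, k)
      }
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' Sample a random weighted DAG
#'
#' Draws a uniformly random node order and includes each forward pair as an
#' edge independently with probability `edge_prob`. Weights are uniform on
#' `[0.5, 1.5]` in magnitude with random sign; bounding the magnitude away
#' from zero keeps planted effects detectable (near-zero coefficients would
#' approach unfaithful distributions).
#'
#' @param n_nodes number of nodes (positive).
#' @param edge_prob probability of each forward pair being an edge.
#' @param seed integer seed; the same seed reproduces the same DAG.
#' @return a `dag` with nodes `M1 ... M<n_nodes>`.
#' @export
random_dag <- function(n_nodes, edge_prob, seed) {
  if (n_nodes < 1) stop("n_nodes must be positive")
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  nodes <- paste0("M", seq_len(n_nodes))
  ord <- sample(nodes)
  parent <- character(0); child <- character(0)
  if (n_nodes >= 2) {
    for (i in seq_len(n_nodes - 1)) {
      for (j in seq(i + 1, n_nodes)) {
        if (stats::runif(1) < edge_prob) {
          parent <- c(parent, ord[i])
          child <- c(child, ord[j])
        }
      }
    }
  }
  n_e <- length(parent)
  weight <- if (n_e > 0) stats::runif(n_e, 0.5, 1.5) * sample(c(-1, 1), n_e, replace = TRUE)
            else numeric(0)
  dag(nodes, data.frame(parent = parent, child = child, weight = weight,
                        stringsAsFactors = FALSE))
}

#' Simulate observations from a linear Gaussian structural equation model
#'
#' Each node equals the weighted sum of its parents plus independent
#' Gaussian noise, evaluated in topological order, so the joint
#' distribution is Markov and faithful to the DAG for generic weights.
#'
#' @param g a `dag`.
#' @param n_samples number of observations (at least 2).
#' @param noise_sd standard deviation of every node's noise term.
#' @param seed integer seed.
#' @return numeric matrix, `n_samples` rows by `length(g$nodes)` columns,
#'   columns in `g$nodes` order.
#' @export
simulate_sem <- function(g, n_samples, noise_sd = 1, seed = 1) {
  stopifnot(inherits(g, "dag"))
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  ord <- topological_order(g)
  if (is.null(ord)) stop("input graph is cyclic")
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  W <- dag_weight_matrix(g)
  X <- matrix(0, n_samples, length(g$nodes), dimnames = list(NULL, g$nodes))
  for (v in ord) {
    parents <- g$nodes[W[, v] != 0]
    eps <- stats::rnorm(n_samples, 0, noise_sd)
    X[, v] <- if (length(parents) > 0)
      X[, parents, drop = FALSE] %*% W[parents, v] + eps else eps
  }
  X
}

#' Analytic covariance of the linear Gaussian SEM
#'
#' With weight matrix `W` (`W[parent, child]`) and i.i.d. noise variance
#' `noise_sd^2`, the stationary solution is `x = (I - W')^{-1} e`, so
#' `Cov(x) = (I - W')^{-1} sigma^2 I (I - W')^{-T}`.
#'
#' @inheritParams simulate_sem
#' @return covariance matrix in node order.
#' @export
sem_covariance <- function(g, noise_sd = 1) {
  W <- dag_weight_matrix(g)
  p <- nrow(W)
  A <- solve(diag(p) - t(W))
  S <- noise_sd^2 * A %*% t(A)
  dimnames(S) <- dimnames(W)
  S
}

#' Write a DAG edge list as TSV
#'
#' Columns: parent, child, weight. Isolated nodes do not appear in the edge
#' list, so [read_dag_tsv()] takes the node set explicitly.
#'
#' @param g a `dag`.
#' @param path output file path.
#' @export
write_dag_tsv <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DAG edge list written by [write_dag_tsv()]
#'
#' @param path TSV with columns parent, child, weight.
#' @param nodes full node set (edges alone may omit isolated nodes).
#' @return a `dag`.
#' @export
read_dag_tsv <- function(path, nodes) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  dag(nodes, e)
}
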
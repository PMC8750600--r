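#' Construct a completed partially directed acyclic graph (CPDAG)
#'
#' The output type of PC-style structure learning: directed edges are
#' oriented the same way in every DAG of the Markov equivalence class;
#' undirected edges flip direction between members of the class (the
#' "bidirected" edges of equivalence-class terminology).
#'
#' @param nodes character vector of node identifiers.
#' @param directed_edges data frame with columns `from`, `to` (may be empty).
#' @param undirected_edges data frame with columns `a`, `b` (may be empty);
#'   stored with `a < b` canonically.
#' @return object of class `cpdag`.
#' @export
cpdag <- function(nodes,
                  directed_edges = data.frame(from = character(), to = character()),
                  undirected_edges = data.frame(a = character(), b = character())) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  de <- as.data.frame(directed_edges)
  ue <- as.data.frame(undirected_edges)
  if (nrow(de) > 0) {
    de$from <- as.character(de$from); de$to <- as.character(de$to)
    if (any(de$from == de$to)) stop("self-loop in directed edges")
    if (!all(c(de$from, de$to) %in% nodes)) stop("directed edge endpoint not a node")
  }
  if (nrow(ue) > 0) {
    ue$a <- as.character(ue$a); ue$b <- as.character(ue$b)
    if (any(ue$a == ue$b)) stop("self-loop in undirected edges")
    if (!all(c(ue$a, ue$b) %in% nodes)) stop("undirected edge endpoint not a node")
    swap <- ue$a > ue$b
    tmp <- ue$a[swap]; ue$a[swap] <- ue$b[swap]; ue$b[swap] <- tmp
  }
  key_d <- if (nrow(de) > 0) paste(pmin(de$from, de$to), pmax(de$from, de$to)) else character(0)
  key_u <- if (nrow(ue) > 0) paste(ue$a, ue$b) else character(0)
  if (anyDuplicated(c(key_d, key_u)))
    stop("a node pair appears more than once across the edge sets")
  structure(list(nodes = nodes, directed_edges = de, undirected_edges = ue),
            class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  cat(sprintf("cpdag: %d nodes, %d directed, %d undirected edges\n",
              length(x$nodes), nrow(x$directed_edges), nrow(x$undirected_edges)))
  invisible(x)
}

# partially-directed adjacency matrix: m[i,j]=1 & m[j,i]=0 means i -> j;
# both 1 means undirected; both 0 means no edge
cpdag_to_amat <- function(g) {
  p <- length(g$nodes)
  m <- matrix(0L, p, p, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$directed_edges) > 0)
    m[cbind(g$directed_edges$from, g$directed_edges$to)] <- 1L
  if (nrow(g$undirected_edges) > 0) {
    m[cbind(g$undirected_edges$a, g$undirected_edges$b)] <- 1L
    m[cbind(g$undirected_edges$b, g$undirected_edges$a)] <- 1L
  }
  m
}

amat_to_cpdag <- function(m) {
  nodes <- rownames(m)
  from <- character(0); to <- character(0); ua <- character(0); ub <- character(0)
  p <- nrow(m)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j || m[i, j] == 0) next
    if (m[j, i] == 0) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
    } else if (i < j) {
      ua <- c(ua, nodes[i]); ub <- c(ub, nodes[j])
    }
  }
  cpdag(nodes, data.frame(from = from, to = to, stringsAsFactors = FALSE),
        data.frame(a = ua, b = ub, stringsAsFactors = FALSE))
}

#' Structural Hamming distance between two CPDAGs
#'
#' Each unordered node pair has a status in one of four states: absent,
#' undirected, directed i to j, directed j to i. The SHD is the number of
#' pairs whose status differs between the graphs; any mismatch counts one.
#'
#' @param g1,g2 `cpdag`s over the same node set.
#' @return nonnegative integer.
#' @export
structural_hamming_distance <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes)) stop("graphs have different node sets")
  m1 <- cpdag_to_amat(g1)
  m2 <- cpdag_to_amat(g2)[g1$nodes, g1$nodes]
  p <- length(g1$nodes)
  d <- 0L
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    s1 <- c(m1[i, j], m1[j, i]); s2 <- c(m2[i, j], m2[j, i])
    if (!identical(s1, s2)) d <- d + 1L
  }
  d
}

#' Summary counts for a CPDAG
#'
#' Reports the number of directed and undirected edges, the number of
#' connected subgraphs with at least two nodes (edge direction ignored),
#' and the "effect-only" nodes: nodes with at least one incoming directed
#' edge, no outgoing directed edge, and no undirected incidences -- pure
#' sinks of the causal structure.
#'
#' @param g a `cpdag`.
#' @return list of class `cpdag_summary` with `n_directed`, `n_undirected`,
#'   `n_connected_subgraphs`, `effect_only_nodes`.
#' @export
summarize_cpdag <- function(g) {
  stopifnot(inherits(g, "cpdag"))
  m <- cpdag_to_amat(g)
  und <- (m + t(m)) > 0
  ig <- igraph::graph_from_adjacency_matrix(und * 1, mode = "undirected")
  comp <- igraph::components(ig)
  n_sub <- sum(comp$csize >= 2)
  has_in <- colSums(m == 1 & t(m) == 0) > 0
  has_out <- rowSums(m == 1 & t(m) == 0) > 0
  has_und <- rowSums(m == 1 & t(m) == 1) > 0
  eff <- g$nodes[has_in & !has_out & !has_und]
  structure(list(n_directed = nrow(g$directed_edges),
                 n_undirected = nrow(g$undirected_edges),
                 n_connected_subgraphs = n_sub,
                 effect_only_nodes = eff),
            class = "cpdag_summary")
}

#' @export
print.cpdag_summary <- function(x, ...) {
  cat(sprintf("cpdag_summary: %d directed, %d undirected edges, %d subgraphs; effect-only: %s\n",
              x$n_directed, x$n_undirected, x$n_connected_subgraphs,
              if (length(x$effect_only_nodes) == 0) "none"
              else paste(x$effect_only_nodes, collapse = ", ")))
  invisible(x)
}

#' Write a CPDAG as an edge-list TSV
#'
#' Columns: source, target, type (`directed` / `undirected`).
#'
#' @param g a `cpdag`.
#' @param path output path.
#' @export
write_cpdag_tsv <- function(g, path) {
  de <- g$directed_edges
  ue <- g$undirected_edges
  df <- data.frame(
    source = c(de$from, ue$a),
    target = c(de$to, ue$b),
    type = c(rep("directed", nrow(de)), rep("undirected", nrow(ue))),
    stringsAsFactors = FALSE)
  df <- df[order(df$type, df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CPDAG edge-list TSV written by [write_cpdag_tsv()]
#' @param path TSV path.
#' @param nodes full node set.
#' @return a `cpdag`.
#' @export
read_cpdag_tsv <- function(path, nodes) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  de <- df[df$type == "directed", , drop = FALSE]
  ue <- df[df$type == "undirected", , drop = FALSE]
  cpdag(nodes,
        data.frame(from = de$source, to = de$target, stringsAsFactors = FALSE),
        data.frame(a = ue$source, b = ue$target, stringsAsFactors = FALSE))
}

#' Serialize a CPDAG to DOT for rendering
#'
#' Directed edges become arrows, undirected edges plain lines.
#'
#' @param g a `cpdag`.
#' @param path output `.dot` path.
#' @export
write_cpdag_dot <- function(g, path) {
  lines <- c("digraph cpdag {")
  lines <- c(lines, sprintf("  \"%s\";", g$nodes))
  if (nrow(g$directed_edges) > 0)
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                              g$directed_edges$from, g$directed_edges$to))
  if (nrow(g$undirected_edges) > 0)
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [dir=none];",
                              g$undirected_edges$a, g$undirected_edges$b))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
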
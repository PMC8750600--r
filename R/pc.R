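#' Sufficient statistic for Gaussian conditional-independence testing
#'
#' The PC algorithm on continuous variables only needs the Pearson
#' correlation matrix of the variables and the number of observations it
#' was computed from.
#'
#' @param correlation symmetric correlation matrix with unit diagonal.
#' @param n sample size (positive integer).
#' @return object of class `ci_suff_stat`.
#' @export
ci_suff_stat <- function(correlation, n) {
  correlation <- as.matrix(correlation)
  if (nrow(correlation) != ncol(correlation)) stop("correlation must be square")
  if (max(abs(correlation - t(correlation))) > 1e-8) stop("correlation must be symmetric")
  if (any(abs(correlation) > 1 + 1e-8)) stop("correlation entries must be in [-1, 1]")
  if (max(abs(diag(correlation) - 1)) > 1e-8) stop("correlation must have unit diagonal")
  if (n < 1) stop("n must be positive")
  if (is.null(rownames(correlation)))
    dimnames(correlation) <- list(paste0("V", seq_len(nrow(correlation))),
                                  paste0("V", seq_len(nrow(correlation))))
  structure(list(correlation = correlation, n = as.integer(n)),
            class = "ci_suff_stat")
}

#' Sufficient statistic from an observation matrix
#' @param x samples x variables matrix.
#' @return a [ci_suff_stat()].
#' @export
ci_suff_stat_from_data <- function(x) {
  ci_suff_stat(stats::cor(x), nrow(x))
}

#' Partial correlation from a correlation matrix
#'
#' The partial Pearson correlation of variables `i` and `j` given the set
#' `S`, from the inverse of the sub-correlation-matrix on `{i, j} union S`:
#' `rho = -Omega_ij / sqrt(Omega_ii * Omega_jj)`. The result is clamped to
#' `[-1 + eps, 1 - eps]` so the Fisher transform stays finite.
#'
#' @param suff a `ci_suff_stat`.
#' @param i,j variable names or indices, distinct, not in `S`.
#' @param S conditioning set (possibly empty).
#' @param eps clamp margin; default `1e-12`.
#' @return partial correlation in `(-1, 1)`.
#' @export
partial_correlation <- function(suff, i, j, S = character(0), eps = 1e-12) {
  C <- suff$correlation
  nm <- rownames(C)
  ii <- if (is.character(i)) i else nm[i]
  jj <- if (is.character(j)) j else nm[j]
  SS <- if (length(S) == 0) character(0) else if (is.character(S)) S else nm[S]
  if (ii == jj) stop("i and j must differ")
  if (ii %in% SS || jj %in% SS) stop("i and j must not be in the conditioning set")
  idx <- c(ii, jj, SS)
  sub <- C[idx, idx, drop = FALSE]
  Om <- tryCatch(solve(sub), error = function(e)
    stop(sprintf("singular correlation sub-matrix on {%s}", paste(idx, collapse = ", "))))
  rho <- -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
  max(min(rho, 1 - eps), -1 + eps)
}

#' Fisher-z test of zero partial correlation
#'
#' `z = 0.5 log((1 + rho) / (1 - rho))`; under conditional independence,
#' `T = sqrt(n - |S| - 3) * |z|` is approximately standard normal, giving a
#' two-sided p-value `2 * (1 - Phi(T))`. The pair is declared independent
#' when `p > alpha`. Requires `n - |S| - 3 >= 1`.
#'
#' @inheritParams partial_correlation
#' @param alpha significance level; default 0.05.
#' @return list of class `ci_test_result`: `partial_correlation`,
#'   `fisher_z`, `statistic`, `p_value`, `independent`.
#' @export
fisher_z_test <- function(suff, i, j, S = character(0), alpha = 0.05) {
  df <- suff$n - length(S) - 3
  if (df < 1)
    stop(sprintf("Fisher-z test undefined: n - |S| - 3 = %d < 1", df))
  rho <- partial_correlation(suff, i, j, S)
  z <- 0.5 * log((1 + rho) / (1 - rho))
  stat <- sqrt(df) * abs(z)
  p <- 2 * stats::pnorm(-stat)
  structure(list(partial_correlation = rho, fisher_z = z, statistic = stat,
                 p_value = p, independent = p > alpha),
            class = "ci_test_result")
}

# generic order-independent ("stable") skeleton search over an arbitrary
# conditional-independence test function: test(i, j, S) -> TRUE when
# independent. Adjacency sets are snapshotted at the start of each level so
# the result does not depend on the order edges are visited within a level.
pc_skeleton_generic <- function(nodes, test, max_cond_size = Inf) {
  p <- length(nodes)
  adj <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  sepsets <- list()
  sep_key <- function(a, b) paste(min(a, b), max(a, b), sep = "\r")
  l <- 0L
  repeat {
    snapshot <- adj
    nbr_counts <- rowSums(snapshot)
    if (all(nbr_counts - 1 < l)) break
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i == j || !adj[i, j]) next
        nbrs <- which(snapshot[i, ])
        nbrs <- setdiff(nbrs, j)
        if (length(nbrs) < l) next
        # combn(x, m) interprets scalar x as seq_len(x); guard against it
        subsets <- if (l == 0L) list(integer(0))
                   else if (length(nbrs) == l) list(sort(nbrs))
                   else utils::combn(sort(nbrs), l, simplify = FALSE)
        for (S in subsets) {
          if (test(nodes[i], nodes[j], nodes[S])) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepsets[[sep_key(nodes[i], nodes[j])]] <- nodes[S]
            break
          }
        }
        if (!adj[i, j]) next
      }
    }
    l <- l + 1L
    if (l > max_cond_size) break
  }
  # every non-adjacent pair needs a sepset entry for orientation; pairs never
  # separated (e.g. search stopped at max_cond_size) keep no entry
  list(adjacency = adj, sepsets = sepsets, max_level = l - 1L)
}

#' PC skeleton search with Fisher-z tests
#'
#' Order-independent ("stable") variant: at each conditioning level the
#' adjacency sets are snapshotted, and for every ordered adjacent pair
#' `(i, j)` all subsets of the snapshot neighborhood of `i` (minus `j`) of
#' that size are tested in lexicographic order; the first independence
#' removes the edge and records the separating set.
#'
#' @param suff a `ci_suff_stat`.
#' @param alpha significance level in (0, 1).
#' @param max_cond_size cap on the conditioning-set size; default
#'   `suff$n - 5`, which keeps the Fisher-z requirement
#'   `n - |S| - 3 >= 1` satisfied with room to spare at small sample sizes.
#' @return list with `adjacency` (logical symmetric matrix), `sepsets`
#'   (named list keyed by node pair), `max_level`.
#' @export
pc_skeleton <- function(suff, alpha = 0.05, max_cond_size = NULL) {
  stopifnot(inherits(suff, "ci_suff_stat"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(max_cond_size)) max_cond_size <- max(0L, suff$n - 5L)
  nodes <- rownames(suff$correlation)
  test <- function(i, j, S) fisher_z_test(suff, i, j, S, alpha)$independent
  pc_skeleton_generic(nodes, test, max_cond_size)
}

# sepset lookup helper shared by orientation code
get_sepset <- function(sepsets, a, b) {
  sepsets[[paste(min(a, b), max(a, b), sep = "\r")]]
}

#' Orient v-structures on a skeleton
#'
#' For every unshielded triple `x - y - z` (x, z non-adjacent), orient
#' `x -> y <- z` exactly when `y` is not in the recorded separating set of
#' `(x, z)`. Triples are processed in sorted order; a later triple may
#' overwrite an earlier orientation (the conflict count is reported via a
#' warning).
#'
#' @param skeleton output of [pc_skeleton()] (or the generic search).
#' @return partially-directed adjacency matrix (see `cpdag_to_amat`
#'   conventions): entry `[i, j] = 1, [j, i] = 0` means `i -> j`.
#' @export
orient_v_structures <- function(skeleton) {
  adj <- skeleton$adjacency
  sepsets <- skeleton$sepsets
  nodes <- rownames(adj)
  p <- length(nodes)
  g <- matrix(as.integer(adj), p, p, dimnames = dimnames(adj))
  conflicts <- 0L
  for (y in seq_len(p)) {
    nb <- which(adj[y, ])
    if (length(nb) < 2) next
    for (x in nb) for (z in nb) {
      if (x >= z || adj[x, z]) next
      ss <- get_sepset(sepsets, nodes[x], nodes[z])
      if (is.null(ss)) next  # pair never separated (conditioning cap hit)
      if (!(nodes[y] %in% ss)) {
        # orient x -> y <- z; overwriting a previous head-tail is a conflict
        if ((g[y, x] == 1 && g[x, y] == 0) || (g[y, z] == 1 && g[z, y] == 0))
          conflicts <- conflicts + 1L
        g[x, y] <- 1L; g[y, x] <- 0L
        g[z, y] <- 1L; g[y, z] <- 0L
      }
    }
  }
  if (conflicts > 0)
    warning(sprintf("%d conflicting v-structure orientation(s); last writer wins", conflicts))
  g
}

#' Apply Meek's orientation rules until fixpoint
#'
#' Completes a partially directed graph to the CPDAG of its equivalence
#' class. Rules (a, b, c, d range over nodes; `-` undirected, `->` directed):
#' R1: `a -> b`, `b - c`, a and c non-adjacent, then `b -> c`.
#' R2: `a -> b -> c` with `a - c`, then `a -> c`.
#' R3: `a - b`, `a - c`, `a - d`, `c -> b`, `d -> b`, c and d non-adjacent,
#' then `a -> b`.
#' R4: `a - b`, `a - c`, `c -> d`, `d -> b`, b and c non-adjacent, then
#' `a -> b` (only reachable with background knowledge; included for
#' completeness).
#'
#' @param pdag partially-directed adjacency matrix from
#'   [orient_v_structures()].
#' @return a [cpdag()].
#' @export
apply_meek_rules <- function(pdag) {
  g <- pdag
  p <- nrow(g)
  directed <- function(i, j) g[i, j] == 1 && g[j, i] == 0
  undirected <- function(i, j) g[i, j] == 1 && g[j, i] == 1
  adjacent <- function(i, j) g[i, j] == 1 || g[j, i] == 1
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (a == b || !undirected(a, b)) next
      orient <- FALSE
      for (c in seq_len(p)) {
        if (c == a || c == b) next
        # R1: c -> a, a - b, c and b non-adjacent  =>  a -> b
        if (directed(c, a) && !adjacent(c, b)) { orient <- TRUE; break }
        # R2: a -> c -> b with a - b  =>  a -> b
        if (directed(a, c) && directed(c, b)) { orient <- TRUE; break }
      }
      if (!orient) {
        for (c in seq_len(p)) {
          if (orient || c == a || c == b) next
          for (d in seq_len(p)) {
            if (d == a || d == b || d == c) next
            # R3: a - c, a - d, c -> b, d -> b, c and d non-adjacent
            if (undirected(a, c) && undirected(a, d) &&
                directed(c, b) && directed(d, b) && !adjacent(c, d)) {
              orient <- TRUE; break
            }
            # R4: a - c, c -> d, d -> b, b and c non-adjacent
            if (undirected(a, c) && directed(c, d) && directed(d, b) &&
                !adjacent(b, c)) {
              orient <- TRUE; break
            }
          }
        }
      }
      if (orient) {
        g[a, b] <- 1L; g[b, a] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  amat_to_cpdag(g)
}

#' Estimate a CPDAG with the PC algorithm
#'
#' Composition of the stable skeleton search, v-structure orientation and
#' Meek completion. Deterministic given the sufficient statistic and
#' `alpha`.
#'
#' @inheritParams pc_skeleton
#' @return a [cpdag()].
#' @export
pc <- function(suff, alpha = 0.05, max_cond_size = NULL) {
  sk <- pc_skeleton(suff, alpha, max_cond_size)
  apply_meek_rules(orient_v_structures(sk))
}

#' PC with an arbitrary conditional-independence test
#'
#' Runs the identical skeleton / orientation / completion machinery with a
#' caller-supplied test function, e.g. the d-separation oracle, bypassing
#' the Gaussian sufficient statistic.
#'
#' @param nodes node identifiers.
#' @param test function `(i, j, S) -> logical`, `TRUE` when independent.
#' @param max_cond_size conditioning cap; default unlimited.
#' @return a [cpdag()].
#' @export
pc_with_test <- function(nodes, test, max_cond_size = Inf) {
  sk <- pc_skeleton_generic(nodes, test, max_cond_size)
  apply_meek_rules(orient_v_structures(sk))
}

#' d-separation oracle for a DAG
#'
#' Returns a conditional-independence test function that declares `i` and
#' `j` independent given `S` exactly when they are d-separated by `S` in
#' the DAG, via the ancestral-moralization criterion: restrict to ancestors
#' of `{i, j} union S`, marry parents of common children, drop directions,
#' delete `S`, and check whether `i` and `j` are disconnected.
#'
#' @param g a [dag()].
#' @return function `(i, j, S) -> logical` usable with [pc_with_test()].
#' @export
d_separation_oracle <- function(g) {
  nodes <- g$nodes
  W <- dag_weight_matrix(g) != 0  # W[parent, child]
  function(i, j, S = character(0)) {
    target <- unique(c(i, j, S))
    # ancestors of the target set (including itself)
    anc <- target
    repeat {
      parents <- nodes[rowSums(W[, anc, drop = FALSE]) > 0]
      new <- setdiff(parents, anc)
      if (length(new) == 0) break
      anc <- c(anc, new)
    }
    sub <- W[anc, anc, drop = FALSE]
    # moralize: undirected skeleton + marriages between co-parents
    m <- sub | t(sub)
    for (child in seq_along(anc)) {
      pa <- which(sub[, child])
      if (length(pa) >= 2)
        for (u in pa) for (v in pa) if (u != v) m[u, v] <- TRUE
    }
    # remove the conditioning set, test connectivity of i and j
    keep <- setdiff(anc, S)
    if (!(i %in% keep) || !(j %in% keep)) return(TRUE)
    m <- m[keep, keep, drop = FALSE]
    reach <- c(i)
    repeat {
      nb <- keep[colSums(m[reach, , drop = FALSE]) > 0]
      new <- setdiff(nb, reach)
      if (length(new) == 0) break
      reach <- c(reach, new)
    }
    !(j %in% reach)
  }
}

#' CPDAG of a DAG's Markov equivalence class
#'
#' Keeps the DAG's skeleton, directs exactly the edges participating in
#' v-structures, and closes under Meek's rules. Consistent with running
#' [pc_with_test()] under the [d_separation_oracle()] of the same DAG.
#'
#' @param g a [dag()].
#' @return a [cpdag()].
#' @export
dag_to_cpdag <- function(g) {
  nodes <- g$nodes
  p <- length(nodes)
  W <- dag_weight_matrix(g) != 0
  adj <- W | t(W)
  # start all-undirected, then pin v-structure arrows
  m <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  m[adj] <- 1L
  for (y in seq_len(p)) {
    pa <- which(W[, y])
    if (length(pa) < 2) next
    for (x in pa) for (z in pa) {
      if (x >= z || adj[x, z]) next
      m[x, y] <- 1L; m[y, x] <- 0L
      m[z, y] <- 1L; m[y, z] <- 0L
    }
  }
  apply_meek_rules(m)
}

#' Enumerate all labeled DAGs on a small node set
#'
#' Iterates over every subset of ordered node pairs and keeps the acyclic
#' ones. Sizes grow super-exponentially; intended for n <= 4 (25 DAGs on 3
#' nodes, 543 on 4).
#'
#' @param nodes character vector of node identifiers (at most 5).
#' @return list of [dag()]s with unit edge weights.
#' @export
enumerate_dags <- function(nodes) {
  p <- length(nodes)
  if (p > 5) stop("enumeration is only feasible for at most 5 nodes")
  pairs <- expand.grid(from = seq_len(p), to = seq_len(p))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  n_pairs <- nrow(pairs)
  out <- list()
  for (code in 0:(2^n_pairs - 1)) {
    sel <- which(bitwAnd(code, bitwShiftL(1, seq_len(n_pairs) - 1)) > 0)
    if (length(sel) >= 2) {
      key <- paste(pmin(pairs$from[sel], pairs$to[sel]),
                   pmax(pairs$from[sel], pairs$to[sel]))
      if (anyDuplicated(key)) next  # both directions of one pair: not a simple graph
    }
    e <- data.frame(parent = nodes[pairs$from[sel]],
                    child = nodes[pairs$to[sel]],
                    weight = rep(1, length(sel)),
                    stringsAsFactors = FALSE)
    g <- tryCatch(dag(nodes, e), error = function(err) NULL)
    if (!is.null(g)) out[[length(out) + 1]] <- g
  }
  out
}
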
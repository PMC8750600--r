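# shared builders for the test suite; everything is generated in code

chain_dag <- function() {
  dag(c("X", "Y", "Z"),
      data.frame(parent = c("X", "Y"), child = c("Y", "Z"), weight = c(1, 1)))
}

collider_dag <- function() {
  dag(c("X", "Y", "Z"),
      data.frame(parent = c("X", "Z"), child = c("Y", "Y"), weight = c(1, 1)))
}

# paired omics with explicit matrices, auto-named when dimnames are missing
make_paired <- function(tr, pr = tr) {
  tr <- as.matrix(tr); pr <- as.matrix(pr)
  if (is.null(rownames(tr))) {
    rownames(tr) <- rownames(pr) <- sprintf("G%02d", seq_len(nrow(tr)))
  }
  if (is.null(colnames(tr))) {
    colnames(tr) <- colnames(pr) <- sprintf("S%02d", seq_len(ncol(tr)))
  }
  paired_omics(tr, pr)
}

# two clean noise-free correlated blocks for module detection tests:
# every feature in a block is a loading times a shared profile
block_expression <- function(block_sizes, n_samples = 12, seed = 1) {
  set.seed(seed)
  profiles <- matrix(rnorm(length(block_sizes) * n_samples),
                     length(block_sizes), n_samples)
  rows <- do.call(rbind, lapply(seq_along(block_sizes), function(b) {
    t(sapply(seq_len(block_sizes[b]), function(i) runif(1, 0.5, 1.5) * profiles[b, ]))
  }))
  dimnames(rows) <- list(sprintf("G%03d", seq_len(nrow(rows))),
                         sprintf("S%02d", seq_len(n_samples)))
  rows
}

# brute-force CPDAG of a DAG via equivalence-class enumeration: collect all
# DAGs sharing skeleton and v-structures; an edge is directed in the CPDAG
# iff it points the same way in every member. Independent of the package's
# Meek-rule code path.
brute_force_cpdag <- function(g, all_dags = NULL) {
  skel_key <- function(d) {
    W <- dag_weight_matrix(d) != 0
    a <- W | t(W)
    paste(which(a[upper.tri(a)]), collapse = ",")
  }
  vstruct_key <- function(d) {
    W <- dag_weight_matrix(d) != 0
    a <- W | t(W)
    out <- character(0)
    for (y in seq_along(d$nodes)) {
      pa <- which(W[, y])
      if (length(pa) < 2) next
      for (x in pa) for (z in pa)
        if (x < z && !a[x, z])
          out <- c(out, paste(d$nodes[x], d$nodes[y], d$nodes[z]))
    }
    paste(sort(out), collapse = ";")
  }
  if (is.null(all_dags)) all_dags <- enumerate_dags(g$nodes)
  key <- paste(skel_key(g), vstruct_key(g))
  members <- Filter(function(d) paste(skel_key(d), vstruct_key(d)) == key, all_dags)
  mats <- lapply(members, function(d) (dag_weight_matrix(d) != 0) * 1L)
  n <- length(mats)
  fwd <- Reduce(`+`, mats)
  rev <- Reduce(`+`, lapply(mats, t))
  p <- length(g$nodes)
  amat <- matrix(0L, p, p, dimnames = list(g$nodes, g$nodes))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j || (fwd[i, j] + rev[i, j]) == 0) next
    if (fwd[i, j] == n) amat[i, j] <- 1L            # same direction everywhere
    else if (rev[i, j] != n) { amat[i, j] <- 1L; amat[j, i] <- 1L }
  }
  pcmods:::amat_to_cpdag(amat)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "pcmods", mustWork = TRUE)
}
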
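test_that("partial correlation matches recursion and identity cases", {
  C <- diag(3)
  dimnames(C) <- list(c("X", "Y", "Z"), c("X", "Y", "Z"))
  suff0 <- ci_suff_stat(C, 50)
  expect_equal(partial_correlation(suff0, "X", "Z", "Y"), 0)
  C2 <- C
  C2["X", "Y"] <- C2["Y", "X"] <- 0.8
  C2["Y", "Z"] <- C2["Z", "Y"] <- 0.8
  C2["X", "Z"] <- C2["Z", "X"] <- 0.64
  suff <- ci_suff_stat(C2, 50)
  # (0.64 - 0.8*0.8) / (1 - 0.64) = 0
  expect_equal(partial_correlation(suff, "X", "Z", "Y"), 0, tolerance = 1e-10)
  expect_equal(partial_correlation(suff, "X", "Z"), 0.64)  # empty set: marginal
  expect_error(partial_correlation(suff, "X", "X"), "differ")
  expect_error(partial_correlation(suff, "X", "Y", "Y"), "conditioning")
})

test_that("Fisher-z test reproduces closed-form arithmetic and its precondition", {
  C <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  res <- fisher_z_test(ci_suff_stat(C, 19), "A", "B", alpha = 0.05)
  expect_equal(res$fisher_z, 0.5 * log(3), tolerance = 1e-6)     # 0.5493
  expect_equal(res$statistic, 4 * 0.5 * log(3), tolerance = 1e-6) # 2.197
  expect_equal(res$p_value, 2 * pnorm(-4 * 0.5 * log(3)), tolerance = 1e-9)
  expect_lt(res$p_value, 0.05)
  expect_false(res$independent)
  # zero correlation: statistic 0, p-value 1
  C0 <- diag(2); dimnames(C0) <- dimnames(C)
  r0 <- fisher_z_test(ci_suff_stat(C0, 19), "A", "B")
  expect_equal(r0$statistic, 0, tolerance = 1e-5)
  expect_equal(r0$p_value, 1, tolerance = 1e-5)
  expect_true(r0$independent)
  # n - |S| - 3 < 1: undefined
  C3 <- diag(3); dimnames(C3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_error(fisher_z_test(ci_suff_stat(C3, 4), "A", "B", "C"), "undefined")
})

test_that("skeleton search under the d-separation oracle finds the right sepsets", {
  ch <- chain_dag()
  sk <- pcmods:::pc_skeleton_generic(ch$nodes, d_separation_oracle(ch))
  expect_true(sk$adjacency["X", "Y"] && sk$adjacency["Y", "Z"])
  expect_false(sk$adjacency["X", "Z"])
  expect_identical(pcmods:::get_sepset(sk$sepsets, "X", "Z"), "Y")

  co <- collider_dag()
  sk2 <- pcmods:::pc_skeleton_generic(co$nodes, d_separation_oracle(co))
  expect_false(sk2$adjacency["X", "Z"])
  expect_identical(pcmods:::get_sepset(sk2$sepsets, "X", "Z"), character(0))

  indep <- dag(c("A", "B", "C"))
  sk3 <- pcmods:::pc_skeleton_generic(indep$nodes, d_separation_oracle(indep))
  expect_true(all(!sk3$adjacency))
})

test_that("v-structure orientation directs colliders and nothing else", {
  co <- collider_dag()
  sk <- pcmods:::pc_skeleton_generic(co$nodes, d_separation_oracle(co))
  g <- orient_v_structures(sk)
  expect_identical(unname(g["X", "Y"]), 1L)
  expect_identical(unname(g["Y", "X"]), 0L)
  expect_identical(unname(g["Z", "Y"]), 1L)
  expect_identical(unname(g["Y", "Z"]), 0L)
  ch <- chain_dag()
  gch <- orient_v_structures(pcmods:::pc_skeleton_generic(ch$nodes, d_separation_oracle(ch)))
  expect_identical(gch, t(gch))  # everything stays undirected
})

test_that("Meek rules R1 and R2 fire as defined", {
  # R1: A -> B, B - C, A and C non-adjacent  =>  B -> C
  m <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- 1L
  m["B", "C"] <- m["C", "B"] <- 1L
  out <- apply_meek_rules(m)
  expect_identical(nrow(out$directed_edges), 2L)
  expect_true(any(out$directed_edges$from == "B" & out$directed_edges$to == "C"))
  # R2: A -> B -> C with A - C  =>  A -> C
  m2 <- matrix(0L, 3, 3, dimnames = dimnames(m))
  m2["A", "B"] <- 1L; m2["B", "C"] <- 1L
  m2["A", "C"] <- m2["C", "A"] <- 1L
  out2 <- apply_meek_rules(m2)
  expect_true(any(out2$directed_edges$from == "A" & out2$directed_edges$to == "C"))
  # fully undirected triangle: no rule fires
  tri <- matrix(1L, 3, 3, dimnames = dimnames(m)); diag(tri) <- 0L
  out3 <- apply_meek_rules(tri)
  expect_identical(nrow(out3$directed_edges), 0L)
  expect_identical(nrow(out3$undirected_edges), 3L)
})

test_that("pc under the oracle returns the equivalence class, not the DAG", {
  ch <- chain_dag()
  cp <- pc_with_test(ch$nodes, d_separation_oracle(ch))
  expect_identical(nrow(cp$directed_edges), 0L)
  expect_identical(nrow(cp$undirected_edges), 2L)
  co <- collider_dag()
  cpc <- pc_with_test(co$nodes, d_separation_oracle(co))
  expect_identical(nrow(cpc$directed_edges), 2L)
  expect_identical(nrow(cpc$undirected_edges), 0L)
  indep <- dag(c("A", "B", "C"))
  cpi <- pc_with_test(indep$nodes, d_separation_oracle(indep))
  expect_identical(nrow(cpi$directed_edges) + nrow(cpi$undirected_edges), 0L)
})

test_that("dag_to_cpdag matches canonical equivalence classes", {
  single <- dag(c("A", "B"), data.frame(parent = "A", child = "B", weight = 1))
  cp <- dag_to_cpdag(single)
  expect_identical(nrow(cp$directed_edges), 0L)
  expect_identical(nrow(cp$undirected_edges), 1L)
  cpc <- dag_to_cpdag(collider_dag())
  expect_identical(nrow(cpc$directed_edges), 2L)
  full3 <- dag(c("A", "B", "C"),
               data.frame(parent = c("A", "A", "B"), child = c("B", "C", "C"),
                          weight = rep(1, 3)))
  cpf <- dag_to_cpdag(full3)
  expect_identical(nrow(cpf$directed_edges), 0L)
  expect_identical(nrow(cpf$undirected_edges), 3L)
})

test_that("dag_to_cpdag agrees with brute-force equivalence-class enumeration on 3 nodes", {
  all3 <- enumerate_dags(c("A", "B", "C"))
  expect_identical(length(all3), 25L)
  for (g in all3) {
    expect_identical(structural_hamming_distance(dag_to_cpdag(g),
                                                 brute_force_cpdag(g, all3)), 0L)
  }
})

test_that("structural Hamming distance counts pairwise status mismatches", {
  n <- c("A", "B", "C")
  g1 <- cpdag(n, data.frame(from = "A", to = "B"))
  expect_identical(structural_hamming_distance(g1, g1), 0L)
  g2 <- cpdag(n, data.frame(from = "A", to = "B"),
              data.frame(a = "B", b = "C"))
  expect_identical(structural_hamming_distance(g1, g2), 1L)  # extra undirected edge
  g3 <- cpdag(n, undirected_edges = data.frame(a = "A", b = "B"))
  expect_identical(structural_hamming_distance(g1, g3), 1L)  # directed vs undirected
  g4 <- cpdag(n, data.frame(from = "B", to = "A"))
  expect_identical(structural_hamming_distance(g1, g4), 1L)  # reversed direction
  expect_error(structural_hamming_distance(g1, cpdag(c("A", "B"))), "node sets")
})

test_that("CPDAG summaries count edges, subgraphs and effect-only nodes", {
  n <- c("A", "B", "C", "D", "E")
  g <- cpdag(n, data.frame(from = c("A", "B"), to = c("C", "C")))
  s <- summarize_cpdag(g)
  expect_identical(s$n_directed, 2L)
  expect_identical(s$n_undirected, 0L)
  expect_identical(s$n_connected_subgraphs, 1L)
  expect_identical(s$effect_only_nodes, "C")
  empty <- summarize_cpdag(cpdag(n))
  expect_identical(empty$n_directed + empty$n_undirected + empty$n_connected_subgraphs, 0L)
  one_und <- summarize_cpdag(cpdag(n, undirected_edges = data.frame(a = "A", b = "B")))
  expect_identical(one_und$n_undirected, 1L)
  expect_identical(one_und$n_connected_subgraphs, 1L)
  expect_identical(length(one_und$effect_only_nodes), 0L)
})

test_that("CPDAGs survive the TSV round trip and render to DOT", {
  n <- c("ME1", "ME2", "ME3")
  g <- cpdag(n, data.frame(from = "ME1", to = "ME2"),
             data.frame(a = "ME2", b = "ME3"))
  td <- withr::local_tempdir()
  write_cpdag_tsv(g, file.path(td, "g.tsv"))
  g2 <- read_cpdag_tsv(file.path(td, "g.tsv"), n)
  expect_identical(structural_hamming_distance(g, g2), 0L)
  write_cpdag_dot(g, file.path(td, "g.dot"))
  dot <- readLines(file.path(td, "g.dot"))
  expect_true(any(grepl("\"ME1\" -> \"ME2\";", dot, fixed = TRUE)))
  expect_true(any(grepl("dir=none", dot, fixed = TRUE)))
})

test_that("pc output is invariant to variable relabeling on oracle input", {
  g <- random_dag(5, 0.5, 77)
  cp <- pc_with_test(g$nodes, d_separation_oracle(g))
  perm <- c(3, 5, 1, 2, 4)
  g_perm <- dag(g$nodes[perm], g$edges)
  cp_perm <- pc_with_test(g_perm$nodes, d_separation_oracle(g_perm))
  expect_identical(structural_hamming_distance(cp, cp_perm), 0L)
})
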
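test_that("random_dag respects edge probability extremes and node count", {
  g0 <- random_dag(4, 0, 7)
  expect_identical(nrow(g0$edges), 0L)
  g1 <- random_dag(4, 1, 7)
  expect_identical(nrow(g1$edges), 6L)  # complete DAG: n(n-1)/2
  expect_error(random_dag(0, 0.5, 1), "positive")
  expect_error(random_dag(3, 1.5, 1), "edge_prob")
})

test_that("random_dag is always acyclic and weight magnitudes stay in [0.5, 1.5]", {
  for (s in 1:300) {
    g <- random_dag(6, 0.4, s)
    expect_false(is.null(topological_order(g)))
    if (nrow(g$edges) > 0) {
      expect_true(all(abs(g$edges$weight) >= 0.5))
      expect_true(all(abs(g$edges$weight) <= 1.5))
    }
  }
})

test_that("random_dag and simulate_sem are deterministic under a seed", {
  expect_identical(random_dag(5, 0.5, 11), random_dag(5, 0.5, 11))
  g <- random_dag(5, 0.5, 11)
  expect_identical(simulate_sem(g, 50, 1, 3), simulate_sem(g, 50, 1, 3))
})

test_that("simulate_sem on an empty DAG gives mutually independent nodes", {
  g <- dag(c("A", "B", "C"))
  x <- simulate_sem(g, 5000, 1, 21)
  r <- cor(x)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("single-edge SEM reproduces the closed-form correlation w/sqrt(w^2+1)", {
  g <- dag(c("A", "B"), data.frame(parent = "A", child = "B", weight = 1))
  x <- simulate_sem(g, 20000, 1, 13)
  expect_equal(cor(x[, "A"], x[, "B"]), 1 / sqrt(2), tolerance = 0.02 / 0.707)
})

test_that("SEM sample covariance matches the analytic (I-W)^-T Sigma (I-W)^-1 form", {
  for (s in 1:3) {
    g <- random_dag(4, 0.5, 100 + s)
    x <- simulate_sem(g, 20000, 1, 200 + s)
    S_hat <- cov(x)
    S <- sem_covariance(g, 1)[colnames(x), colnames(x)]
    expect_lt(max(abs(S_hat - S)), 0.05 * max(1, max(abs(S))))
  }
})

test_that("simulate_sem rejects cyclic input and tiny samples", {
  g <- dag(c("A", "B"))
  g$edges <- data.frame(parent = c("A", "B"), child = c("B", "A"), weight = c(1, 1))
  expect_error(simulate_sem(g, 10), "cyclic")
  expect_error(simulate_sem(dag(c("A", "B")), 1), "n_samples")
})

test_that("generate_paired_omics conserves feature counts and labels", {
  g <- dag(c("M1", "M2"))
  out <- generate_paired_omics(c(60, 60), 30, g, n_samples = 10, seed = 4)
  expect_identical(n_features(out$data), 150L)
  expect_identical(n_features(out$data), length(out$truth$module_labels))
  expect_identical(sum(out$truth$module_labels == 1), 60L)
  expect_identical(sum(out$truth$module_labels == 0), 30L)
  expect_true(all(out$truth$module_labels %in% 0:2))
})

test_that("noise-free generation with full agreement gives |cor| = 1 within modules", {
  g <- dag(c("M1", "M2"))
  out <- generate_paired_omics(c(10, 10), 0, g, n_samples = 8,
                               feature_noise_sd = 1e-9, layer_agreement = 1,
                               low_expression_fraction = 0, seed = 9)
  for (layer in list(out$data$transcript, out$data$protein)) {
    for (m in 1:2) {
      members <- names(out$truth$module_labels)[out$truth$module_labels == m]
      r <- abs(cor(t(layer[members, ])))
      expect_equal(min(r), 1, tolerance = 1e-6)
    }
  }
})

test_that("within-module correlation exceeds between-module correlation by default", {
  g <- dag(c("M1", "M2", "M3"))
  out <- generate_paired_omics(c(40, 40, 40), 20, g, seed = 17)
  labels <- out$truth$module_labels
  r <- abs(cor(t(out$data$transcript)))
  same <- outer(labels, labels, "==") & labels > 0
  diff <- outer(labels > 0, labels > 0, "&") & !outer(labels, labels, "==")
  diag(same) <- FALSE
  expect_gt(mean(r[same]), mean(r[diff]))
})

test_that("generated abundances are nonnegative and complete unless missingness is enabled", {
  g <- dag(c("M1", "M2"))
  out <- generate_paired_omics(c(30, 30), 20, g, seed = 3)
  expect_false(anyNA(out$data$transcript))
  expect_false(anyNA(out$data$protein))
  expect_true(all(out$data$transcript >= 0))
  expect_true(all(out$data$protein >= 0))
  out2 <- generate_paired_omics(c(30, 30), 20, g, na_fraction = 0.05, seed = 3)
  expect_true(anyNA(out2$data$transcript) || anyNA(out2$data$protein))
})

test_that("generation is deterministic and rejects sign-ambiguous loading ranges", {
  g <- dag(c("M1", "M2"))
  a <- generate_paired_omics(c(20, 20), 10, g, seed = 5)
  b <- generate_paired_omics(c(20, 20), 10, g, seed = 5)
  expect_identical(a$data$transcript, b$data$transcript)
  expect_identical(a$data$protein, b$data$protein)
  expect_error(generate_paired_omics(c(20, 20), 10, g, loading_range = c(-0.5, 0.5), seed = 1),
               "loading_range")
})

test_that("paired omics and truth survive a TSV round trip", {
  g <- dag(c("M1", "M2"), data.frame(parent = "M1", child = "M2", weight = 0.8))
  out <- generate_paired_omics(c(8, 8), 4, g, n_samples = 6, seed = 2,
                               low_expression_fraction = 0)
  td <- withr::local_tempdir()
  write_paired_omics(out$data, file.path(td, "t.tsv"), file.path(td, "p.tsv"))
  back <- read_paired_omics(file.path(td, "t.tsv"), file.path(td, "p.tsv"))
  expect_equal(back$transcript, out$data$transcript)
  expect_equal(back$protein, out$data$protein)
  write_dag_tsv(g, file.path(td, "dag.tsv"))
  g2 <- read_dag_tsv(file.path(td, "dag.tsv"), g$nodes)
  expect_equal(g2$edges, g$edges)
})
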
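test_that("adjacency powers correlations as specified for both network types", {
  # two features engineered to have exact correlation 0.5 across 4 samples
  x <- c(1, -1, 1, -1)
  y <- c(1, 0, 0, -1)
  m <- rbind(a = x, b = y)
  colnames(m) <- paste0("S", 1:4)
  r <- cor(x, y)
  a_un <- adjacency_from_expression(m, power = 2, network_type = "unsigned")
  expect_equal(a_un["a", "b"], abs(r)^2)
  expect_equal(diag(a_un), c(a = 1, b = 1))
  a_si <- adjacency_from_expression(rbind(a = x, b = -y), power = 2, network_type = "signed")
  expect_equal(unname(a_si[1, 2]), ((1 - r) / 2)^2)
  expect_error(adjacency_from_expression(rbind(a = x, b = rep(1, 4)), 2), "variance")
})

test_that("scale-free fit index hits 1, 0 and -1 on constructed degree distributions", {
  # counts proportional to 1/k at separated values: exact log-log line, slope -1
  k <- rep(c(1, 3, 5, 7), times = c(105, 35, 21, 15))
  expect_equal(scale_free_fit(k, n_bins = 4), 1)
  # flat p(k): equal counts per bin
  k_flat <- rep(c(1, 3, 5, 7), times = c(30, 30, 30, 30))
  expect_equal(scale_free_fit(k_flat, n_bins = 4), 0)
  # increasing p(k) on an exact line (freq proportional to k): sign gives -1
  k_inc <- rep(c(1, 3, 5, 7), times = c(15, 45, 75, 105))
  expect_equal(scale_free_fit(k_inc, n_bins = 4), -1)
  expect_warning(res <- scale_free_fit(rep(2, 50)), "degenerate")
  expect_identical(res, 0)
})

test_that("soft threshold selection picks the smallest qualifying power", {
  g <- dag(paste0("M", 1:3))
  d <- generate_paired_omics(c(40, 40, 40), 20, g, seed = 71)$data
  d <- filter_paired_omics(d)$data
  layers <- list(transcript = d$transcript, protein = d$protein)
  st <- pick_soft_threshold(layers, powers = c(2, 4, 6, 9, 12, 16), r2_cut = 0.5)
  expect_identical(st$min_r2, unname(apply(st$signed_r2, 1, min)))
  qualifying <- st$powers[st$min_r2 >= 0.5]
  if (length(qualifying) > 0) expect_identical(st$chosen_power, min(qualifying))
  else expect_true(is.na(st$chosen_power))
  # unattainable cut -> no power chosen
  st2 <- pick_soft_threshold(layers, powers = c(2, 4), r2_cut = 0.999)
  expect_true(is.na(st2$chosen_power))
  expect_error(pick_soft_threshold(layers, powers = numeric(0)), "empty")
})

test_that("mean connectivity decreases in the power whenever adjacency is fractional", {
  g <- dag(paste0("M", 1:2))
  d <- generate_paired_omics(c(30, 30), 20, g, seed = 72)$data
  st <- pick_soft_threshold(list(d$transcript), powers = 1:6, r2_cut = 0.85)
  mk <- st$mean_connectivity[, 1]
  expect_true(all(diff(mk) < 0))
})

test_that("topological overlap matches closed forms and stays bounded", {
  # isolated pair: no connection, no shared neighbors
  a <- diag(2)
  expect_equal(tom_from_adjacency(a)[1, 2], 0)
  # block of identical features: TOM is exactly 1 inside the block
  m <- 5
  a1 <- matrix(1, m, m)
  expect_equal(max(abs(tom_from_adjacency(a1) - 1)), 0)
  # random adjacency: symmetry and [0, 1] bounds
  set.seed(42)
  for (i in 1:100) {
    r <- matrix(runif(20 * 20), 20, 20)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- tom_from_adjacency(a)
    expect_lt(max(abs(tom - t(tom))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(unname(diag(tom)), rep(1, 20))
  }
})

test_that("consensus TOM calibrates by quantile ratio and takes the minimum", {
  set.seed(7)
  r <- matrix(runif(100), 10, 10)
  t1 <- (r + t(r)) / 2; diag(t1) <- 1
  expect_equal(consensus_tom(list(t1, t1)), t1)  # idempotent on duplicates
  t0 <- diag(10)
  expect_warning(cons0 <- consensus_tom(list(t1, t0)), "calibration")
  expect_equal(max(abs(cons0 - diag(10))), 0)  # zero layer wins the minimum
  # quantile ratio: second TOM scaled by q1/q2 before the minimum
  t2 <- pmin(2 * t1, 1); diag(t2) <- 1
  q1 <- quantile(t1[row(t1) != col(t1)], 0.95)
  q2 <- quantile(t2[row(t2) != col(t2)], 0.95)
  cons <- consensus_tom(list(t1, t2), 0.95)
  manual <- pmin(t1, pmin(t2 * (q1 / q2), 1)); diag(manual) <- 1
  expect_equal(cons, manual)
  expect_true(all(cons <= t1 + 1e-12))
})

test_that("module detection recovers clean planted blocks and respects min size", {
  expr <- block_expression(c(60, 60))
  a <- adjacency_from_expression(expr, 6)
  tom <- tom_from_adjacency(a)
  part <- detect_modules(1 - tom, min_module_size = 30)
  expect_identical(length(part$module_ids), 2L)
  truth <- rep(1:2, each = 60)
  expect_equal(module_recovery_ari(unname(part$labels), truth), 1)
  # labels ordered by decreasing size
  expect_true(all(diff(as.integer(part$sizes)) <= 0))
  # fewer features than the minimum: everything unassigned
  small <- detect_modules(1 - tom[1:20, 1:20], min_module_size = 30)
  expect_true(all(small$labels == 0))
})

test_that("module detection is invariant to feature permutation up to renaming", {
  expr <- block_expression(c(40, 35, 45), seed = 3)
  tom <- tom_from_adjacency(adjacency_from_expression(expr, 6))
  part <- detect_modules(1 - tom)
  set.seed(5)
  perm <- sample(nrow(expr))
  part2 <- detect_modules(1 - tom[perm, perm])
  expect_equal(module_recovery_ari(part$labels, part2$labels), 1)
})

test_that("module eigengene is the unit-norm leading component, sign-aligned", {
  # identical features: eigengene proportional to the standardized profile
  profile <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expr <- rbind(a = 2 * profile, b = 5 * profile, c = 0.5 * profile)
  colnames(expr) <- paste0("S", 1:8)
  e <- module_eigengene(expr, c("a", "b", "c"))
  zs <- scale(profile)[, 1]
  expect_equal(unname(e), zs / sqrt(sum(zs^2)), tolerance = 1e-8)
  expect_equal(sum(e^2), 1)
  expect_gt(cor(e, profile), 0)  # sign alignment
  # two perfectly anticorrelated features: rank-1 after standardization
  expr2 <- rbind(a = profile, b = -profile)
  colnames(expr2) <- paste0("S", 1:8)
  xs <- t(scale(t(expr2)))
  sv <- svd(xs)
  expect_equal(sv$d[1]^2 / sum(sv$d^2), 1)
  expect_error(module_eigengene(rbind(a = rep(1, 8)), "a"), "variance")
})

test_that("close modules merge by consensus eigengene dissimilarity", {
  n <- 10
  set.seed(8)
  base <- rnorm(n)
  # two modules with eigengene correlation ~0.99 in both layers, one distant
  m1 <- t(sapply(1:30, function(i) base + rnorm(n, 0, 0.05)))
  m2 <- t(sapply(1:30, function(i) base + rnorm(n, 0, 0.05)))
  m3 <- t(sapply(1:30, function(i) rnorm(n)))
  expr <- rbind(m1, m2, m3)
  dimnames(expr) <- list(sprintf("G%03d", 1:90), sprintf("S%02d", 1:n))
  part <- module_partition(setNames(rep(1:3, each = 30), rownames(expr)))
  merged <- merge_close_modules(list(expr, expr), part, cut_height = 0.25)
  expect_identical(length(merged$module_ids), 2L)
  expect_identical(unname(merged$sizes[1]), 60L)
  # uncorrelated modules stay apart
  part2 <- module_partition(setNames(rep(1:2, c(30, 30)), rownames(expr)[31:90]))
  kept <- merge_close_modules(list(expr[31:90, ]), part2, cut_height = 0.25)
  expect_identical(length(kept$module_ids), 2L)
})

test_that("three near-identical modules collapse to one module", {
  n <- 12
  set.seed(9)
  base <- rnorm(n)
  expr <- t(sapply(1:90, function(i) base + rnorm(n, 0, 0.02)))
  dimnames(expr) <- list(sprintf("G%03d", 1:90), sprintf("S%02d", 1:n))
  part <- module_partition(setNames(rep(1:3, each = 30), rownames(expr)))
  merged <- merge_close_modules(list(expr), part, cut_height = 0.25)
  expect_identical(length(merged$module_ids), 1L)
})

test_that("planted consensus modules are recovered at low noise with full agreement", {
  g <- dag(paste0("M", 1:3))
  out <- generate_paired_omics(c(45, 45, 45), 30, g, n_samples = 12,
                               feature_noise_sd = 0.2, layer_agreement = 1,
                               seed = 55)
  d <- filter_paired_omics(out$data)$data
  cm <- consensus_modules(d, power = 6)
  truth <- out$truth$module_labels[names(cm$partition$labels)]
  expect_gte(module_recovery_ari(cm$partition$labels, truth), 0.9)
})
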
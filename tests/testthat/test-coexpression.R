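test_that("signed adjacency matches the closed form and validates input", {
  expect_equal(signed_adjacency(matrix(c(1, 1, 1, 1), 2), 4)[1, 2], 1)
  expect_equal(signed_adjacency(matrix(c(1, -1, -1, 1), 2), 7)[1, 2], 0)
  expect_equal(signed_adjacency(matrix(c(1, 0, 0, 1), 2), 4)[1, 2], 0.0625)
  a <- signed_adjacency(matrix(c(1, 0.4, 0.4, 1), 2), 4)
  expect_equal(diag(a), c(0, 0))
  expect_error(signed_adjacency(matrix(c(1, 1.1, 1.1, 1), 2), 4), "outside")
})

test_that("TOM matches the hand-worked 3-node example and a brute-force oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  tom <- tom_similarity(a)
  # l_12 = a_13 * a_32 = 0.25; k = 1 each; TOM_12 = (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(diag(tom), rep(1, 3))

  set.seed(42)
  n <- 8
  r <- matrix(runif(n * n), n); r <- (r + t(r)) / 2; diag(r) <- 0
  tom2 <- tom_similarity(r)
  k <- colSums(r)
  for (i in 1:4) for (j in (i + 1):5) {
    l <- sum(r[i, -c(i, j)] * r[-c(i, j), j])
    expect_equal(tom2[i, j], (l + r[i, j]) / (min(k[i], k[j]) + 1 - r[i, j]),
                 tolerance = 1e-12)
  }
  expect_true(all(tom2 >= 0 & tom2 <= 1))
  expect_equal(tom2, t(tom2))
})

test_that("TOM degenerate graphs behave as the formula dictates", {
  z <- matrix(0, 4, 4)
  tz <- tom_similarity(z)
  expect_equal(tz, diag(4))
  o <- matrix(1, 5, 5); diag(o) <- 0
  expect_equal(tom_similarity(o), matrix(1, 5, 5))
})

test_that("mean connectivity decreases with power; suggestion is deterministic", {
  set.seed(3)
  x <- matrix(rnorm(40 * 50), 40, 50,
              dimnames = list(sprintf("G%02d", 1:40), sprintf("S%02d", 1:50)))
  sft <- suppressWarnings(
    pick_soft_threshold(x, candidate_powers = c(1, 2, 4, 8), r2_target = 0.8))
  expect_true(all(diff(sft$table$mean_connectivity) < 0))
  sft2 <- suppressWarnings(
    pick_soft_threshold(x, candidate_powers = c(1, 2, 4, 8), r2_target = 0.8))
  expect_identical(sft$suggested_power, sft2$suggested_power)
})

test_that("scale-free fit recovers an exact power law", {
  # degree sequence with p(k) proportional to 1/k over k = 1..10
  k <- rep(1:10, times = round(2520 / (1:10)))
  fit <- scale_free_fit(k, n_bins = 10)
  expect_gte(fit$r_squared, 0.95)
  # independent regression oracle on the same bins
  oracle <- suppressWarnings(
    summary(lm(log10(freq) ~ log10(k_mean), data = fit$bins))$r.squared)
  expect_equal(abs(fit$r_squared), oracle, tolerance = 1e-12)
  expect_lt(fit$slope, 0)
  # increasing degree distribution gets a negated R^2
  k_up <- rep(1:10, times = 1:10 * 5)
  expect_lt(scale_free_fit(k_up, n_bins = 5)$r_squared, 0)
})

test_that("module eigengene is the leading PC with nonnegative orientation", {
  set.seed(5)
  prof <- rnorm(30)
  x <- rbind(prof, prof, prof) + 0
  rownames(x) <- paste0("G", 1:3); colnames(x) <- paste0("S", 1:30)
  eg <- module_eigengene(x)
  expect_equal(attr(eg, "var_explained"), 1, tolerance = 1e-12)
  zs <- (prof - mean(prof)) / sd(prof)
  expect_equal(abs(cor(eg, zs)), 1, tolerance = 1e-12)
  zrow <- (x - rowMeans(x)) / apply(x, 1, sd)
  expect_gte(cor(as.numeric(eg), colMeans(zrow)), 0)
  # orientation contract under sign flip
  eg_flip <- module_eigengene(-x)
  zrow_f <- (-x - rowMeans(-x)) / apply(-x, 1, sd)
  expect_gte(cor(as.numeric(eg_flip), colMeans(zrow_f)), 0)

  # two-gene closed form: standardized covariance [[1, r], [r, 1]] has leading
  # eigenvector (1, 1)/sqrt(2), so the eigengene is the normalized mean z row
  y <- rbind(rnorm(25), rnorm(25)); y[2, ] <- y[1, ] * 0.8 + rnorm(25, sd = 0.4)
  dimnames(y) <- list(c("A", "B"), paste0("S", 1:25))
  egy <- module_eigengene(y)
  zsum <- colSums((y - rowMeans(y)) / apply(y, 1, sd))
  expect_equal(abs(cor(as.numeric(egy), zsum)), 1, tolerance = 1e-10)

  expect_error(module_eigengene(matrix(1, 2, 5)), "zero-variance")
  expect_error(module_eigengene(matrix(1, 1, 5)), ">= 2 genes")
})

test_that("detect_modules recovers planted modules and greys out noise", {
  cfg <- generator_config(n_genes = 250L, n_samples = 150L,
                          module_sizes = c(50L, 50L), seed = 21L)
  coh <- generate_cohort(cfg)
  ft <- build_feature_matrix(coh$expression, coh$samples)
  part <- detect_modules(ft, network_params(power = 4))
  truth <- coh$truth$modules
  detected <- part$labels[truth$gene]
  expect_identical(length(unique(detected[detected > 0])), 2L)
  expect_gte(ari(detected, truth$module), 0.9)
  # eigengenes have unit length
  expect_equal(colSums(part$eigengenes^2), c(ME1 = 1, ME2 = 1), tolerance = 1e-10)
})

test_that("undersized perfect clusters are left unassigned", {
  set.seed(9)
  prof <- rnorm(60)
  x <- matrix(rep(prof, each = 29), 29) +
    matrix(rnorm(29 * 60, sd = 1e-3), 29)
  x <- rbind(x, matrix(rnorm(40 * 60), 40))
  dimnames(x) <- list(sprintf("G%02d", 1:69), sprintf("S%02d", 1:60))
  part <- detect_modules(x, network_params(power = 4, min_module_size = 30L))
  expect_true(all(part$labels[1:29] == 0L))
})

test_that("detect_modules is permutation-equivariant up to renumbering", {
  cfg <- tiny_config(seed = 13L)
  coh <- generate_cohort(cfg)
  ft <- build_feature_matrix(coh$expression, coh$samples)
  p1 <- detect_modules(ft, network_params(power = 4))
  set.seed(1)
  perm <- sample(nrow(ft))
  p2 <- detect_modules(ft[perm, ], network_params(power = 4))
  expect_gte(ari(p1$labels[rownames(ft)], p2$labels[rownames(ft)]), 0.999)
})

test_that("block-wise detection matches single-block recovery on planted modules", {
  coh <- generate_cohort(generator_config(n_genes = 200L, n_samples = 80L,
                                          module_sizes = c(40L, 40L), seed = 1L))
  ft <- build_feature_matrix(coh$expression, coh$samples)
  blk <- detect_modules(ft, network_params(power = 4, max_block_size = 80L))
  truth <- coh$truth$modules
  expect_gte(ari(blk$labels[truth$gene], truth$module), 0.9)
  blk2 <- detect_modules(ft, network_params(power = 4, max_block_size = 80L))
  expect_identical(blk$labels, blk2$labels)
})

test_that("degenerate inputs are rejected or repaired", {
  x <- matrix(rnorm(10 * 2), 2, 10,
              dimnames = list(c("a", "b"), sprintf("S%02d", 1:10)))
  expect_error(detect_modules(x), "at least 3 genes")
  y <- rbind(x, c = rep(1, 10), d = rnorm(10))
  expect_warning(detect_modules(y, network_params(power = 2)), "constant")
  expect_error(network_params(merge_cut_height = 1.2), "merge_cut_height")
  expect_error(network_params(reassign_threshold = 0.5), "reassign")
})
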
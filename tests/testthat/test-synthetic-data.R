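test_that("generator is deterministic and validates its configuration", {
  cfg <- tiny_config(seed = 7L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  expect_error(generator_config(noise_sd = 0), "noise_sd")
  expect_error(generator_config(n_genes = 10, module_sizes = c(8, 8)),
               "module_sizes")
  expect_error(generator_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(generator_config(latent_loading = -0.5), "latent_loading")
})

test_that("cohort structure honours its invariants", {
  coh <- generate_cohort(tiny_config(seed = 2L))
  expect_true(all(coh$expression >= 0))
  expect_false(anyDuplicated(colnames(coh$expression)) > 0)
  expect_setequal(coh$samples$sample, colnames(coh$expression))
  expect_true(all(coh$survival$event %in% c(0L, 1L)))
  expect_true(all(coh$survival$time >= 0))
  # planted modules partition the planted genes disjointly
  tab <- table(coh$truth$modules$gene)
  expect_true(all(tab == 1))
  expect_equal(sum(coh$truth$modules$module > 0), sum(tiny_config()$module_sizes))
  # gene-level NFYA row equals the sum of isoform TPMs
  expect_equal(unname(coh$expression["NFYA", ]),
               coh$samples$yal + coh$samples$yas)
})

test_that("planted correlation matches the factor-model closed form", {
  # expected within-module r = lambda^2 / (lambda^2 + sigma^2) = 0.8
  cfg <- generator_config(n_genes = 60L, n_samples = 1000L, module_sizes = 50L,
                          latent_loading = 1, noise_sd = 0.5, seed = 11L)
  coh <- generate_cohort(cfg)
  mod_genes <- coh$truth$modules$gene[coh$truth$modules$module == 1L]
  cm <- cor(t(log_tpm(coh$expression[mod_genes, ])))
  mean_r <- mean(cm[upper.tri(cm)])
  expect_lt(abs(mean_r - 0.8), 0.05)

  # decoupled generator: within-module correlation vanishes
  cfg0 <- generator_config(n_genes = 60L, n_samples = 300L, module_sizes = 50L,
                           latent_loading = 0, ratio_coupling = 0, seed = 12L)
  coh0 <- generate_cohort(cfg0)
  cm0 <- cor(t(log_tpm(coh0$expression[mod_genes, ])))
  expect_lt(mean(abs(cm0[upper.tri(cm0)])), 3 / sqrt(300))
})

test_that("cohort pairs share exactly the requested ratio-module genes", {
  mk <- function(m1, seed) generator_config(n_genes = m1 + 60L,
                                            n_samples = 40L,
                                            module_sizes = c(m1, 20L),
                                            seed = seed)
  pair <- generate_cohort_pair(mk(40L, 1L), mk(60L, 2L), shared_genes = 15L)
  modA <- with(pair$A$truth$modules, gene[module == 1L])
  modB <- with(pair$B$truth$modules, gene[module == 1L])
  expect_length(intersect(modA, modB), 15L)
  expect_setequal(intersect(modA, modB), pair$shared)
  # no leakage of shared names outside the ratio modules
  expect_length(intersect(rownames(pair$A$expression), rownames(pair$B$expression)),
                15L + 1L) # + the gene-level NFYA row

  none <- generate_cohort_pair(mk(40L, 1L), mk(60L, 2L), shared_genes = 0L)
  expect_length(intersect(with(none$A$truth$modules, gene[module == 1L]),
                          with(none$B$truth$modules, gene[module == 1L])), 0L)

  full <- generate_cohort_pair(mk(40L, 1L), mk(60L, 2L), shared_genes = 40L)
  modA <- with(full$A$truth$modules, gene[module == 1L])
  modB <- with(full$B$truth$modules, gene[module == 1L])
  expect_true(all(modA %in% modB))

  expect_error(generate_cohort_pair(mk(40L, 1L), mk(60L, 2L), shared_genes = 41L),
               "exceeds")
})

test_that("survival generator separates true high/low-ratio groups", {
  cfg <- generator_config(n_genes = 20L, n_samples = 400L, module_sizes = 10L,
                          log_hazard_ratio = 0.9, seed = 5L)
  coh <- generate_cohort(cfg)
  hi <- coh$truth$high_ratio
  lr <- logrank_test(coh$survival[hi, ], coh$survival[!hi, ])
  expect_lt(lr$p_value, 0.01)
})

test_that("mixture generator puts proportions on the simplex with usable truth", {
  ref <- make_celltype_reference(3L, 60L, seed = 4L)
  mix <- generate_mixture_samples(ref, 100L, dirichlet_alpha = 1, seed = 8L)
  P <- as.matrix(mix$proportions[, -1])
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_true(all(P >= 0))
  expect_identical(dim(mix$expression), c(60L, 100L))

  # noiseless two-component mixture solves exactly by hand:
  # bulk = 0.3 * ref[,1] + 0.7 * ref[,2] -> unique nonneg solution (0.3, 0.7)
  ref2 <- ref[, 1:2]
  bulk <- as.numeric(ref2 %*% c(0.3, 0.7))
  coefs <- solve(crossprod(ref2), crossprod(ref2, bulk))
  expect_equal(as.numeric(coefs), c(0.3, 0.7), tolerance = 1e-10)

  expect_error(generate_mixture_samples(ref, 10L, dirichlet_alpha = 0),
               "dirichlet_alpha")
  expect_warning(
    generate_mixture_samples(cbind(ref[, 1], ref[, 1] * 2), 5L, seed = 1L),
    "rank")
})

test_that("rbp cohort simulator plants directional coupling", {
  sim <- generate_rbp_cohorts(generator_config(n_cohorts = 3L, seed = 6L),
                              n_rbps_null = 4L, n_samples = 100L)
  expect_length(sim$cohorts, 3L)
  coh <- sim$cohorts[[1]]
  up <- sim$truth$rbp[sim$truth$direction == "up"][1]
  down <- sim$truth$rbp[sim$truth$direction == "down"][1]
  f_proxy <- log(coh$ratio$ratio)
  expect_gt(cor(coh$expression[up, ], f_proxy), 0.3)
  expect_lt(cor(coh$expression[down, ], f_proxy), -0.3)
})

test_that("written cohort round-trips through plain-text files", {
  skip_if_not_installed("jsonlite")
  coh <- generate_cohort(tiny_config(seed = 9L))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  expr <- readr::read_tsv(paths[["expression"]], show_col_types = FALSE)
  expect_equal(nrow(expr), nrow(coh$expression))
  surv <- readr::read_tsv(paths[["survival"]], show_col_types = FALSE)
  expect_equal(surv$time, coh$survival$time)
})
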
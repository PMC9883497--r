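#' Configuration for an end-to-end synthetic-cohort pipeline run
#'
#' Bundles the generator, network, signature, survival, RBP and
#' deconvolution options with one global seed. The seed is fanned out to
#' per-stage seeds by a fixed counter scheme so stages are individually
#' reproducible. Defaults are scaled for a laptop run (a pair of a few
#' hundred genes each); the cohort-pair sizes from the motivating analysis
#' (512/2508-gene ratio modules, 158 shared genes) can be requested
#' explicitly.
#'
#' @param seed global integer seed.
#' @param configA,configB generator configs for the two cohorts (seeds are
#'   overwritten from the global seed).
#' @param shared_genes planted size of the cross-cohort signature.
#' @param powerA,powerB soft-thresholding powers per cohort.
#' @param min_group_frac,n_permutations survival-scan options.
#' @param alpha,n_top RBP screen options.
#' @param n_mixture_samples,n_cell_types,mixture_noise_sd deconvolution
#'   options; the trended cell type emulates a rising mesenchymal fraction.
#' @return an `nfyar_pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            configA = generator_config(n_genes = 400L,
                                                       n_samples = 200L,
                                                       module_sizes = c(80L, 40L)),
                            configB = generator_config(n_genes = 500L,
                                                       n_samples = 200L,
                                                       module_sizes = c(120L, 40L)),
                            shared_genes = 60L,
                            powerA = 4, powerB = 7,
                            min_group_frac = 0.1, n_permutations = 0L,
                            alpha = 0.05, n_top = 20L,
                            n_mixture_samples = 150L, n_cell_types = 4L,
                            mixture_noise_sd = 0.25) {
  structure(list(seed = as.integer(seed), configA = configA, configB = configB,
                 shared_genes = as.integer(shared_genes),
                 powerA = powerA, powerB = powerB,
                 min_group_frac = min_group_frac,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, n_top = as.integer(n_top),
                 n_mixture_samples = as.integer(n_mixture_samples),
                 n_cell_types = as.integer(n_cell_types),
                 mixture_noise_sd = mixture_noise_sd),
            class = "nfyar_pipeline_config")
}

#' @noRd
run_stage <- function(name, manifest, code) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(code, error = function(e)
    abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
          class = "nfyar_stage_error", parent = e))
  manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  manifest$hashes[[name]] <- hash(value)
  list(value = value, manifest = manifest)
}

#' Run the full isoform-ratio analysis end to end on synthetic cohorts
#'
#' Executes: cohort-pair generation, feature construction, module detection
#' per cohort, ratio-module identification, cross-cohort signature
#' derivation, sample scoring, survival cutoff scans for the capped ratio
#' and the signature score, the cross-cohort RBP screen, and
#' deconvolution-based stratum summaries. A manifest records parameters,
#' stage seeds, stage timings and a content hash per stage output, so two
#' runs with the same config and seed yield identical hash tables.
#'
#' @param config an `nfyar_pipeline_config` from [pipeline_config()].
#' @param out_dir optional directory; when given, each stage's tables are
#'   written as TSV/JSON as the stage completes (so earlier outputs persist
#'   if a later stage fails).
#' @return an `nfyar_pipeline` object: list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "nfyar_pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(config = unclass(config), seed = config$seed,
                   hashes = list(), timings = list(), files = list())
  res <- list()
  emit <- function(name, tbl) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, path)
    manifest$files[[name]] <<- unname(tools::md5sum(path))
  }

  config$configA$seed <- stage_seed(config$seed, 1L)
  config$configB$seed <- stage_seed(config$seed, 2L)

  st <- run_stage("generate", manifest,
                  generate_cohort_pair(config$configA, config$configB,
                                       config$shared_genes))
  pair <- st$value; manifest <- st$manifest

  st <- run_stage("features", manifest, {
    lapply(pair[c("A", "B")], function(coh)
      build_feature_matrix(coh$expression, coh$samples, gene_to_replace = "NFYA"))
  })
  feats <- st$value; manifest <- st$manifest

  st <- run_stage("modules", manifest, {
    list(A = detect_modules(feats$A, network_params(power = config$powerA)),
         B = detect_modules(feats$B, network_params(power = config$powerB)))
  })
  mods <- st$value; manifest <- st$manifest
  emit("modules_A", tidy(mods$A)); emit("modules_B", tidy(mods$B))

  st <- run_stage("signature", manifest, {
    sets <- purrr::imap(mods, function(m, nm) {
      rm_id <- find_ratio_module(m)
      names(m$labels)[m$labels == rm_id]
    })
    intersect_signatures(sets)
  })
  sig <- st$value; manifest <- st$manifest
  emit("signature", tibble::tibble(gene = sig$genes))

  st <- run_stage("scores", manifest, {
    purrr::imap(feats, function(f, nm) {
      sc <- score_samples(sig, zscore_matrix(f))
      dplyr::left_join(sc, pair[[nm]]$samples[, c("sample", "subtype")],
                       by = "sample")
    })
  })
  scores <- st$value; manifest <- st$manifest
  emit("scores_A", scores$A); emit("scores_B", scores$B)

  st <- run_stage("survival", manifest, {
    ftA <- isoform_features(feats$A)
    ratio_marker <- setNames(ftA$capped_ratio, ftA$sample)
    score_marker <- setNames(scores$A$score, scores$A$sample)
    list(
      ratio = scan_cutoffs(ratio_marker, pair$A$survival,
                           min_group_frac = config$min_group_frac,
                           n_permutations = config$n_permutations,
                           seed = stage_seed(config$seed, 3L)),
      signature_score = scan_cutoffs(score_marker, pair$A$survival,
                                     min_group_frac = config$min_group_frac,
                                     n_permutations = config$n_permutations,
                                     seed = stage_seed(config$seed, 4L))
    )
  })
  cutoffs <- st$value; manifest <- st$manifest
  emit("cutoff_scan_ratio", cutoffs$ratio$scan)
  emit("cutoff_scan_score", cutoffs$signature_score$scan)

  st <- run_stage("rbp", manifest, {
    cfg <- config$configA
    cfg$seed <- stage_seed(config$seed, 5L)
    sim <- generate_rbp_cohorts(cfg)
    screen <- rbp_screen(sim$cohorts, alpha = config$alpha)
    list(ranking = rank_rbps(screen, n_top = config$n_top), truth = sim$truth)
  })
  rbp <- st$value; manifest <- st$manifest
  emit("rbp_up", rbp$ranking$up); emit("rbp_down", rbp$ranking$down)

  st <- run_stage("deconvolution", manifest, {
    ref <- make_celltype_reference(config$n_cell_types, n_genes = 200L,
                                   seed = stage_seed(config$seed, 6L))
    set_generator_seed(stage_seed(config$seed, 7L))
    latent <- rnorm(config$n_mixture_samples)
    mix <- generate_mixture_samples(ref, config$n_mixture_samples,
                                    dirichlet_alpha = 2,
                                    noise_sd = config$mixture_noise_sd,
                                    seed = stage_seed(config$seed, 8L),
                                    trend_type = ncol(ref), trend_strength = 0.8,
                                    latent = latent)
    props <- estimate_proportions(mix$expression, ref)
    marker <- exp(latent)
    deciles <- decile_strata(marker)
    list(proportions = props,
         decile_means = average_by_stratum(props, deciles),
         truth = mix$proportions, marker = marker)
  })
  deconv <- st$value; manifest <- st$manifest
  emit("proportions", deconv$proportions)
  emit("decile_means", deconv$decile_means)

  res <- list(pair = pair, features = feats, modules = mods, signature = sig,
              scores = scores, cutoffs = cutoffs, rbp = rbp, deconv = deconv,
              manifest = manifest)
  if (!is.null(out_dir)) {
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      mpath <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest[c("seed", "hashes", "timings", "files")],
                           mpath, auto_unbox = TRUE, digits = NA)
    }
  }
  structure(res, class = "nfyar_pipeline")
}

#' @export
print.nfyar_pipeline <- function(x, ...) {
  cat(sprintf(paste0("<nfyar_pipeline> seed %d\n",
                     "  signature: %d genes; ratio cutoff %.3g (p = %.3g); ",
                     "score cutoff %.3g (p = %.3g)\n"),
              x$manifest$seed, length(x$signature$genes),
              x$cutoffs$ratio$cutoff, x$cutoffs$ratio$p_value,
              x$cutoffs$signature_score$cutoff, x$cutoffs$signature_score$p_value))
  invisible(x)
}
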
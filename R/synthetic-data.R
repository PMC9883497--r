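#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set describing one simulated tumour
#' cohort. The generator emulates the statistical structure the downstream
#' analysis assumes: a log-normal-ish TPM matrix with planted correlated gene
#' modules driven by latent factors, two splice isoforms of one gene whose
#' log abundances are coupled with opposite sign to the first module's factor
#' (so their ratio tracks the factor), subtype labels with one mesenchymal
#' ("ClaudinLow-like") label enriched among high-factor samples, and
#' exponential progression-free-interval times whose hazard increases for
#' high-factor samples under independent uniform censoring.
#'
#' On the log2(TPM + 1) scale, a gene g of module m is
#' `mu_g + lambda * f_m + N(0, noise_sd)` with `f_m ~ N(0, 1)` per sample;
#' the planted within-module Pearson correlation is therefore
#' `lambda^2 / (lambda^2 + noise_sd^2)`. Module 1 is the "ratio module": the
#' long isoform loads `+ratio_coupling` and the short isoform
#' `-ratio_coupling` on its factor. The defaults (two 50-gene modules,
#' `lambda = 1`, `noise_sd = 0.5`, 300 samples, log hazard ratio 0.9) give a
#' planted correlation of 0.8 and clearly separated survival groups.
#'
#' @param n_genes total number of genes in the expression matrix.
#' @param n_samples number of samples (tumours).
#' @param module_sizes integer vector of planted module sizes; the first
#'   module is the ratio module. `sum(module_sizes) <= n_genes`.
#' @param latent_loading loading `lambda >= 0` of module genes on their factor.
#' @param noise_sd residual standard deviation on the log2 scale, `> 0`.
#' @param ratio_coupling loading coupling the latent factor to
#'   `+log2(NF-YAl)` and `-log2(NF-YAs)`.
#' @param baseline_hazard exponential baseline hazard per unit time, `> 0`.
#' @param log_hazard_ratio log hazard ratio `beta` of the high-ratio
#'   (`f > 0`) group.
#' @param censor_horizon upper bound of the Uniform(0, horizon) censoring time.
#' @param n_subtypes number of subtype labels (the first is "ClaudinLow-like").
#' @param n_rbps_up,n_rbps_down numbers of RNA-binding proteins planted with
#'   positive / negative coupling to the ratio in [generate_rbp_cohorts()].
#' @param n_cohorts number of cohorts for the RBP simulation.
#' @param seed integer seed; identical config + seed gives bit-identical output.
#' @return a validated `nfyar_config` list.
#' @seealso [generate_cohort()], [generate_cohort_pair()]
#' @export
generator_config <- function(n_genes = 600L,
                             n_samples = 300L,
                             module_sizes = c(50L, 50L),
                             latent_loading = 1,
                             noise_sd = 0.5,
                             ratio_coupling = 1,
                             baseline_hazard = 0.1,
                             log_hazard_ratio = 0.9,
                             censor_horizon = 30,
                             n_subtypes = 4L,
                             n_rbps_up = 5L,
                             n_rbps_down = 5L,
                             n_cohorts = 21L,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    module_sizes = as.integer(module_sizes),
    latent_loading = latent_loading, noise_sd = noise_sd,
    ratio_coupling = ratio_coupling, baseline_hazard = baseline_hazard,
    log_hazard_ratio = log_hazard_ratio, censor_horizon = censor_horizon,
    n_subtypes = as.integer(n_subtypes),
    n_rbps_up = as.integer(n_rbps_up), n_rbps_down = as.integer(n_rbps_down),
    n_cohorts = as.integer(n_cohorts), seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "nfyar_config")
}

#' @noRd
validate_config <- function(cfg) {
  chk_count <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (length(v) < 1L || anyNA(v) || any(v < min))
      stop_config("config field `%s` must be >= %d", field, min)
  }
  for (f in c("n_genes", "n_samples", "n_subtypes", "n_cohorts")) chk_count(f)
  chk_count("module_sizes")
  for (f in c("n_rbps_up", "n_rbps_down")) chk_count(f, min = 0L)
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop_config("config field `module_sizes` sums to %d > n_genes = %d",
                sum(cfg$module_sizes), cfg$n_genes)
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop_config("config field `noise_sd` must be > 0")
  if (cfg$latent_loading < 0)
    stop_config("config field `latent_loading` must be >= 0")
  if (cfg$baseline_hazard <= 0)
    stop_config("config field `baseline_hazard` must be > 0")
  if (cfg$censor_horizon <= 0)
    stop_config("config field `censor_horizon` must be > 0")
  if (is.na(cfg$seed))
    stop_config("config field `seed` must be a finite integer")
  invisible(cfg)
}

#' @noRd
set_generator_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Generate one synthetic tumour cohort with planted ground truth
#'
#' Draws a cohort from the factor model described in [generator_config()].
#' Everything downstream (feature construction, module detection, signature
#' scoring, survival stratification) can be validated against the returned
#' `truth` component: planted module membership, per-sample latent factors,
#' and the true high-ratio label, which is defined as `f > 0` on the ratio
#' module's latent factor (i.e. independent of the realized noisy ratio).
#'
#' @param config an `nfyar_config` from [generator_config()].
#' @return an `nfyar_cohort` list with components
#'   * `expression`: genes x samples nonnegative TPM matrix (`n_genes`
#'     synthetic genes plus a gene-level `NFYA` row, the sum of the two
#'     isoform TPMs, which [build_feature_matrix()] replaces),
#'   * `samples`: tibble (sample, yal, yas, subtype) of per-sample isoform
#'     TPMs and subtype labels,
#'   * `survival`: tibble (sample, time, event) of progression-free interval,
#'   * `truth`: list with `modules` tibble (gene, module; 0 = background),
#'     `latent` samples x modules factor matrix, `high_ratio` logical vector,
#'     and the generating `config`.
#' @examples
#' coh <- generate_cohort(generator_config(n_genes = 80, n_samples = 40, seed = 7))
#' dim(coh$expression)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "nfyar_config")) config <- do.call(generator_config, config)
  validate_config(config)
  set_generator_seed(config$seed)
  n_g <- config$n_genes; n_s <- config$n_samples
  n_mod <- length(config$module_sizes)

  genes <- sprintf("G%06d", seq_len(n_g))
  samples <- sprintf("S%04d", seq_len(n_s))
  module_of <- integer(n_g)
  module_of[seq_len(sum(config$module_sizes))] <-
    rep(seq_len(n_mod), times = config$module_sizes)

  latent <- matrix(rnorm(n_s * n_mod), n_s, n_mod,
                   dimnames = list(samples, paste0("f", seq_len(n_mod))))
  mu <- runif(n_g, 3, 8)
  logx <- matrix(mu, n_g, n_s) +
    matrix(rnorm(n_g * n_s, sd = config$noise_sd), n_g, n_s)
  for (m in seq_len(n_mod)) {
    idx <- which(module_of == m)
    logx[idx, ] <- logx[idx, ] +
      config$latent_loading * matrix(latent[, m], length(idx), n_s, byrow = TRUE)
  }
  dimnames(logx) <- list(genes, samples)
  expression <- unlog_tpm(logx)

  f1 <- unname(latent[, 1])
  yal <- unlog_tpm(4 + config$ratio_coupling * f1 + rnorm(n_s, sd = config$noise_sd))
  yas <- unlog_tpm(4 - config$ratio_coupling * f1 + rnorm(n_s, sd = config$noise_sd))
  # gene-level abundance of the isoform-bearing gene: sum of its isoforms
  expression <- rbind(expression, NFYA = yal + yas)

  rate <- config$baseline_hazard * exp(config$log_hazard_ratio * (f1 > 0))
  event_time <- rexp(n_s, rate = rate)
  censor_time <- runif(n_s, 0, config$censor_horizon)
  surv <- tibble::tibble(
    sample = samples,
    time = pmin(event_time, censor_time),
    event = as.integer(event_time <= censor_time)
  )

  subtype_levels <- c("ClaudinLow-like",
                      paste0("Subtype", LETTERS[seq_len(config$n_subtypes - 1L)]))
  subtype <- vapply(f1, function(f) {
    w <- c(exp(1.5 * f), rep(1, config$n_subtypes - 1L))
    sample(subtype_levels, 1L, prob = w / sum(w))
  }, character(1))

  structure(list(
    expression = expression,
    samples = tibble::tibble(sample = samples, yal = yal, yas = yas,
                             subtype = subtype),
    survival = surv,
    truth = list(
      modules = tibble::tibble(gene = genes, module = module_of),
      latent = latent,
      high_ratio = setNames(f1 > 0, samples),
      config = config
    )
  ), class = "nfyar_cohort")
}

#' Generate a pair of cohorts whose ratio modules share a known gene set
#'
#' Two cohorts are drawn independently (each from its own config/seed) and
#' their gene identifiers rewritten so that exactly `shared_genes` genes of
#' the two ratio modules carry common names (`SH######`); every other gene is
#' cohort-private (`A_`/`B_` prefixes). This plants the ground truth for a
#' cross-cohort signature: the intersection of the two true ratio-module
#' gene sets has exactly `shared_genes` members.
#'
#' Defaults mirror the motivating analysis, where a 512-gene ratio module in
#' one cohort and a 2508-gene module in a second shared 158 genes.
#'
#' @param configA,configB `nfyar_config` objects for the two cohorts.
#' @param shared_genes number of common ratio-module genes; must not exceed
#'   either cohort's ratio-module size.
#' @return list of two `nfyar_cohort` objects (`A`, `B`) plus
#'   `shared` — the character vector of shared gene names.
#' @export
generate_cohort_pair <- function(configA = generator_config(n_genes = 800L,
                                                            module_sizes = c(512L, 50L)),
                                 configB = generator_config(n_genes = 3000L,
                                                            module_sizes = c(2508L, 50L),
                                                            seed = 2L),
                                 shared_genes = 158L) {
  shared_genes <- as.integer(shared_genes)
  for (cfg in list(configA, configB)) {
    if (shared_genes > cfg$module_sizes[1])
      stop_config("shared_genes = %d exceeds a ratio-module size of %d",
                  shared_genes, cfg$module_sizes[1])
  }
  a <- generate_cohort(configA)
  b <- generate_cohort(configB)
  shared <- if (shared_genes > 0) sprintf("SH%06d", seq_len(shared_genes)) else character(0)

  rename_cohort <- function(coh, prefix) {
    genes <- rownames(coh$expression)
    ratio_idx <- which(coh$truth$modules$module == 1L)
    new <- paste0(prefix, "_", genes)
    new[genes == "NFYA"] <- "NFYA"
    new[ratio_idx[seq_len(shared_genes)]] <- shared
    rownames(coh$expression) <- new
    coh$truth$modules$gene <- new[seq_len(nrow(coh$truth$modules))]
    coh
  }
  list(A = rename_cohort(a, "A"), B = rename_cohort(b, "B"), shared = shared)
}

#' Build a synthetic cell-type reference expression matrix
#'
#' Each cell type receives a block of marker genes expressed well above the
#' shared baseline, giving a full-column-rank genes x types reference on the
#' TPM scale suitable for least-squares deconvolution.
#'
#' @param n_types number of cell types (>= 2).
#' @param n_genes number of genes; at least `5 * n_types` recommended.
#' @param marker_fold fold elevation of a type's markers over baseline.
#' @param seed integer seed.
#' @return genes x types numeric matrix with dimnames; columns are cell types.
#' @export
make_celltype_reference <- function(n_types = 4L, n_genes = 200L,
                                    marker_fold = 8, seed = 1L) {
  n_types <- as.integer(n_types); n_genes <- as.integer(n_genes)
  if (n_types < 2L) stop_config("config field `n_types` must be >= 2")
  set_generator_seed(seed)
  base <- matrix(runif(n_genes * n_types, 1, 10), n_genes, n_types)
  block <- split(seq_len(n_genes), cut(seq_len(n_genes), n_types, labels = FALSE))
  for (t in seq_len(n_types)) base[block[[t]], t] <- base[block[[t]], t] * marker_fold
  dimnames(base) <- list(sprintf("G%06d", seq_len(n_genes)),
                         paste0("CellType", seq_len(n_types)))
  base
}

#' Mix bulk samples from a cell-type reference with known proportions
#'
#' Each bulk column is `reference %*% p + Normal(0, noise_sd)` clipped at 0,
#' with `p` drawn from a Dirichlet(alpha) and recorded as ground truth.
#' Optionally one cell type's proportion can be tilted monotonically along a
#' supplied latent vector (to plant, e.g., a rising mesenchymal fraction
#' across marker deciles): the Dirichlet draw is reweighted by
#' `exp(trend_strength * latent_s)` on that type and renormalized.
#'
#' @param reference genes x types reference matrix (see
#'   [make_celltype_reference()]).
#' @param n_samples number of bulk samples.
#' @param dirichlet_alpha Dirichlet concentration, scalar or per-type vector,
#'   all `> 0`.
#' @param noise_sd additive noise SD on the TPM scale (`>= 0`).
#' @param seed integer seed.
#' @param trend_type optional column name or index of the trended cell type.
#' @param trend_strength tilt strength per latent unit.
#' @param latent optional numeric vector (length `n_samples`) driving the tilt.
#' @return list with `expression` (genes x samples matrix) and `proportions`
#'   (tibble: sample plus one column per cell type, rows on the simplex).
#' @export
generate_mixture_samples <- function(reference, n_samples,
                                     dirichlet_alpha = 1, noise_sd = 0,
                                     seed = 1L, trend_type = NULL,
                                     trend_strength = 1, latent = NULL) {
  if (!is.matrix(reference) || ncol(reference) < 2L)
    stop_config("config field `reference` must be a genes x types matrix with >= 2 types")
  if (is.null(colnames(reference)))
    colnames(reference) <- paste0("CellType", seq_len(ncol(reference)))
  if (is.null(rownames(reference)))
    rownames(reference) <- sprintf("G%06d", seq_len(nrow(reference)))
  if (any(dirichlet_alpha <= 0))
    stop_config("config field `dirichlet_alpha` must be > 0")
  n_types <- ncol(reference)
  if (qr(reference)$rank < n_types)
    warn("reference matrix is rank-deficient; proportions may not be identifiable")
  alpha <- rep_len(dirichlet_alpha, n_types)
  set_generator_seed(seed)
  P <- t(vapply(seq_len(n_samples), function(s) {
    g <- rgamma(n_types, shape = alpha)
    g / sum(g)
  }, numeric(n_types)))
  if (!is.null(trend_type)) {
    if (is.null(latent)) stop_config("config field `latent` is required with `trend_type`")
    if (length(latent) != n_samples)
      stop_config("config field `latent` must have length n_samples")
    tt <- if (is.character(trend_type)) match(trend_type, colnames(reference)) else trend_type
    if (is.na(tt)) stop_config("config field `trend_type` not found in reference")
    P[, tt] <- P[, tt] * exp(trend_strength * latent)
    P <- P / rowSums(P)
  }
  samples <- sprintf("M%04d", seq_len(n_samples))
  bulk <- reference %*% t(P)
  if (noise_sd > 0)
    bulk <- bulk + matrix(rnorm(length(bulk), sd = noise_sd), nrow(bulk))
  bulk <- pmax(bulk, 0)
  colnames(bulk) <- samples
  props <- tibble::as_tibble(P, .name_repair = "minimal")
  names(props) <- colnames(reference)
  props <- dplyr::bind_cols(tibble::tibble(sample = samples), props)
  list(expression = bulk, proportions = props)
}

#' Simulate many small cohorts with planted RBP/ratio coupling
#'
#' Emulates a pan-cancer screen for splicing regulators: in each of
#' `n_cohorts` cohorts a per-sample latent factor drives the isoform ratio
#' (`ratio = exp(f + noise)`), planted "up" RBPs gain `+coupling * f` on
#' their log2 expression, "down" RBPs `-coupling * f`, and null RBPs are
#' pure noise. Ground truth directions are returned for precision checks on
#' the cross-cohort ranking.
#'
#' @param config an `nfyar_config`; `n_rbps_up`, `n_rbps_down`, `n_cohorts`
#'   and `noise_sd` are used.
#' @param n_rbps_null number of uncoupled RBPs.
#' @param n_samples samples per cohort.
#' @param coupling loading of planted RBPs on the latent factor.
#' @return list with `cohorts` — a named list, each element holding `ratio`
#'   (tibble: sample, ratio) and `expression` (RBPs x samples log2 matrix) —
#'   and `truth` (tibble: rbp, direction in {up, down, null}).
#' @export
generate_rbp_cohorts <- function(config = generator_config(),
                                 n_rbps_null = 40L, n_samples = 120L,
                                 coupling = 0.8) {
  validate_config(config)
  rbps <- c(sprintf("RBPU%02d", seq_len(config$n_rbps_up)),
            sprintf("RBPD%02d", seq_len(config$n_rbps_down)),
            sprintf("RBPN%02d", seq_len(n_rbps_null)))
  dir <- rep(c("up", "down", "null"),
             c(config$n_rbps_up, config$n_rbps_down, n_rbps_null))
  load <- c(rep(coupling, config$n_rbps_up),
            rep(-coupling, config$n_rbps_down), rep(0, n_rbps_null))
  set_generator_seed(config$seed)
  cohorts <- lapply(seq_len(config$n_cohorts), function(k) {
    samples <- sprintf("C%02dS%03d", k, seq_len(n_samples))
    f <- rnorm(n_samples)
    ratio <- exp(f + rnorm(n_samples, sd = 0.3))
    mu <- runif(length(rbps), 3, 8)
    expr <- matrix(mu, length(rbps), n_samples) +
      outer(load, f) +
      matrix(rnorm(length(rbps) * n_samples, sd = config$noise_sd), length(rbps))
    dimnames(expr) <- list(rbps, samples)
    list(ratio = tibble::tibble(sample = samples, ratio = ratio),
         expression = expr)
  })
  names(cohorts) <- sprintf("cohort%02d", seq_len(config$n_cohorts))
  list(cohorts = cohorts, truth = tibble::tibble(rbp = rbps, direction = dir))
}

#' Write a cohort's tables to plain-text files
#'
#' Writes expression (TSV, genes in rows, header = sample IDs), survival
#' (sample, time, event), sample annotations (sample, yal, yas, subtype) and
#' the ground truth (JSON) under `dir`.
#'
#' @param cohort an `nfyar_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nfyar_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth.json")
  )
  expr_tbl <- tibble::as_tibble(cohort$expression, rownames = "gene")
  readr::write_tsv(expr_tbl, paths[["expression"]])
  readr::write_tsv(cohort$samples, paths[["samples"]])
  readr::write_tsv(cohort$survival, paths[["survival"]])
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_input("writing truth.json requires the jsonlite package")
  jsonlite::write_json(list(
    modules = cohort$truth$modules,
    high_ratio = as.list(cohort$truth$high_ratio),
    config = unclass(cohort$truth$config)
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
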
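#' Locate the module carrying the isoform-ratio feature
#'
#' Returns the module label of the engineered `NFYAr` feature. The analysis
#' expects the long-isoform feature to share that module (the ratio being
#' driven mostly by long-isoform abundance); a warning is emitted when it
#' does not.
#'
#' @param partition an `nfyar_modules` object (or a named integer label
#'   vector) containing the `NFYAr` feature.
#' @return integer module id.
#' @export
find_ratio_module <- function(partition) {
  labels <- if (inherits(partition, "nfyar_modules")) partition$labels else partition
  if (!.NFYA_RATIO %in% names(labels))
    stop_input("partition does not contain the %s feature", .NFYA_RATIO)
  mod <- labels[[.NFYA_RATIO]]
  if (mod == 0L) stop_input("ratio feature unassigned (grey module)")
  if (.NFYA_LONG %in% names(labels) && labels[[.NFYA_LONG]] != mod)
    warn(sprintf("%s (module %d) and %s (module %d) are in different modules",
                 .NFYA_RATIO, mod, .NFYA_LONG, labels[[.NFYA_LONG]]))
  mod
}

#' Intersect ratio-module gene sets across cohorts into a signature
#'
#' Takes the per-cohort gene sets of the ratio-bearing modules, strips the
#' engineered feature names (`NFYA_long`, `NFYA_short`, `NFYAr`), and
#' returns their intersection — the cross-cohort signature of genes
#' co-expressed with the isoform ratio in every cohort.
#'
#' @param module_genes_by_cohort named list (>= 2 cohorts) of character
#'   vectors of module gene identifiers.
#' @return an `nfyar_signature` object: list with `genes` (character) and
#'   `provenance` (tibble: cohort, module_size). An empty intersection is
#'   returned with a warning, not an error.
#' @export
intersect_signatures <- function(module_genes_by_cohort) {
  if (length(module_genes_by_cohort) < 2L)
    stop_input("need module gene sets from at least 2 cohorts")
  cleaned <- purrr::map(module_genes_by_cohort,
                        ~ setdiff(unique(.x), engineered_feature_names()))
  genes <- purrr::reduce(cleaned, intersect)
  if (!length(genes)) warn("cohort modules have an empty intersection")
  cohorts <- names(module_genes_by_cohort) %||%
    paste0("cohort", seq_along(module_genes_by_cohort))
  structure(list(
    genes = genes,
    provenance = tibble::tibble(cohort = cohorts,
                                module_size = unname(lengths(cleaned)))
  ), class = "nfyar_signature")
}

#' @export
print.nfyar_signature <- function(x, ...) {
  cat(sprintf("<nfyar_signature> %d genes from %d cohorts (module sizes: %s)\n",
              length(x$genes), nrow(x$provenance),
              paste(x$provenance$module_size, collapse = ", ")))
  invisible(x)
}

#' Per-gene Z scores of a log-expression matrix
#'
#' Standardizes each gene over the chosen sample subset:
#' `(x - mean) / sd`, using the sample standard deviation (n - 1). Genes with
#' zero variance over the subset are dropped with a message.
#'
#' @param log_expr genes x samples matrix on the log2(TPM + 1) scale.
#' @param sample_subset character vector of sample names (default: all); the
#'   reference population of the Z scores.
#' @return genes x subset-samples matrix of Z scores.
#' @export
zscore_matrix <- function(log_expr, sample_subset = colnames(log_expr)) {
  check_expression_matrix(log_expr, "log_expr")
  if (!length(sample_subset)) stop_input("`sample_subset` is empty")
  missing <- setdiff(sample_subset, colnames(log_expr))
  if (length(missing)) stop_input("unknown samples in subset: %s",
                                  paste(head(missing, 3), collapse = ", "))
  x <- log_expr[, sample_subset, drop = FALSE]
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    inform(sprintf("dropping %d zero-variance gene(s) from Z matrix", sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (x - rowMeans(x)) / sds
}

#' Score samples by the median Z of a gene signature
#'
#' Each sample's score is the median of its Z scores over the signature genes
#' present in the Z matrix (even gene counts use the mean of the middle two).
#' Signature genes absent from the matrix are ignored with a message.
#'
#' @param signature an `nfyar_signature` or a character vector of genes.
#' @param z genes x samples Z matrix from [zscore_matrix()].
#' @return tibble (sample, score).
#' @export
score_samples <- function(signature, z) {
  genes <- if (inherits(signature, "nfyar_signature")) signature$genes else signature
  present <- intersect(genes, rownames(z))
  if (!length(present)) stop_input("no signature genes present in the Z matrix")
  if (length(present) < length(genes))
    inform(sprintf("%d signature gene(s) absent from the Z matrix",
                   length(genes) - length(present)))
  tibble::tibble(
    sample = colnames(z),
    score = unname(apply(z[present, , drop = FALSE], 2, median))
  )
}
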
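#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a module partition into a gene/module tibble
#'
#' @param x an `nfyar_modules` object.
#' @param ... unused.
#' @return tibble (gene, module); module 0 is unassigned.
#' @export
tidy.nfyar_modules <- function(x, ...) {
  tibble::tibble(gene = names(x$labels), module = unname(x$labels))
}

#' One-row summary of a module partition
#'
#' @param x an `nfyar_modules` object.
#' @param ... unused.
#' @return tibble (n_genes, n_modules, n_unassigned, largest_module,
#'   mean_var_explained).
#' @export
glance.nfyar_modules <- function(x, ...) {
  sizes <- table(x$labels[x$labels > 0L])
  tibble::tibble(
    n_genes = length(x$labels),
    n_modules = length(sizes),
    n_unassigned = sum(x$labels == 0L),
    largest_module = if (length(sizes)) max(sizes) else 0L,
    mean_var_explained = if (length(x$var_explained)) mean(x$var_explained) else NA_real_
  )
}

#' Tidy a cutoff scan into its candidate table
#'
#' @param x an `nfyar_cutoff` object.
#' @param ... unused.
#' @return tibble (cutoff, stat, p, n_low, n_high).
#' @export
tidy.nfyar_cutoff <- function(x, ...) x$scan

#' One-row summary of a cutoff scan
#'
#' @param x an `nfyar_cutoff` object.
#' @param ... unused.
#' @return tibble (cutoff, n_low, n_high, logrank_stat, p_value, p_adjusted).
#' @export
glance.nfyar_cutoff <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, n_low = x$n_low, n_high = x$n_high,
                 logrank_stat = x$logrank_stat, p_value = x$p_value,
                 p_adjusted = x$p_adjusted)
}

#' Tidy a signature into a gene tibble
#'
#' @param x an `nfyar_signature` object.
#' @param ... unused.
#' @return tibble (gene).
#' @export
tidy.nfyar_signature <- function(x, ...) tibble::tibble(gene = x$genes)

#' One-row summary of a cross-cohort signature
#'
#' @param x an `nfyar_signature` object.
#' @param ... unused.
#' @return tibble (n_genes, n_cohorts).
#' @export
glance.nfyar_signature <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), n_cohorts = nrow(x$provenance))
}

#' Tidy an RBP ranking into the per-RBP count table
#'
#' @param x an `nfyar_rbp_ranking` object.
#' @param ... unused.
#' @return tibble (rbp, tot_up, tot_down, ...).
#' @export
tidy.nfyar_rbp_ranking <- function(x, ...) x$counts
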
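#' Per-sample isoform ratio from long/short isoform abundances
#'
#' Computes `ratio = yal / yas` per sample. Samples whose short-isoform
#' abundance falls below `denom_floor` get a missing ratio rather than an
#' unstable division; missingness propagates (those samples are excluded)
#' downstream.
#'
#' @param yal,yas nonnegative per-sample TPM vectors of the long and short
#'   isoform, same length.
#' @param denom_floor minimum short-isoform TPM for the ratio to be defined
#'   (default 0.01 TPM).
#' @return numeric vector of ratios, `NA` where `yas < denom_floor`.
#' @examples
#' compute_ratio(c(10, 0, 5), c(5, 5, 0))
#' @export
compute_ratio <- function(yal, yas, denom_floor = 0.01) {
  if (length(yal) != length(yas))
    stop_input("`yal` and `yas` must have the same length (%d vs %d)",
               length(yal), length(yas))
  if (any(yal < 0, na.rm = TRUE) || any(yas < 0, na.rm = TRUE))
    stop_input("isoform abundances must be nonnegative")
  out <- ifelse(!is.na(yas) & yas >= denom_floor, yal / yas, NA_real_)
  out[is.na(yal)] <- NA_real_
  out
}

#' Cap ratio values at 1 for survival analysis
#'
#' Ratio values above 1 are set to 1 before cutoff scanning, so the scan is
#' driven by the informative low range rather than heavy right-tail values.
#' Missing values stay missing. Idempotent and monotone.
#'
#' @param ratio nonnegative (or missing) ratio vector.
#' @return vector with entries `min(ratio, 1)`.
#' @export
cap_ratio <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE))
    stop_input("`ratio` must be nonnegative")
  pmin(ratio, 1)
}

#' Build the isoform-augmented feature matrix
#'
#' Log-transforms the expression matrix (log2(TPM + 1)), removes the
#' gene-level row of the gene whose isoforms are analysed, and appends three
#' engineered rows: `NFYA_long`, `NFYA_short` and `NFYAr` (the uncapped
#' ratio). By default the three rows get the same log2(x + 1) transform as
#' every gene, so correlation-based network construction treats the ratio as
#' an ordinary gene; `ratio_transform = "identity"` keeps the ratio raw.
#' Samples whose ratio is missing (short isoform under the floor) are dropped
#' from all rows, with a message.
#'
#' @param expr genes x samples nonnegative TPM matrix.
#' @param samples tibble with columns `sample`, `yal`, `yas` (as produced by
#'   [generate_cohort()]); sample set must match `colnames(expr)`.
#' @param gene_to_replace identifier of the gene-level row to remove; a
#'   warning is emitted if absent.
#' @param denom_floor passed to [compute_ratio()].
#' @param ratio_transform `"log1p"` (default) or `"identity"` for the NFYAr row.
#' @return genes x samples numeric matrix on the log2 scale, with
#'   `nrow(expr) - 1 + 3` rows when the replaced gene exists, and an
#'   `isoform_features` attribute holding the per-sample feature tibble
#'   (sample, yal, yas, ratio, capped_ratio).
#' @export
build_feature_matrix <- function(expr, samples, gene_to_replace = "NFYA",
                                 denom_floor = 0.01,
                                 ratio_transform = c("log1p", "identity")) {
  check_expression_matrix(expr)
  ratio_transform <- match.arg(ratio_transform)
  req <- c("sample", "yal", "yas")
  if (!all(req %in% names(samples)))
    stop_input("`samples` must contain columns sample, yal, yas")
  if (!setequal(samples$sample, colnames(expr)))
    stop_input("sample sets of `expr` and `samples` differ")
  samples <- samples[match(colnames(expr), samples$sample), ]

  ratio <- compute_ratio(samples$yal, samples$yas, denom_floor)
  keep <- !is.na(ratio)
  if (!any(keep)) stop_input("no samples remain after dropping missing ratios")
  if (any(!keep))
    inform(sprintf("dropping %d sample(s) with missing isoform ratio", sum(!keep)))

  if (gene_to_replace %in% rownames(expr)) {
    expr <- expr[setdiff(rownames(expr), gene_to_replace), , drop = FALSE]
  } else {
    warn(sprintf("gene `%s` not found in expression matrix; nothing replaced",
                 gene_to_replace))
  }

  feat <- log_tpm(expr[, keep, drop = FALSE])
  ratio_row <- switch(ratio_transform,
                      log1p = log_tpm(ratio[keep]),
                      identity = ratio[keep])
  extra <- rbind(log_tpm(samples$yal[keep]), log_tpm(samples$yas[keep]), ratio_row)
  rownames(extra) <- engineered_feature_names()
  out <- rbind(feat, extra)
  attr(out, "isoform_features") <- tibble::tibble(
    sample = samples$sample,
    yal = samples$yal, yas = samples$yas,
    ratio = ratio, capped_ratio = cap_ratio(ratio)
  )
  out
}

#' Per-sample isoform feature table of a feature matrix
#'
#' @param feature_matrix output of [build_feature_matrix()].
#' @return tibble (sample, yal, yas, ratio, capped_ratio) covering all input
#'   samples, including those dropped for missing ratio.
#' @export
isoform_features <- function(feature_matrix) {
  ft <- attr(feature_matrix, "isoform_features")
  if (is.null(ft)) stop_input("matrix carries no isoform_features attribute")
  ft
}
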
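#' @noRd
stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "nfyar_input_error")

#' @noRd
stop_config <- function(msg, ...) abort(sprintf(msg, ...), class = "nfyar_config_error")

#' Check that an object is a genes-by-samples expression matrix
#' @noRd
check_expression_matrix <- function(x, arg = "expr") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_input("`%s` must be a numeric genes x samples matrix", arg)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_input("`%s` must have gene rownames and sample colnames", arg)
  invisible(x)
}

#' log2(x + 1) transform used throughout the analysis
#'
#' Expression is consumed on the log2(TPM + 1) scale; this helper and its
#' inverse are exported so synthetic data and features share one definition.
#'
#' @param x numeric vector or matrix of nonnegative TPM values.
#' @return transformed values, same shape.
#' @export
log_tpm <- function(x) log2(x + 1)

#' @rdname log_tpm
#' @export
unlog_tpm <- function(x) pmax(2^x - 1, 0)

#' Type-7 (linear interpolation) empirical quantile
#' @noRd
quantile7 <- function(x, p) unname(stats::quantile(x, probs = p, type = 7, names = FALSE))

#' Deterministic per-stage seed fan-out from one global seed
#'
#' Stage seeds are derived as `(seed * 1000 + offset) mod 2^31 - 1` so each
#' pipeline stage gets an independent, reproducible stream.
#' @noRd
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% (2^31 - 1))
}
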
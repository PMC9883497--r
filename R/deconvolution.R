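#' Nonnegative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0`. Used as the proportion
#' estimator behind [estimate_proportions()]; exported because the solver is
#' generally useful and directly testable against hand-solved systems.
#'
#' @param A numeric matrix (m x n, m >= 1).
#' @param b numeric vector of length m.
#' @param tol nonnegativity / gradient tolerance.
#' @return numeric vector x of length n, `x >= 0`.
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  gref <- max(abs(crossprod(A, b)), 1)
  for (outer_it in seq_len(10L * n + 10L)) {
    w <- as.numeric(crossprod(A, b - A %*% x))
    cand <- which(!passive)
    if (!length(cand) || max(w[cand]) <= tol * gref) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      coefs <- stats::lm.fit(A[, passive, drop = FALSE], b)$coefficients
      coefs[is.na(coefs)] <- 0
      s[passive] <- coefs
      if (all(s[passive] > tol)) { x <- s; break }
      q <- passive & (s <= tol)
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
  }
  setNames(pmax(x, 0), colnames(A))
}

#' Estimate cell-type proportions of bulk samples by constrained least squares
#'
#' For each bulk sample, regresses its expression over the genes shared with
#' the reference on the reference's cell-type columns under a nonnegativity
#' constraint, then normalizes the coefficients to sum to 1. This is a
#' deliberately simple, fully specified stand-in for ensemble deconvolution
#' tools: the downstream use is only average proportions per stratum.
#'
#' @param bulk genes x samples nonnegative expression matrix (TPM scale).
#' @param reference genes x cell-types nonnegative reference matrix.
#' @return tibble: `sample` plus one proportion column per cell type; each
#'   row is on the simplex. An all-zero fit yields uniform proportions with
#'   a warning.
#' @export
estimate_proportions <- function(bulk, reference) {
  check_expression_matrix(bulk, "bulk")
  if (!is.matrix(reference) || is.null(rownames(reference)) ||
      is.null(colnames(reference)))
    stop_input("`reference` must be a genes x cell-types matrix with dimnames")
  n_types <- ncol(reference)
  shared <- intersect(rownames(bulk), rownames(reference))
  if (length(shared) < n_types)
    stop_input("only %d gene(s) shared between bulk and reference (< %d types)",
               length(shared), n_types)
  if (length(shared) < 5L * n_types)
    warn(sprintf("only %d shared genes for %d cell types; estimates may be unstable",
                 length(shared), n_types))
  A <- reference[shared, , drop = FALSE]
  B <- bulk[shared, , drop = FALSE]
  P <- t(vapply(seq_len(ncol(B)), function(s) {
    x <- nnls_solve(A, B[, s])
    tot <- sum(x)
    if (tot <= 0) {
      warn(sprintf("sample %s: all-zero fit; returning uniform proportions",
                   colnames(B)[s]))
      rep(1 / n_types, n_types)
    } else x / tot
  }, numeric(n_types)))
  out <- tibble::as_tibble(P, .name_repair = "minimal")
  names(out) <- colnames(reference)
  dplyr::bind_cols(tibble::tibble(sample = colnames(B)), out)
}

#' Assign samples to marker deciles
#'
#' Decile boundaries are the 0.1, ..., 0.9 linear-interpolation quantiles of
#' the non-missing marker values; ties at a boundary go to the lower decile.
#'
#' @param ratio per-sample marker (>= 10 non-missing values).
#' @return integer decile labels 1..10 aligned with the input (NA preserved).
#' @export
decile_strata <- function(ratio) {
  ok <- !is.na(ratio)
  if (sum(ok) < 10L) stop_input("need >= 10 non-missing values for deciles")
  x <- ratio[ok]
  if (length(unique(x)) < 2L) stop_input("degenerate marker: all values identical")
  b <- quantile7(x, seq(0.1, 0.9, by = 0.1))
  breaks <- c(-Inf, unique(b), Inf)
  lab <- cut(x, breaks = breaks, labels = FALSE, right = TRUE)
  if (length(breaks) < 11L) {
    # heavy ties collapsed one or more boundaries; map back to 1..10 positions
    lab <- match(breaks[lab + 1L], c(b, Inf))
  }
  out <- rep(NA_integer_, length(ratio))
  out[ok] <- as.integer(lab)
  out
}

#' Average cell-type proportions within strata
#'
#' @param props proportion tibble from [estimate_proportions()] (`sample`
#'   plus per-type columns).
#' @param labels stratum labels aligned with the rows of `props`; a factor's
#'   empty levels are reported as all-missing rows with a warning.
#' @return tibble: `stratum` plus one mean-proportion column per cell type;
#'   rows of non-empty strata are on the simplex.
#' @export
average_by_stratum <- function(props, labels) {
  if (length(labels) != nrow(props)) stop_input("`labels` must align with `props` rows")
  type_cols <- setdiff(names(props), "sample")
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(labels[!is.na(labels)]))
  rows <- purrr::map(lv, function(s) {
    idx <- which(!is.na(labels) & labels == s)
    if (!length(idx)) {
      warn(sprintf("stratum %s is empty", s))
      vals <- rep(NA_real_, length(type_cols))
    } else {
      vals <- colMeans(props[idx, type_cols, drop = FALSE])
    }
    tibble::tibble(stratum = s, !!!setNames(as.list(vals), type_cols))
  })
  dplyr::bind_rows(rows)
}

#' Partition samples by subtype and within-subtype high ratio
#'
#' Within each subtype independently, samples in the fourth quartile of the
#' marker form the "highQ4" group and the rest "rest" (see
#' [quartile_groups()]); subtypes with fewer than 8 samples are kept whole
#' as "rest" with a warning.
#'
#' @param subtypes per-sample subtype labels (complete).
#' @param ratio per-sample marker, aligned.
#' @return tibble (subtype, ratio_group, stratum) row-aligned with the input;
#'   `stratum` is `"<subtype>.<group>"`.
#' @export
subtype_partition <- function(subtypes, ratio) {
  if (length(subtypes) != length(ratio)) stop_input("`subtypes`/`ratio` length mismatch")
  if (anyNA(subtypes)) stop_input("subtype labels must be complete")
  group <- rep(NA_character_, length(ratio))
  for (st in unique(subtypes)) {
    idx <- which(subtypes == st)
    if (sum(!is.na(ratio[idx])) < 8L) {
      warn(sprintf("subtype %s has < 8 samples with marker values; all kept as rest", st))
      group[idx] <- "rest"
    } else {
      qg <- quartile_groups(ratio[idx])
      group[idx] <- dplyr::if_else(qg == "high", "highQ4", "rest")
    }
  }
  tibble::tibble(subtype = subtypes, ratio_group = group,
                 stratum = paste(subtypes, group, sep = "."))
}
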
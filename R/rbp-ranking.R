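#' Split samples into fourth-quartile ("high") and remaining ("low") groups
#'
#' High-ratio samples are those at or above the 0.75 empirical quantile of
#' the marker (linear-interpolation quantile; ties at the boundary all go
#' high); all other samples form the low group. Missing values get a missing
#' label.
#'
#' @param ratio per-sample marker values (>= 8 non-missing).
#' @return character vector in {"high", "low"} aligned with the input.
#' @examples
#' quartile_groups(1:8)
#' @export
quartile_groups <- function(ratio) {
  ok <- !is.na(ratio)
  if (sum(ok) < 8L) stop_input("need >= 8 non-missing values for quartile grouping")
  x <- ratio[ok]
  if (length(unique(x)) < 2L) stop_input("degenerate marker: all values identical")
  q75 <- quantile7(x, 0.75)
  out <- rep(NA_character_, length(ratio))
  out[ok] <- ifelse(x >= q75, "high", "low")
  out
}

#' Two-sided Wilcoxon rank-sum p value
#'
#' Exact by enumeration of rank-sum assignments when the smaller group has at
#' most `exact_max` observations and the data carry no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_max largest small-group size for exact enumeration.
#' @return list with `p_value`, `statistic` (Mann-Whitney U of `x`), and
#'   `method` ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop_input("both groups must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && min(n1, n2) <= exact_max) {
    small <- min(n1, n2)
    combos <- utils::combn(N, small)
    Wall <- colSums(matrix(seq_len(N)[combos], nrow = small))
    mu <- small * (N + 1) / 2
    W_small <- if (n1 <= n2) W else sum(r[-seq_len(n1)])
    p <- mean(abs(Wall - mu) >= abs(W_small - mu) - 1e-9)
    return(list(p_value = p, statistic = U, method = "exact"))
  }
  mu <- n1 * (N + 1) / 2
  tie_sizes <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(p_value = 1, statistic = U, method = "normal"))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  list(p_value = min(1, 2 * pnorm(-abs(z))), statistic = U, method = "normal")
}

#' Test one RNA-binding protein for differential expression between groups
#'
#' Two-sided Wilcoxon rank-sum test of the RBP's expression in high- versus
#' low-ratio samples. Direction is "up" when the high-group median exceeds
#' the low-group median, "down" when below; with tied medians the result is
#' never significant regardless of p.
#'
#' @param values per-sample expression of the RBP.
#' @param groups labels from [quartile_groups()] ("high"/"low"), aligned.
#' @param alpha per-cohort significance level (default 0.05, uncorrected, as
#'   is conventional for this screen).
#' @return one-row tibble (p_value, direction, significant, statistic, method).
#' @export
rbp_test <- function(values, groups, alpha = 0.05) {
  if (length(values) != length(groups)) stop_input("`values`/`groups` length mismatch")
  ok <- !is.na(values) & !is.na(groups)
  hi <- values[ok & groups == "high"]; lo <- values[ok & groups == "low"]
  if (length(hi) < 2L || length(lo) < 2L)
    stop_input("each group needs >= 2 observations (got %d/%d)",
               length(hi), length(lo))
  wt <- wilcoxon_rank_sum(hi, lo)
  mh <- median(hi); ml <- median(lo)
  direction <- if (mh > ml) "up" else if (mh < ml) "down" else NA_character_
  tibble::tibble(p_value = wt$p_value, direction = direction,
                 significant = !is.na(direction) && wt$p_value < alpha,
                 statistic = wt$statistic, method = wt$method)
}

#' Run the RBP screen over a set of cohorts
#'
#' For each cohort, samples are split by [quartile_groups()] on the ratio and
#' every RBP is tested with [rbp_test()].
#'
#' @param cohorts named list; each element has `ratio` (tibble: sample,
#'   ratio) and `expression` (RBPs x samples matrix), as produced by
#'   [generate_rbp_cohorts()].
#' @param rbps character vector of RBP identifiers (default: all rows of the
#'   first cohort). Missing (rbp, cohort) pairs are skipped with a message.
#' @param alpha per-cohort significance level.
#' @return tibble (rbp, cohort, p_value, direction, significant).
#' @export
rbp_screen <- function(cohorts, rbps = NULL, alpha = 0.05) {
  if (is.null(rbps)) rbps <- rownames(cohorts[[1]]$expression)
  cohort_names <- names(cohorts) %||% paste0("cohort", seq_along(cohorts))
  res <- purrr::imap(cohorts, function(coh, nm) {
    groups <- quartile_groups(coh$ratio$ratio)
    names(groups) <- coh$ratio$sample
    present <- intersect(rbps, rownames(coh$expression))
    if (length(present) < length(rbps))
      inform(sprintf("cohort %s: %d RBP(s) absent", nm, length(rbps) - length(present)))
    purrr::map(present, function(rb) {
      dplyr::mutate(
        rbp_test(coh$expression[rb, coh$ratio$sample], groups[coh$ratio$sample],
                 alpha = alpha),
        rbp = rb, cohort = nm, .before = 1)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(res)
}

#' Rank RBPs by the number of cohorts with significant shifts
#'
#' Counts, per RBP, the cohorts in which it is significantly up ("Tot UP")
#' or down ("Tot DOWN") in high-ratio samples, and returns the top tables
#' sorted by those counts (ties broken by the opposite count ascending, then
#' identifier).
#'
#' @param results tibble from [rbp_screen()] (rbp, cohort, p_value,
#'   direction, significant).
#' @param n_top rows kept in each table (default 20).
#' @param motif optional tibble (rbp, motif_present) carried through as an
#'   annotation.
#' @return an `nfyar_rbp_ranking` object: list with `up` and `down` tibbles
#'   (rbp, tot_up, tot_down, and motif_present if given), `counts` (all
#'   RBPs), and `flags` (tibble rbp, cohort, flag in {1, -1, 0}).
#' @export
rank_rbps <- function(results, n_top = 20L, motif = NULL) {
  counts <- results |>
    dplyr::group_by(.data$rbp) |>
    dplyr::summarise(
      tot_up = sum(.data$significant & .data$direction == "up", na.rm = TRUE),
      tot_down = sum(.data$significant & .data$direction == "down", na.rm = TRUE),
      .groups = "drop")
  if (!is.null(motif)) counts <- dplyr::left_join(counts, motif, by = "rbp")
  up <- counts |>
    dplyr::arrange(dplyr::desc(.data$tot_up), .data$tot_down, .data$rbp) |>
    head(n_top)
  down <- counts |>
    dplyr::arrange(dplyr::desc(.data$tot_down), .data$tot_up, .data$rbp) |>
    head(n_top)
  flags <- results |>
    dplyr::mutate(flag = dplyr::case_when(
      .data$significant & .data$direction == "up" ~ 1L,
      .data$significant & .data$direction == "down" ~ -1L,
      TRUE ~ 0L)) |>
    dplyr::select("rbp", "cohort", "flag")
  structure(list(up = up, down = down, counts = counts, flags = flags),
            class = "nfyar_rbp_ranking")
}

#' @export
print.nfyar_rbp_ranking <- function(x, ...) {
  cat(sprintf("<nfyar_rbp_ranking> %d RBPs over %d cohorts; top up: %s\n",
              nrow(x$counts), length(unique(x$flags$cohort)),
              paste(head(x$up$rbp, 3), collapse = ", ")))
  invisible(x)
}
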
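#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve. The curve is right-continuous,
#' starts at S(0) = 1 and drops only at event times; a censored-only input
#' yields S identically 1.
#'
#' @param times nonnegative follow-up times.
#' @param events event indicators (1 = progression event, 0 = censored).
#' @return tibble (time, n_risk, n_event, n_censor, survival), one row per
#'   distinct observed time, `survival` being S(t) just after `time`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 0))
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop_input("`times` is empty")
  if (length(times) != length(events)) stop_input("`times`/`events` length mismatch")
  if (any(times < 0)) stop_input("negative survival time")
  if (!all(events %in% c(0, 1))) stop_input("`events` must be 0/1")
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                 n_censor = n_censor, survival = surv)
}

#' @noRd
as_survival_table <- function(x, arg = "surv") {
  if (!is.data.frame(x) || !all(c("time", "event") %in% names(x)))
    stop_input("`%s` must be a data frame with columns time and event", arg)
  if (any(x$time < 0)) stop_input("negative survival time in `%s`", arg)
  if (!all(x$event %in% c(0, 1))) stop_input("`%s$event` must be 0/1", arg)
  x
}

#' Two-sided log-rank test between two survival tables
#'
#' Standard 1-degree-of-freedom log-rank chi-square: at each distinct event
#' time a 2 x 2 hypergeometric table contributes observed-minus-expected
#' events and a variance term for group A;
#' `stat = (sum(O_A - E_A))^2 / sum(V)` with the p value from the upper tail
#' of chi-square(1).
#'
#' @param groupA,groupB data frames with columns `time` and `event`.
#' @return list with `statistic`, `p_value`, and `n` (c(nA, nB)).
#' @export
logrank_test <- function(groupA, groupB) {
  groupA <- as_survival_table(groupA, "groupA")
  groupB <- as_survival_table(groupB, "groupB")
  if (!nrow(groupA) || !nrow(groupB)) stop_input("both groups must be nonempty")
  time <- c(groupA$time, groupB$time)
  event <- c(groupA$event, groupB$event)
  inA <- rep(c(TRUE, FALSE), c(nrow(groupA), nrow(groupB)))
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) {
    warn("no events in either group; log-rank statistic is 0")
    return(list(statistic = 0, p_value = 1, n = c(nrow(groupA), nrow(groupB))))
  }
  u <- 0; v <- 0
  for (t in dt) {
    at_risk <- time >= t
    n_k <- sum(at_risk); nA <- sum(at_risk & inA)
    d_k <- sum(time == t & event == 1)
    dA <- sum(time == t & event == 1 & inA)
    u <- u + dA - d_k * nA / n_k
    if (n_k > 1)
      v <- v + d_k * (nA / n_k) * (1 - nA / n_k) * (n_k - d_k) / (n_k - 1)
  }
  stat <- if (v > 0) u^2 / v else 0
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       n = c(nrow(groupA), nrow(groupB)))
}

#' Exhaustive log-rank cutoff scan of a continuous marker
#'
#' Emulates optimal-cutpoint dichotomization of progression-free interval:
#' candidate cutoffs are the midpoints between consecutive distinct sorted
#' marker values whose split leaves both groups at least
#' `min_group_frac * n` samples; each candidate is scored by the two-sided
#' log-rank test between `low = marker <= c` and `high = marker > c`; the
#' optimum minimizes p (ties broken by larger statistic, then smaller
#' cutoff). The headline `p_value` is the naive minimum over the scan, as in
#' the web tool this mirrors; with `n_permutations > 0` a permutation-adjusted
#' p (marker relabelled against survival, min-p recomputed) quantifies the
#' selection optimism of that minimum.
#'
#' Missing marker values are excluded. For an isoform-ratio marker, apply
#' [cap_ratio()] upstream.
#'
#' @param marker per-sample marker: a named numeric vector or a two-column
#'   data frame (sample, value).
#' @param surv data frame (sample, time, event).
#' @param min_group_frac minimum group fraction in (0, 0.5) (default 0.1).
#' @param n_permutations permutations for the adjusted p (0 = skip).
#' @param seed seed for the permutations.
#' @return an `nfyar_cutoff` object: list with `cutoff`, `n_low`, `n_high`,
#'   `logrank_stat`, `p_value`, `p_adjusted`, `scan` (tibble: cutoff, stat,
#'   p, n_low, n_high), `km` (tibble of per-group Kaplan-Meier curves at the
#'   optimum), and `n` (samples analysed).
#' @export
scan_cutoffs <- function(marker, surv, min_group_frac = 0.1,
                         n_permutations = 0L, seed = 1L) {
  if (is.data.frame(marker)) {
    if (ncol(marker) < 2L) stop_input("`marker` data frame needs (sample, value)")
    marker <- setNames(as.numeric(marker[[2]]), marker[[1]])
  }
  surv <- as_survival_table(surv)
  if (anyDuplicated(surv$sample)) stop_input("duplicate samples in `surv`")
  if (!is.null(names(marker)) && !is.null(surv$sample)) {
    common <- intersect(names(marker), surv$sample)
    if (!length(common)) stop_input("no samples shared between marker and survival")
    marker <- marker[common]
    surv <- surv[match(common, surv$sample), ]
  } else if (length(marker) != nrow(surv)) {
    stop_input("unnamed marker must align with `surv` rows")
  }
  keep <- !is.na(marker)
  marker <- marker[keep]; surv <- surv[keep, ]
  n <- length(marker)
  if (min_group_frac <= 0 || min_group_frac >= 0.5)
    stop_input("`min_group_frac` must be in (0, 0.5)")
  if (length(unique(marker)) < 2L) stop_input("no valid cutoff: constant marker")

  o <- order(marker)
  mk <- marker[o]; time <- surv$time[o]; event <- surv$event[o]
  min_n <- ceiling(min_group_frac * n)
  distinct_boundary <- which(diff(mk) > 0)
  J <- distinct_boundary[distinct_boundary >= min_n &
                           (n - distinct_boundary) >= min_n]
  if (!length(J)) stop_input("no valid cutoff: no admissible split")

  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) warn("no events; all log-rank statistics are 0")
  if (length(dt)) {
    # samples (marker order) x event times; cumulating down a column gives the
    # risk-set / event count of the "low" group for every split position at once
    RISKt <- outer(time, dt, `>=`) * 1
    EVt <- outer(time, dt, `==`) * event
    d <- colSums(EVt); nk <- colSums(RISKt)
    cfac <- ifelse(nk > 1, d * (nk - d) / ((nk - 1) * nk^2), 0)
    scan_stat <- function(row_perm) {
      cr <- apply(RISKt[row_perm, , drop = FALSE], 2, cumsum)
      ce <- apply(EVt[row_perm, , drop = FALSE], 2, cumsum)
      U <- rowSums(ce) - as.numeric(cr %*% (d / nk))
      V <- as.numeric(cr %*% (cfac * nk)) - as.numeric((cr * cr) %*% cfac)
      ifelse(V[J] > 0, U[J]^2 / V[J], 0)
    }
    stats_obs <- scan_stat(seq_len(n))
  } else {
    scan_stat <- function(row_perm) rep(0, length(J))
    stats_obs <- rep(0, length(J))
  }
  p_obs <- pchisq(stats_obs, df = 1, lower.tail = FALSE)
  cuts <- unname((mk[J] + mk[J + 1]) / 2)
  scan <- tibble::tibble(cutoff = cuts, stat = stats_obs, p = p_obs,
                         n_low = J, n_high = n - J)
  best <- order(scan$p, -scan$stat, scan$cutoff)[1]

  p_adj <- NA_real_
  if (n_permutations > 0L) {
    # min p over the scan is a monotone function of the max statistic, so the
    # permutation comparison works on statistics directly
    set_generator_seed(seed)
    obs_max <- max(scan$stat)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      if (max(scan_stat(sample.int(n))) >= obs_max - 1e-12) hits <- hits + 1L
    }
    p_adj <- (1 + hits) / (1 + n_permutations)
  }

  low <- o[seq_len(J[best])]; high <- o[-seq_len(J[best])]
  km <- dplyr::bind_rows(
    dplyr::mutate(km_estimate(surv$time[low], surv$event[low]), group = "low"),
    dplyr::mutate(km_estimate(surv$time[high], surv$event[high]), group = "high")
  )
  structure(list(cutoff = scan$cutoff[best],
                 n_low = scan$n_low[best], n_high = scan$n_high[best],
                 logrank_stat = scan$stat[best], p_value = scan$p[best],
                 p_adjusted = p_adj, n_permutations = as.integer(n_permutations),
                 scan = scan, km = km, n = n),
            class = "nfyar_cutoff")
}

#' @export
print.nfyar_cutoff <- function(x, ...) {
  cat(sprintf(paste0("<nfyar_cutoff> optimal cutoff %.4g (n_low = %d, n_high = %d)\n",
                     "  log-rank chi-square = %.3f, naive p = %.3g"),
              x$cutoff, x$n_low, x$n_high, x$logrank_stat, x$p_value))
  if (!is.na(x$p_adjusted))
    cat(sprintf(", permutation-adjusted p = %.3g (%d permutations)",
                x$p_adjusted, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Reference prognostic thresholds from the motivating TCGA analysis
#'
#' Documented constants, not reproduced by this package (they require the
#' TCGA BRCA/STAD cohorts): the optimal progression-free-interval cutoffs
#' were 0.86 (BRCA isoform ratio), 0.27 (STAD isoform ratio), 1.13 (BRCA
#' signature median Z) and -0.60 (STAD signature median Z).
#'
#' @return tibble (cohort, marker, cutoff).
#' @export
reference_cutoffs <- function() {
  tibble::tibble(
    cohort = c("BRCA", "STAD", "BRCA", "STAD"),
    marker = c("ratio", "ratio", "signature_score", "signature_score"),
    cutoff = c(0.86, 0.27, 1.13, -0.60)
  )
}
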
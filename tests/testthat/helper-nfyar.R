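# Adjusted Rand index between two label vectors (independent of any package
# clustering code; straight from the contingency-table closed form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small, fast cohort configuration for unit tests.
tiny_config <- function(seed = 1L, ...) {
  generator_config(n_genes = 120L, n_samples = 60L, module_sizes = c(30L, 30L),
                   seed = seed, ...)
}

# Brute-force log-rank statistic: explicit 2x2 hypergeometric table at every
# distinct event time. Used as the independent oracle for logrank_test and
# scan_cutoffs.
brute_logrank <- function(timeA, eventA, timeB, eventB) {
  time <- c(timeA, timeB); event <- c(eventA, eventB)
  inA <- rep(c(TRUE, FALSE), c(length(timeA), length(timeB)))
  u <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    atrisk <- time >= t
    n <- sum(atrisk); nA <- sum(atrisk & inA)
    d <- sum(time == t & event == 1)
    dA <- sum(time == t & event == 1 & inA)
    u <- u + dA - d * nA / n
    if (n > 1) v <- v + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  if (v > 0) u^2 / v else 0
}
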
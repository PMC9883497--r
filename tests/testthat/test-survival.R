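test_that("Kaplan-Meier estimator matches product-limit arithmetic", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(km_estimate(c(2, 4, 6), c(0, 0, 0))$survival, rep(1, 3))
  km1 <- km_estimate(5, 1)
  expect_equal(km1$survival, 0)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM curve is a valid survival function and agrees with survfit", {
  skip_if_not_installed("survival")
  set.seed(8)
  tm <- round(rexp(40, 0.2), 1); ev <- rbinom(40, 1, 0.6)
  km <- km_estimate(tm, ev)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  expect_equal(km$survival[match(sf$time, km$time)], sf$surv, tolerance = 1e-12)
})

test_that("log-rank test matches hand calculation and the survdiff oracle", {
  A <- data.frame(time = c(1, 3), event = c(1, 1))
  B <- data.frame(time = c(2, 4), event = c(1, 1))
  res <- logrank_test(A, B)
  # hand-worked hypergeometric tables: U = 1/2 - 1/3 + 1/2 = 2/3,
  # V = 1/4 + 2/9 + 1/4 = 13/18, stat = (2/3)^2 / (13/18) = 8/13
  expect_equal(res$statistic, 8 / 13, tolerance = 1e-12)
  expect_equal(res$statistic, brute_logrank(A$time, A$event, B$time, B$event),
               tolerance = 1e-12)

  # identical groups carry no signal
  same <- data.frame(time = c(1, 2, 5), event = c(1, 0, 1))
  expect_equal(logrank_test(same, same)$statistic, 0)
  expect_equal(logrank_test(same, same)$p_value, 1)

  # label swap invariance
  expect_equal(logrank_test(A, B)$statistic, logrank_test(B, A)$statistic)

  expect_error(logrank_test(A[0, ], B), "nonempty")
  expect_warning(r0 <- logrank_test(data.frame(time = 1, event = 0),
                                    data.frame(time = 2, event = 0)),
                 "no events")
  expect_equal(r0$p_value, 1)
})

test_that("log-rank agrees with survdiff across random datasets", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (i in 1:25) {
    nA <- sample(4:20, 1); nB <- sample(4:20, 1)
    A <- data.frame(time = rexp(nA), event = rbinom(nA, 1, 0.7))
    B <- data.frame(time = 1.4 * rexp(nB), event = rbinom(nB, 1, 0.7))
    if (sum(A$event) + sum(B$event) == 0) next
    d <- rbind(cbind(A, g = 0), cbind(B, g = 1))
    oracle <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
    expect_equal(logrank_test(A, B)$statistic, oracle$chisq, tolerance = 1e-8)
  }
})

test_that("a pre-first-event censored sample acts only through risk sets", {
  A <- data.frame(time = c(2, 5, 7), event = c(1, 1, 0))
  B <- data.frame(time = c(3, 6), event = c(1, 1))
  base <- logrank_test(A, B)$statistic
  # censored strictly before the first event: never at risk, statistic unchanged
  A2 <- rbind(A, data.frame(time = 1, event = 0))
  expect_equal(logrank_test(A2, B)$statistic, base, tolerance = 1e-12)
  expect_equal(logrank_test(A2, B)$statistic,
               brute_logrank(A2$time, A2$event, B$time, B$event),
               tolerance = 1e-12)
  # censored at the first event time: enters that risk set, statistic moves
  A3 <- rbind(A, data.frame(time = 2, event = 0))
  expect_false(isTRUE(all.equal(base, logrank_test(A3, B)$statistic)))
  expect_equal(logrank_test(A3, B)$statistic,
               brute_logrank(A3$time, A3$event, B$time, B$event),
               tolerance = 1e-12)
})

test_that("scan_cutoffs picks the hand-derived optimum among admissible splits", {
  mk <- setNames(c(0.1, 0.2, 0.8, 0.9), paste0("s", 1:4))
  sv <- data.frame(sample = paste0("s", 1:4),
                   time = c(10, 9, 1, 2), event = c(0, 0, 1, 1))
  sc <- scan_cutoffs(mk, sv, min_group_frac = 0.25)
  expect_equal(sc$cutoff, 0.5)
  expect_equal(nrow(sc$scan), 3L)
  # every scanned statistic equals the standalone log-rank test
  for (k in seq_len(nrow(sc$scan))) {
    cc <- sc$scan$cutoff[k]
    lo <- sv[mk <= cc, ]; hi <- sv[mk > cc, ]
    expect_equal(sc$scan$stat[k], suppressWarnings(logrank_test(lo, hi))$statistic,
                 tolerance = 1e-12)
  }
  expect_error(scan_cutoffs(setNames(rep(1, 10), paste0("s", 1:10)),
                            data.frame(sample = paste0("s", 1:10),
                                       time = 1:10, event = rep(1, 10))),
               "constant marker")
})

test_that("single admissible candidate reproduces logrank_test exactly", {
  mk <- setNames(c(1, 1, 1, 2, 2, 2), paste0("s", 1:6))
  sv <- data.frame(sample = paste0("s", 1:6),
                   time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 1, 0, 1))
  sc <- scan_cutoffs(mk, sv, min_group_frac = 0.3)
  expect_identical(nrow(sc$scan), 1L)
  lr <- logrank_test(sv[mk <= 1.5, ], sv[mk > 1.5, ])
  expect_equal(sc$logrank_stat, lr$statistic, tolerance = 1e-12)
  expect_equal(sc$p_value, lr$p_value, tolerance = 1e-12)
})

test_that("permutation-adjusted p is reproducible and exceeds the naive minimum", {
  set.seed(12)
  n <- 80
  mk <- setNames(runif(n), paste0("s", 1:n))
  sv <- data.frame(sample = names(mk), time = rexp(n, 0.1),
                   event = rbinom(n, 1, 0.7))
  sc1 <- scan_cutoffs(mk, sv, n_permutations = 99, seed = 5)
  sc2 <- scan_cutoffs(mk, sv, n_permutations = 99, seed = 5)
  expect_identical(sc1$p_adjusted, sc2$p_adjusted)
  expect_gte(sc1$p_adjusted, sc1$p_value)
  expect_true(sc1$p_adjusted > 0 & sc1$p_adjusted <= 1)
})

test_that("scan recovers a planted step-hazard threshold", {
  set.seed(77)
  n <- 500
  marker <- cap_ratio(exp(rnorm(n)))
  names(marker) <- paste0("s", 1:n)
  tau <- 0.5
  rate <- 0.05 * exp(0.9 * (marker > tau))
  sv <- data.frame(sample = names(marker),
                   time = pmin(rexp(n, rate), runif(n, 0, 30)),
                   event = as.integer(rexp(n, rate) <= 30)) # recomputed below
  tt <- rexp(n, rate); cc <- runif(n, 0, 30)
  sv$time <- pmin(tt, cc); sv$event <- as.integer(tt <= cc)
  sc <- scan_cutoffs(marker, sv, min_group_frac = 0.1)
  b <- quantile(marker, seq(0.1, 0.9, 0.1), type = 7)
  lo <- max(c(min(marker), b[b <= tau])); hi <- min(c(b[b > tau], max(marker)))
  expect_lte(abs(sc$cutoff - tau), hi - lo)
})
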
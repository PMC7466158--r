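test_that("ror reproduces direct arithmetic and flags zero cells", {
  r <- ror(20, 80, 100, 800)
  expect_true(r$computable)
  expect_equal(r$ror, 2, tolerance = 1e-12)
  # direct evaluation of the CI formula: exp(ln 2 -+ 1.959964 * 0.2715695)
  expect_equal(r$ci_lower, 1.1745449, tolerance = 1e-6)
  expect_equal(r$ci_upper, 3.4055745, tolerance = 1e-6)

  # identity case: CI symmetric about 1 on the log scale
  r1 <- ror(50, 50, 50, 50)
  expect_equal(r1$ror, 1)
  expect_equal(log(r1$ci_lower), -log(r1$ci_upper), tolerance = 1e-12)

  expect_false(ror(0, 80, 100, 800)$computable)
  expect_true(ror(0, 80, 100, 800, haldane = TRUE)$computable)
  expect_error(ror(-1, 2, 3, 4), "count")

  # oracle equivalence on random zero-free tables; also the 2x2
  # transposition invariance of the odds ratio
  set.seed(3)
  for (i in 1:50) {
    n <- rpois(4, 30) + 1
    got <- ror(n[1], n[2], n[3], n[4])
    want <- oracle_ror(n[1], n[2], n[3], n[4])
    expect_equal(got$ror, unname(want["ror"]), tolerance = 1e-12)
    expect_equal(got$ci_lower, unname(want["lo"]), tolerance = 1e-12)
    transposed <- ror(n[1], n[3], n[2], n[4])  # swap rows<->columns
    expect_equal(transposed$ror, got$ror, tolerance = 1e-12)
  }
})

test_that("subset criteria combine directional signals as OR / AND", {
  # both directions signal strongly
  both <- contingency_table(30, 20, 5, 200, 5, 200, 50, 5000)
  expect_true(subset_signal(both, "previous")$signal)
  expect_true(subset_signal(both, "new")$signal)

  # only the within-d1 direction signals: d2's other-event cell huge
  one <- contingency_table(30, 20, 5, 200, 100, 120, 50, 5000)
  v_prev <- subset_signal(one, "previous")
  v_new <- subset_signal(one, "new")
  expect_true(xor(v_prev$detail$signal_d1, v_prev$detail$signal_d2))
  expect_true(v_prev$signal)
  expect_false(v_new$signal)

  # neither signals
  none <- contingency_table(5, 200, 5, 200, 5, 200, 50, 5000)
  expect_false(subset_signal(none, "previous")$signal)
  expect_false(subset_signal(none, "new")$signal)

  # min_n11 floor suppresses an otherwise-signalling table
  expect_false(subset_signal(both, "new", min_n11 = 31)$signal)
})

test_that("new-criterion signals are a subset of previous-criterion signals", {
  set.seed(9)
  for (i in 1:400) {
    row <- random_counts_row(i)
    ct <- as_contingency(row)
    if (subset_signal(ct, "new")$signal) {
      expect_true(subset_signal(ct, "previous")$signal)
    }
  }
})

test_that("omega statistic matches hand evaluation and its identities", {
  # constructed so f00 = f10 = f01 = 0.1 -> g11 = 0.1, e111 = 10
  ct <- contingency_table(30, 70, 10, 90, 10, 90, 10, 90)
  d <- omega_signal(ct)$detail
  expect_equal(d$g11, 0.1, tolerance = 1e-12)
  expect_equal(d$e111, 10, tolerance = 1e-12)
  expect_equal(d$omega, log2(30.5 / 10.5), tolerance = 1e-12)
  expect_equal(round(d$omega, 4), 1.5384)
  expect_equal(d$omega025, d$omega - 1.959964 / (log(2) * sqrt(30)),
               tolerance = 1e-12)
  expect_equal(round(d$omega025, 4), 1.0222)
  expect_true(omega_signal(ct)$signal)

  # n111 = E111 => omega = 0 (10/100 observed vs f-cells all 0.1)
  ct0 <- contingency_table(10, 90, 10, 90, 10, 90, 10, 90)
  d0 <- omega_signal(ct0)$detail
  expect_equal(d0$e111, 10, tolerance = 1e-12)
  expect_equal(d0$omega, 0, tolerance = 1e-12)
  expect_false(omega_signal(ct0)$signal)

  # n111 = 0: lower bound -Inf, never a signal
  ctz <- contingency_table(0, 100, 10, 90, 10, 90, 10, 90)
  vz <- omega_signal(ctz)
  expect_identical(vz$detail$omega025, -Inf)
  expect_false(vz$signal)

  # zero row marginal -> not computable
  ctm <- contingency_table(0, 0, 10, 90, 10, 90, 10, 90)
  expect_false(omega_signal(ctm)$detail$computable)
  expect_false(omega_signal(ctm)$signal)
})

test_that("g11 closed form reduces to the max() fallbacks", {
  set.seed(21)
  g11_of <- function(f00, f10, f01, n = 1000) {
    # build integer tables realising the f-cells exactly
    ct <- contingency_table(1, n - 1,
                            round(f10 * n), n - round(f10 * n),
                            round(f01 * n), n - round(f01 * n),
                            round(f00 * n), n - round(f00 * n))
    omega_signal(ct)$detail
  }
  for (i in 1:200) {
    f <- round(runif(3, 0.01, 0.5), 3)  # f00, f10, f01 on a 1/1000 grid
    d <- g11_of(f[1], f[2], f[3])
    if (d$f10 < d$f00) {
      expect_equal(d$g11, max(d$f00, d$f01), tolerance = 1e-12)
    }
    if (d$f01 < d$f00) {
      expect_equal(d$g11, max(d$f00, d$f10), tolerance = 1e-12)
    }
    if (d$f10 == d$f00 && d$f01 == d$f00) {
      expect_equal(d$g11, d$f00, tolerance = 1e-12)
    }
  }
})

test_that("additive model: hand example, null identity, scaling property", {
  # f11 = f10 = f01 = f00 -> delta = 0, no signal
  ct0 <- contingency_table(10, 90, 10, 90, 10, 90, 10, 90)
  v0 <- additive_signal(ct0)
  expect_equal(v0$detail$delta, 0, tolerance = 1e-12)
  expect_false(v0$signal)

  # f00 = 0.01, f10 = f01 = 0.05, f11 = 0.30, all marginals 1000
  ct <- contingency_table(300, 700, 50, 950, 50, 950, 10, 990)
  v <- additive_signal(ct)
  expect_equal(v$detail$delta, 0.21, tolerance = 1e-12)
  se_hand <- sqrt(0.3 * 0.7 / 1000 + 2 * 0.05 * 0.95 / 1000 +
                    0.01 * 0.99 / 1000)
  expect_equal(v$detail$se, se_hand, tolerance = 1e-12)
  expect_true(v$signal)

  # doubling all cells leaves delta unchanged and shrinks the CI
  ct2 <- contingency_table(600, 1400, 100, 1900, 100, 1900, 20, 1980)
  v2 <- additive_signal(ct2)
  expect_equal(v2$detail$delta, v$detail$delta, tolerance = 1e-12)
  expect_lt(v2$detail$se, v$detail$se)

  expect_false(additive_signal(
    contingency_table(0, 0, 1, 9, 1, 9, 1, 9))$detail$computable)
})

test_that("multiplicative model: hand example, null identity, symmetry", {
  # f11/f10 = f01/f00 -> ratio 1, no signal
  ct0 <- contingency_table(20, 80, 10, 90, 20, 80, 10, 90)
  v0 <- multiplicative_signal(ct0)
  expect_equal(v0$detail$ratio, 1, tolerance = 1e-12)
  expect_false(v0$signal)

  # f00 = 0.01, f10 = f01 = 0.05, f11 = 0.50, all marginals 500:
  # ratio is exactly 2 but with only 5 background events the log-scale
  # variance (dominated by (1-f00)/(n00p f00) = 0.198) keeps the lower
  # bound at 0.714 -- no signal at this size
  ct <- contingency_table(250, 250, 25, 475, 25, 475, 5, 495)
  v <- multiplicative_signal(ct)
  expect_equal(v$detail$ratio, 2, tolerance = 1e-12)
  v_hand <- (1 - 0.5) / (500 * 0.5) + 2 * (1 - 0.05) / (500 * 0.05) +
    (1 - 0.01) / (500 * 0.01)
  expect_equal(v$detail$lower, exp(log(2) - 1.959964 * sqrt(v_hand)),
               tolerance = 1e-12)
  expect_false(v$signal)
  # same cells at 10x the sample size: lower bound 1.444 -> signal
  ct10 <- contingency_table(2500, 2500, 250, 4750, 250, 4750, 50, 4950)
  v10 <- multiplicative_signal(ct10)
  expect_equal(v10$detail$ratio, 2, tolerance = 1e-12)
  expect_equal(v10$detail$lower, 1.4441682, tolerance = 1e-6)
  expect_true(v10$signal)

  # invariant under swapping drug1/drug2 (rows 10 and 01)
  ct_sw <- contingency_table(250, 250, 25, 475, 25, 475, 5, 495)
  expect_equal(multiplicative_signal(ct_sw)$detail$ratio,
               v$detail$ratio, tolerance = 1e-12)

  # zero denominator cell -> not computable
  ctz <- contingency_table(10, 90, 0, 100, 25, 475, 5, 495)
  expect_false(multiplicative_signal(ctz)$detail$computable)
  expect_false(multiplicative_signal(ctz)$signal)
})

test_that("chi-square model: expectation, continuity correction, one-sidedness", {
  # n11p = 200, f10 = f01 = 0.1, f00 = 0.05 -> e = 40
  ct <- contingency_table(80, 120, 100, 900, 100, 900, 50, 950)
  v <- chi_square_signal(ct)
  expect_equal(v$detail$expected, 40, tolerance = 1e-12)
  chisq_hand <- (abs(80 - 40) - 0.5)^2 * (1 / 40 + 1 / 160)
  expect_equal(v$detail$chisq, chisq_hand, tolerance = 1e-12)
  expect_true(v$signal)

  # observed equals expected -> statistic ~ 0, no signal
  ct0 <- contingency_table(40, 160, 100, 900, 100, 900, 50, 950)
  v0 <- chi_square_signal(ct0)
  expect_lt(v0$detail$chisq, 0.1)
  expect_false(v0$signal)

  # deficit (n111 << e) can have a large statistic but never signals
  ctd <- contingency_table(1, 199, 100, 900, 100, 900, 50, 950)
  vd <- chi_square_signal(ctd)
  expect_gt(vd$detail$chisq, 3.841)
  expect_false(vd$signal)

  # degenerate expectation -> not computable
  expect_false(chi_square_signal(
    contingency_table(10, 90, 0, 100, 0, 100, 5, 95))$detail$computable)
})

test_that("hypothetical truth is the three-way signal intersection", {
  set.seed(5)
  counts <- do.call(rbind, lapply(1:120, random_counts_row, lambda = 25))
  va <- detect_signals(counts, "additive")
  vm <- detect_signals(counts, "multiplicative")
  vc <- detect_signals(counts, "chi-square")
  truth <- hypothetical_truth(va, vm, vc)

  # brute-force row-by-row intersection
  want <- counts[va$signal & vm$signal & vc$signal,
                 c("drug1", "drug2", "event")]
  expect_setequal(tid(truth), tid(want))

  # any empty component set -> empty truth
  vz <- va; vz$signal <- FALSE
  expect_identical(nrow(hypothetical_truth(vz, vm, vc)), 0L)

  # mismatched universes are a usage error
  expect_error(hypothetical_truth(va[-1, ], vm, vc), "universe")
})

test_that("detect_signals is pure and consistent with single-table calls", {
  set.seed(13)
  counts <- do.call(rbind, lapply(1:40, random_counts_row))
  out1 <- detect_signals(counts, "omega")
  out2 <- detect_signals(counts, "omega")
  expect_identical(out1, out2)
  i <- 17
  ct <- as_contingency(counts[i, ])
  expect_identical(out1$signal[i], omega_signal(ct)$signal)
})
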
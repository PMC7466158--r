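test_that("confusion counts match a per-element tally", {
  u <- paste0("t", 1:50)
  expect_identical(
    unclass(confusion(u, u, u))[1:4],
    c(tp = 50L, fp = 0L, tn = 0L, fn = 0L))
  expect_identical(
    unclass(confusion(character(0), u[1:7], u))[1:4],
    c(tp = 0L, fp = 0L, tn = 43L, fn = 7L))

  set.seed(31)
  for (i in 1:20) {
    pred <- sample(u, rbinom(1, 50, 0.4))
    truth <- sample(u, rbinom(1, 50, 0.3))
    got <- confusion(pred, truth, u)
    # ORACLE: element-wise tally
    tp <- fp <- tn <- fn <- 0L
    for (el in u) {
      p <- el %in% pred; t <- el %in% truth
      if (p && t) tp <- tp + 1L else if (p) fp <- fp + 1L
      else if (t) fn <- fn + 1L else tn <- tn + 1L
    }
    expect_identical(unclass(got)[1:4], c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_identical(sum(got), 50L)
  }

  expect_error(confusion(c(u, "alien"), u[1], u), "outside the universe")
})

test_that("metrics compute all seven indicators with NA for 0/0", {
  m <- classification_metrics(10, 0, 10, 0)
  for (k in c("accuracy", "precision", "recall", "specificity",
              "f_measure", "npv")) {
    expect_equal(m[[k]], 1)
  }
  expect_equal(m$youden, 1)

  # degenerate: no predicted positives -> precision undefined, not 0
  m0 <- classification_metrics(0, 0, 10, 5)
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$f_measure))
  expect_equal(m0$recall, 0)
  expect_error(classification_metrics(0, 0, 0, 0), "zero")
})

test_that("metric identities hold on random confusion counts", {
  set.seed(17)
  for (i in 1:200) {
    cc <- rpois(4, 20) + c(1, 0, 1, 0)  # ensure defined denominators
    m <- classification_metrics(cc[1], cc[2], cc[3], cc[4])
    expect_equal(m$youden, m$recall + m$specificity - 1, tolerance = 1e-12)
    if (!is.na(m$f_measure)) {
      expect_gte(m$f_measure, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f_measure, max(m$precision, m$recall) + 1e-12)
    }
  }
  # F equals precision and recall when they coincide
  m <- classification_metrics(10, 5, 100, 5)
  expect_equal(m$precision, m$recall)
  expect_equal(m$f_measure, m$precision, tolerance = 1e-12)
})

test_that("agreement reproduces hand arithmetic and its symmetries", {
  # (a, b, c, d) = (30, 10, 10, 50)
  u <- paste0("t", 1:100)
  A <- u[1:40]          # a + b
  B <- u[c(1:30, 41:50)]  # a + c
  ag <- agreement(A, B, u)
  expect_identical(ag$table, c(a = 30L, b = 10L, c = 10L, d = 50L))
  expect_equal(ag$kappa, (0.8 - 0.52) / (1 - 0.52), tolerance = 1e-12)
  expect_equal(round(ag$kappa, 3), 0.583)
  expect_equal(ag$p_positive, 0.75)
  expect_equal(ag$p_negative, 50 / 60, tolerance = 1e-12)
  expect_true(ag$kappa_ci_lower < ag$kappa &&
                ag$kappa < ag$kappa_ci_upper)

  # identical sets -> kappa 1, both agreements 1
  ag1 <- agreement(A, A, u)
  expect_equal(ag1$kappa, 1)
  expect_equal(ag1$p_positive, 1)
  expect_equal(ag1$p_negative, 1)

  # kappa symmetric in its arguments
  ag_sw <- agreement(B, A, u)
  expect_equal(ag_sw$kappa, ag$kappa, tolerance = 1e-12)
  expect_equal(ag_sw$p_positive, ag$p_positive, tolerance = 1e-12)

  # complementing both sets swaps P+ and P-
  ag_c <- agreement(setdiff(u, A), setdiff(u, B), u)
  expect_equal(ag_c$p_positive, ag$p_negative, tolerance = 1e-12)
  expect_equal(ag_c$p_negative, ag$p_positive, tolerance = 1e-12)

  # independent partitions by construction: po = pe -> kappa 0
  u2 <- paste0("s", 1:100)
  A2 <- u2[1:50]                      # left half
  B2 <- u2[c(1:25, 51:75)]            # half of each half
  ag0 <- agreement(A2, B2, u2)
  expect_equal(ag0$kappa, 0, tolerance = 1e-12)

  # degenerate marginals -> kappa undefined
  agd <- agreement(u, u, u)
  expect_true(is.na(agd$kappa))
})

test_that("stratify_by_reports filters the universe consistently", {
  set.seed(23)
  counts <- do.call(rbind, lapply(1:60, random_counts_row, lambda = 3))
  v1 <- detect_signals(counts, "subset-new")
  v2 <- detect_signals(counts, "omega")

  # identity at floor 0
  s0 <- stratify_by_reports(list(v1, v2), counts, 0)
  expect_identical(nrow(s0$universe), nrow(counts))

  s3 <- stratify_by_reports(list(v1, v2), counts, 3)
  expect_identical(nrow(s3$universe), sum(counts$n111 >= 3))
  expect_true(all(s3$verdicts[[1]]$n111 >= 3))

  # hand-sized check of the retained count
  cts <- counts[1:4, ]; cts$n111 <- c(1, 2, 3, 5)
  vv <- detect_signals(cts, "omega")
  expect_identical(nrow(stratify_by_reports(vv, cts, 3)$universe), 2L)

  # RECOMPUTATION ORACLE: agreement on the stratified output equals
  # agreement computed from scratch on the filtered inputs
  ag_strat <- agreement(s3$verdicts[[1]], s3$verdicts[[2]], s3$universe)
  keep <- counts$n111 >= 3
  ag_scratch <- agreement(v1[keep, ], v2[keep, ], counts[keep, ])
  expect_equal(ag_strat$kappa, ag_scratch$kappa, tolerance = 1e-12)
  expect_identical(ag_strat$table, ag_scratch$table)
})
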
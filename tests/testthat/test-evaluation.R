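test_that("contingency metrics reproduce benchmark coarse-grained rows", {
  m <- contingency_metrics(559, 311, 196, 5960)
  expect_equal(round(unname(m), 4), c(0.6425, 0.7404, 0.6880, 0.9278))
  expect_equal(round(contingency_metrics(543, 354, 212, 5914)[["F"]], 4),
               0.6574)
  expect_equal(round(contingency_metrics(550, 320, 205, 5951)[["Acc"]], 4),
               0.9253)
})

test_that("degenerate contingency cases follow the documented contract", {
  m <- contingency_metrics(0, 3, 2, 5)   # defined 0/3 and 0/2 ratios
  expect_equal(unname(m[c("P", "R", "F")]), c(0, 0, 0))
  expect_warning(contingency_metrics(0, 0, 2, 5), "degenerate")
  expect_error(contingency_metrics(0, 0, 0, 0), "all-zero")
  m2 <- contingency_metrics(0, 0, 2, 5, degenerate = "nan")
  expect_true(is.nan(m2[["P"]]))
  # harmonic-mean bracketing on random tables
  set.seed(1)
  for (i in 1:50) {
    ct <- sample.int(40L, 4L)
    m <- contingency_metrics(ct[1], ct[2], ct[3], ct[4])
    expect_gte(m[["F"]], min(m[["P"]], m[["R"]]) - 1e-12)
    expect_lte(m[["F"]], max(m[["P"]], m[["R"]]) + 1e-12)
    if (abs(m[["P"]] - m[["R"]]) < 1e-12)
      expect_equal(m[["F"]], m[["P"]], tolerance = 1e-12)
  }
})

test_that("multi-class report matches an independent reference implementation", {
  # 12-instance 3-class fixture; expected values frozen from
  # scikit-learn's precision_recall_fscore_support / f1_score
  gold <- strsplit("AAAABBBCCCCC", "")[[1]]
  pred <- strsplit("ABAACBBCCACB", "")[[1]]
  rep <- multiclass_report(pred, gold, classes = c("A", "B", "C"))
  expect_equal(rep$per_class$P, c(0.75, 0.5, 0.75), tolerance = 1e-12)
  expect_equal(rep$per_class$R, c(0.75, 2 / 3, 0.6), tolerance = 1e-12)
  expect_equal(rep$per_class$F, c(0.75, 0.5714285714285714,
                                  0.6666666666666666), tolerance = 1e-12)
  expect_equal(rep$CLA, 0.6666666666666666, tolerance = 1e-12)
  expect_equal(rep$MAVG, 0.6626984126984127, tolerance = 1e-12)
  expect_equal(rep$accuracy, 2 / 3, tolerance = 1e-12)
})

test_that("perfect prediction and micro-averaging identities hold", {
  gold <- c("A", "B", "C", "A")
  rep <- multiclass_report(gold, gold, classes = c("A", "B", "C"))
  expect_equal(rep$per_class$F, rep(1, 3))
  expect_equal(rep$CLA, 1); expect_equal(rep$MAVG, 1)
  # with no exclusions, micro-P = micro-R = CLA = accuracy
  set.seed(3)
  pred <- sample(c("A", "B", "C"), 60L, replace = TRUE)
  gold2 <- sample(c("A", "B", "C"), 60L, replace = TRUE)
  r <- multiclass_report(pred, gold2, classes = c("A", "B", "C"))
  expect_equal(unname(r$micro["P"]), unname(r$micro["R"]))
  expect_equal(r$CLA, r$accuracy, tolerance = 1e-12)
  expect_error(multiclass_report(pred[1:3], gold2), "length")
})

test_that("averages are invariant to relabeling and prediction order", {
  set.seed(9)
  pred <- sample(c("A", "B", "C"), 40L, replace = TRUE)
  gold <- sample(c("A", "B", "C"), 40L, replace = TRUE)
  base <- multiclass_report(pred, gold, classes = c("A", "B", "C"))
  relab <- c(A = "X", B = "Y", C = "Z")
  swapped <- multiclass_report(unname(relab[pred]), unname(relab[gold]),
                               classes = c("X", "Y", "Z"))
  expect_equal(swapped$MAVG, base$MAVG, tolerance = 1e-15)
  perm <- sample.int(40L)
  shuffled <- multiclass_report(pred[perm], gold[perm],
                                classes = c("A", "B", "C"))
  expect_equal(shuffled$CLA, base$CLA, tolerance = 1e-15)
})

test_that("the NEGATIVE-exclusion convention changes only the averages", {
  pred <- c("NEGATIVE", "EFFECT", "EFFECT", "INT", "NEGATIVE")
  gold <- c("NEGATIVE", "EFFECT", "INT", "INT", "EFFECT")
  all_in <- multiclass_report(pred, gold,
                              classes = c("NEGATIVE", "EFFECT", "INT"))
  excl <- suppressWarnings(multiclass_report(
    pred, gold, classes = c("NEGATIVE", "EFFECT", "INT"),
    exclude = "NEGATIVE"))
  expect_equal(all_in$per_class, excl$per_class)
  expect_false(isTRUE(all.equal(all_in$MAVG, excl$MAVG)))
})

test_that("the scalability score matches the published cross-corpus values", {
  expect_equal(round(scalability_score(0.6880, 0.716), 4), 0.9860)
  expect_equal(round(scalability_score(0.6574, 0.599), 4), 0.9708)
  expect_equal(scalability_score(0.6299, 0.594), 0.98205, tolerance = 1e-12)
  expect_equal(scalability_score(0.60, 0.70), 0.95, tolerance = 1e-15)
  for (x in c(0, 0.3, 1)) expect_equal(scalability_score(x, x), 1)
  # symmetric, and the sqrt form equals 1 - |a-b|/2
  set.seed(2)
  for (i in 1:25) {
    ab <- runif(2)
    expect_equal(scalability_score(ab[1], ab[2]),
                 scalability_score(ab[2], ab[1]), tolerance = 1e-15)
    expect_equal(scalability_score(ab[1], ab[2]),
                 1 - abs(ab[1] - ab[2]) / 2, tolerance = 1e-15)
  }
})

test_that("reproducibility sums use per-epoch population spread", {
  runs <- list(c(0.5, 0.7), c(0.5, 0.5))
  out <- reproducibility_summary(runs)
  expect_equal(out$variance, c(0, 0.01), tolerance = 1e-12)
  expect_equal(out$sum_variance, 0.01, tolerance = 1e-12)
  expect_equal(out$sum_std, 0.1, tolerance = 1e-12)
  ident <- reproducibility_summary(rbind(c(0.6, 0.8), c(0.6, 0.8)))
  expect_equal(ident$sum_variance, 0)
  expect_equal(ident$sum_std, 0)
  expect_error(reproducibility_summary(list(1:3 / 10, 1:4 / 10)), "unequal")
  expect_error(reproducibility_summary(matrix(0.5, 1L, 3L)), "2 runs")
  # sum of std dominates sqrt of summed variance on random traces
  set.seed(4)
  for (i in 1:20) {
    tr <- matrix(runif(5 * 7), 5L, 7L)
    out <- reproducibility_summary(tr)
    expect_gte(out$sum_std + 1e-12, sqrt(out$sum_variance))
  }
})

test_that("Welch's test agrees with the reference implementation", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  ours <- welch_t_test(a, b)
  ref <- stats::t.test(a, b)   # Welch by default
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-8)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  # identical samples: no evidence of difference
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_false(same$significant)
  # equal variances and equal n: Welch t equals the pooled Student t
  set.seed(6)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(welch_t_test(x, y)$t,
               unname(stats::t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 1e-10)
  # degenerate zero-variance contracts
  expect_equal(welch_t_test(c(1, 1), c(1, 1))$p, 1)
  deg <- welch_t_test(c(1, 1), c(2, 2))
  expect_true(deg$significant); expect_equal(deg$p, 0)
})
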
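test_that("candidate-to-annotation matching respects tolerance and one-to-one rule", {
  expect_identical(match_candidates_to_truth(c(100L, 500L), 502L, 5L),
                   c(FALSE, TRUE))
  # two candidates equidistant from one annotation: earlier one wins
  expect_identical(match_candidates_to_truth(c(10L, 14L), 12L, 5L),
                   c(TRUE, FALSE))
  # zero tolerance means exact-index matching
  expect_identical(match_candidates_to_truth(c(10L, 12L), 12L, 0L),
                   c(FALSE, TRUE))
  # an annotation claims at most one candidate even if several are in range
  expect_identical(sum(match_candidates_to_truth(c(11L, 12L, 13L), 12L, 5L)), 1L)
  expect_error(match_candidates_to_truth(1L, 1L, -1L), "tolerance")
})

test_that("confusion counts agree with a brute-force pairwise count", {
  cc <- confusion(rep(TRUE, 4), rep(TRUE, 4))
  expect_identical(c(cc$tp, cc$tn, cc$fp, cc$fn), c(4L, 0L, 0L, 0L))

  cc2 <- confusion(rep(FALSE, 100), c(rep(TRUE, 5), rep(FALSE, 95)))
  expect_identical(c(cc2$tp, cc2$fn, cc2$tn, cc2$fp), c(0L, 5L, 95L, 0L))

  set.seed(41)
  for (i in 1:20) {
    pred <- stats::runif(50) > 0.5
    truth <- stats::runif(50) > 0.7
    cc <- confusion(pred, truth)
    bf <- brute_confusion(pred, truth)
    expect_identical(c(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn), bf)
    expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, 50L)
  }
  expect_error(confusion(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("G_mean identities: zero on total peak miss, one when perfect", {
  miss <- structure(list(tp = 0L, tn = 95L, fp = 0L, fn = 5L),
                    class = "confusion_counts")
  expect_equal(g_mean(miss), 0)

  perfect <- structure(list(tp = 10L, tn = 90L, fp = 0L, fn = 0L),
                       class = "confusion_counts")
  expect_equal(g_mean(perfect), 1)

  cc <- structure(list(tp = 3L, tn = 96L, fp = 0L, fn = 1L),
                  class = "confusion_counts")
  expect_equal(g_mean(cc), sqrt(0.75))

  no_pos <- structure(list(tp = 0L, tn = 5L, fp = 1L, fn = 0L),
                      class = "confusion_counts")
  expect_error(g_mean(no_pos), "peak")
  no_neg <- structure(list(tp = 5L, tn = 0L, fp = 0L, fn = 1L),
                      class = "confusion_counts")
  expect_error(g_mean(no_neg), "non-peak")
})

test_that("G_mean lies between TPR and TNR", {
  set.seed(42)
  for (i in 1:50) {
    cc <- structure(as.list(stats::setNames(
      sample(0:50, 4, replace = TRUE) + 1L, c("tp", "tn", "fp", "fn"))),
      class = "confusion_counts")
    tpr <- cc$tp / (cc$tp + cc$fn)
    tnr <- cc$tn / (cc$tn + cc$fp)
    g <- g_mean(cc)
    expect_gte(g, min(tpr, tnr) - 1e-12)
    expect_lte(g, max(tpr, tnr) + 1e-12)
  }
})

test_that("sensitivity and specificity evaluate the printed formulas", {
  cc <- structure(list(tp = 572L, tn = 996L, fp = 4L, fn = 428L),
                  class = "confusion_counts")
  ss <- sensitivity_specificity(cc)
  expect_equal(ss[["sensitivity"]], 57.2)
  expect_equal(ss[["specificity"]], 99.6)

  perfect <- structure(list(tp = 3L, tn = 7L, fp = 0L, fn = 0L),
                       class = "confusion_counts")
  expect_equal(unname(sensitivity_specificity(perfect)), c(100, 100))
})

test_that("run summaries report average, extremes and sample stdev", {
  expect_equal(summarize_runs(c(0.5, 0.5, 0.5)),
               c(average = 0.5, max = 0.5, min = 0.5, stdev = 0))
  s <- summarize_runs(c(0, 1))
  expect_equal(unname(s), c(0.5, 1, 0, sqrt(0.5)))
  expect_warning(one <- summarize_runs(0.8), "single run")
  expect_equal(unname(one), c(0.8, 0.8, 0.8, 0))
  expect_error(summarize_runs(numeric(0)), "no runs")
  set.seed(43)
  g <- stats::runif(30)
  sm <- summarize_runs(g)
  expect_true(sm[["min"]] <= sm[["average"]] && sm[["average"]] <= sm[["max"]])
})

test_that("Friedman ranks handle total ties and dominant models", {
  tied <- matrix(0.7, nrow = 5, ncol = 4,
                 dimnames = list(NULL, letters[1:4]))
  fr <- friedman_ranks(tied)
  expect_equal(unname(fr$avg_ranks), rep(2.5, 4))
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p_value, 1)

  set.seed(44)
  acc <- matrix(stats::runif(30), 10, 3, dimnames = list(NULL, c("x", "y", "z")))
  acc[, 2] <- acc[, 2] + 2  # y strictly best everywhere
  expect_equal(unname(friedman_ranks(acc)$avg_ranks["y"]), 1)
  expect_error(friedman_ranks(acc[1, , drop = FALSE]), "at least 2")
})

test_that("Friedman statistic matches textbook formula and stats::friedman.test", {
  set.seed(45)
  acc <- matrix(stats::rnorm(40), 10, 4)  # continuous: no ties
  colnames(acc) <- paste0("m", 1:4)
  fr <- friedman_ranks(acc)
  oracle <- friedman_oracle(acc)
  expect_equal(fr$statistic, oracle$statistic)
  expect_equal(fr$p_value, oracle$p_value)
  ref <- stats::friedman.test(acc)
  expect_equal(fr$statistic, unname(ref$statistic))
  expect_equal(fr$p_value, unname(ref$p.value))
})

test_that("Friedman ranking is equivariant under model permutation", {
  set.seed(46)
  acc <- matrix(stats::rnorm(24), 6, 4, dimnames = list(NULL, letters[1:4]))
  perm <- c(3, 1, 4, 2)
  fr1 <- friedman_ranks(acc)
  fr2 <- friedman_ranks(acc[, perm])
  expect_equal(fr2$avg_ranks, fr1$avg_ranks[perm])
  expect_equal(fr2$statistic, fr1$statistic)
})

test_that("Holm step-down matches thresholds and a brute-force enumeration", {
  p6 <- stats::setNames(c(1e-6, 1e-6, 1e-6, 1e-6, 0.161513, 0.841481),
                        paste("pair", 1:6))
  h <- holm_posthoc(p6, alpha = 0.05)
  expect_equal(h$holm[1], 0.05 / 6)  # 0.00833 for the smallest p
  expect_equal(h$i, 6:1)
  expect_identical(h$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))

  none <- holm_posthoc(rep(1, 4), alpha = 0.05)
  expect_false(any(none$reject))

  set.seed(47)
  for (i in 1:50) {
    p <- stats::runif(sample(2:8, 1))^2
    a <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(holm_posthoc(p, a)$reject, holm_oracle(p, a))
  }
  expect_error(holm_posthoc(c(0.5, 1.2)), "0, 1")
})

test_that("Holm rejections at alpha 0.05 are a subset of those at 0.10", {
  set.seed(48)
  for (i in 1:30) {
    p <- stats::runif(6)^3
    r05 <- holm_posthoc(p, 0.05)
    r10 <- holm_posthoc(p, 0.10)
    expect_true(all(!r05$reject | r10$reject))
  }
})

test_that("pairwise Wilcoxon returns p = 1 for identical models", {
  set.seed(49)
  acc <- cbind(a = stats::runif(8), b = stats::runif(8))
  acc <- cbind(acc, c = acc[, "a"])
  p <- pairwise_wilcoxon(acc)
  expect_equal(unname(p[["a vs. c"]]), 1)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(names(p), c("a vs. b", "a vs. c", "b vs. c"))
})
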
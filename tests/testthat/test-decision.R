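test_that("the window vote rule has an inclusive one-third boundary", {
  expect_equal(decide_window(c(rep(1, 4), rep(0, 6)))$decision, "threat")     # 40%
  expect_equal(decide_window(c(rep(1, 3), rep(0, 7)))$decision, "no_threat")  # 30%
  expect_equal(decide_window(c(1, 0, 0))$decision, "threat")                  # exactly 1/3
  expect_equal(decide_window(integer(0))$decision, "indeterminate")
  expect_error(decide_window(c(1, 0), tau = 0), "tau")
  d <- decide_window(c(1, 1, 0, 0), window_id = "w9", n_total = 7)
  expect_equal(d$n_pulses_total, 7L)
  expect_equal(d$n_pulses_kept, 4L)
  expect_equal(d$positive_fraction, 0.5)
})

test_that("flipping any pulse label towards positive never revokes a threat", {
  set.seed(31)
  for (i in 1:50) {
    labs <- rbinom(sample(3:15, 1), 1, runif(1))
    before <- decide_window(labs)$decision
    j <- sample(seq_along(labs), 1)
    labs2 <- labs; labs2[j] <- 1L
    after <- decide_window(labs2)$decision
    expect_false(before == "threat" && after == "no_threat")
  }
})

test_that("windows with all pulses filtered away come back indeterminate", {
  preds <- data.frame(window_id = c("a", "a", "b"), label_pred = c(1L, 0L, 1L))
  dec <- decide_windows(preds, totals = c(a = 5, b = 3, c = 4))
  expect_setequal(dec$window_id, c("a", "b", "c"))
  expect_equal(dec$decision[dec$window_id == "c"], "indeterminate")
  expect_equal(dec$n_pulses_total[dec$window_id == "c"], 4L)
  expect_equal(dec$n_pulses_kept[dec$window_id == "c"], 0L)
})

test_that("evaluation metrics match hand-computed confusion counts", {
  # TP 3, FP 1, FN 1, TN 5
  dec <- decide_windows(data.frame(
    window_id = rep(sprintf("w%02d", 1:10), each = 1),
    label_pred = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)))
  truth <- stats::setNames(c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0), sprintf("w%02d", 1:10))
  rep_ <- evaluate_decisions(dec, truth)
  expect_equal(rep_$tp, 3); expect_equal(rep_$fp, 1)
  expect_equal(rep_$fn, 1); expect_equal(rep_$tn, 5)
  expect_equal(rep_$precision, 0.75)
  expect_equal(rep_$recall, 0.75)
  expect_equal(rep_$f1, 0.75)
  expect_equal(rep_$accuracy, 0.8)
  # metrics recomputed from the reported confusion counts agree exactly
  expect_equal(rep_$accuracy, (rep_$tp + rep_$tn) / rep_$n_evaluated)
  expect_equal(rep_$f1, 2 * rep_$tp / (2 * rep_$tp + rep_$fp + rep_$fn))
})

test_that("evaluation handles perfect, degenerate and invalid inputs", {
  dec <- decide_windows(data.frame(window_id = c("a", "b"), label_pred = c(1L, 0L)))
  expect_equal(evaluate_decisions(dec, c(a = 1, b = 0))$accuracy, 1)
  expect_equal(evaluate_decisions(dec, c(a = 1, b = 0))$f1, 1)
  # no positives predicted while positives exist: recall 0, precision flagged
  dec0 <- decide_windows(data.frame(window_id = c("a", "b"), label_pred = c(0L, 0L)))
  r <- evaluate_decisions(dec0, c(a = 1, b = 0))
  expect_equal(r$recall, 0)
  expect_equal(r$precision, 0)
  expect_true("precision" %in% r$degenerate)
  # indeterminates are excluded from counts but reported
  deci <- rbind(dec0, decide_window(integer(0), window_id = "z"))
  r2 <- evaluate_decisions(deci, c(a = 1, b = 0))
  expect_equal(r2$n_evaluated, 2L)
  expect_equal(r2$n_indeterminate, 1L)
  expect_error(evaluate_decisions(dec, c(a = 1)), "missing truth")
  all_ind <- decide_window(integer(0), window_id = "q")
  expect_error(evaluate_decisions(all_ind, c(q = 1)), "no evaluable")
})

test_that("McNemar statistic follows the continuity-corrected closed form", {
  r <- mcnemar_test(c(rep(TRUE, 10), rep(FALSE, 2), TRUE, FALSE),
                    c(rep(FALSE, 10), rep(TRUE, 2), TRUE, FALSE),
                    method = "chi2_cc")
  expect_equal(r$b, 10L); expect_equal(r$c, 2L)
  expect_equal(r$statistic, 49 / 12)
  expect_equal(r$p_value, stats::pchisq(49 / 12, 1, lower.tail = FALSE))
  # perfectly symmetric discordance: corrected statistic 0, p = 1
  r2 <- mcnemar_test(c(rep(TRUE, 5), rep(FALSE, 5)),
                     c(rep(FALSE, 5), rep(TRUE, 5)), method = "chi2_cc")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  # no discordant pairs: explicit undefined result
  r3 <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_true(r3$undefined)
  expect_true(is.na(r3$p_value))
  expect_error(mcnemar_test(TRUE, c(TRUE, FALSE)), "paired")
})

test_that("McNemar agrees with brute-force enumeration and reference tests", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(10:120, 1)
    a <- runif(n) < runif(1)
    b <- runif(n) < runif(1)
    # brute-force discordant-pair enumeration
    bb <- 0L; cc <- 0L
    for (j in seq_len(n)) {
      if (a[j] && !b[j]) bb <- bb + 1L
      if (!a[j] && b[j]) cc <- cc + 1L
    }
    r <- mcnemar_test(a, b)
    expect_identical(c(r$b, r$c), c(bb, cc))
    if (bb + cc == 0) {
      expect_true(r$undefined)
    } else if (bb + cc >= 25) {
      expect_equal(r$method, "chi2_cc")
      expect_equal(r$statistic, max(abs(bb - cc) - 1, 0)^2 / (bb + cc))
      ref <- stats::mcnemar.test(matrix(c(0, cc, bb, 0), 2), correct = TRUE)
      expect_equal(r$p_value, unname(ref$p.value))
    } else {
      expect_equal(r$method, "exact")
      ref <- stats::binom.test(min(bb, cc), bb + cc, 0.5)
      expect_equal(r$p_value, min(1, 2 * stats::pbinom(min(bb, cc), bb + cc, 0.5)))
      if (bb != cc) expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
  }
})
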
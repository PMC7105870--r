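test_that("minute score matches the printed coefficients and threshold", {
  z <- score_minute(rep(0, 7))
  expect_equal(z$s_value, 0)
  expect_equal(z$label, "sleep")

  spike <- score_minute(c(0, 0, 0, 0, 400, 0, 0))
  expect_equal(spike$s_value, 3.036)
  expect_equal(spike$label, "wake")

  flat <- score_minute(rep(100, 7))
  expect_equal(flat$s_value, 2.1945)
  expect_equal(flat$label, "wake")

  expect_error(score_minute(rep(0, 6)), "exactly 7")
  expect_error(score_minute(c(-1, rep(0, 6))), "non-negative")
})

test_that("minute score is linear in the activity window", {
  withr::with_seed(21, {
    for (i in 1:20) {
      w <- rpois(7, 80)
      s1 <- score_minute(w)$s_value
      s2 <- score_minute(2 * w)$s_value
      expect_equal(s2, 2 * s1)
      expect_equal(s1, oracle_minute_score(w))
    }
  })
})

test_that("series scoring windows, boundaries, and off-wrist handling", {
  lab <- score_series(rep(0, 60))
  expect_equal(unname(lab[5:58]), rep("sleep", 54))
  expect_equal(unname(lab[c(1:4, 59:60)]), rep("undefined", 6))

  lab400 <- score_series(rep(400L, 60))
  expect_true(all(lab400[5:58] == "wake"))

  df <- data.frame(activity_zcm = rep(0L, 30), offwrist = TRUE)
  expect_true(all(score_series(df) == "undefined"))

  expect_error(score_series(rep(0, 6)), "at least 7")
})

test_that("labels agree with the score threshold before rescoring", {
  withr::with_seed(8, {
    x <- rnbinom(500, mu = 60, size = 3)
    lab <- score_series(x)
    s <- attr(lab, "s_value")
    def <- !is.na(s)
    expect_identical(unname(lab[def]), ifelse(s[def] < 1, "sleep", "wake"))
  })
})

test_that("rescoring applies the configured rule table", {
  # all sleep: no wake bouts, unchanged
  allS <- rep("sleep", 40)
  expect_equal(as.vector(rescore_labels(allS)), allS)

  # disabled: identity
  seq1 <- c(rep("wake", 15), "sleep", "sleep", rep("wake", 15))
  expect_identical(rescore_labels(seq1, enabled = FALSE), seq1)

  # isolated 2-min sleep bout after a 15-min wake run is rescored wake
  expect_equal(as.vector(rescore_labels(seq1)), rep("wake", 32))

  # hand-traced: 9 wake trigger the 1-minute rule only; 2-min bout keeps
  # its second minute (flanks too short for the bout rules)
  seq2 <- c(rep("wake", 9), "sleep", "sleep", rep("wake", 9))
  expect_equal(as.vector(rescore_labels(seq2)),
               c(rep("wake", 10), "sleep", rep("wake", 9)))

  # bout rule: 5-min sleep bout between 10-min wake runs is wiped beyond the
  # 3 minutes the after-wake rule would take
  seq3 <- c(rep("wake", 10), rep("sleep", 5), rep("wake", 10))
  expect_equal(as.vector(rescore_labels(seq3)), rep("wake", 25))

  # 8-min bout needs the 20-min flanks of the second bout rule
  seq4 <- c(rep("wake", 20), rep("sleep", 8), rep("wake", 20))
  expect_equal(as.vector(rescore_labels(seq4)), rep("wake", 48))
  seq5 <- c(rep("wake", 15), rep("sleep", 8), rep("wake", 15))
  out5 <- as.vector(rescore_labels(seq5))
  expect_equal(out5, c(rep("wake", 15), rep("wake", 4), rep("sleep", 4),
                       rep("wake", 15)))
})

test_that("rescoring is a no-op on already-rescored labels", {
  withr::with_seed(31, {
    for (i in 1:25) {
      lab <- random_labels(200, p_sleep = 0.6)
      once <- rescore_labels(lab)
      twice <- rescore_labels(once)
      expect_identical(twice, once)
    }
  })
})

test_that("sleep period detection finds the anchored span", {
  allS <- rep("sleep", 480)
  p <- detect_sleep_period(allS)
  expect_equal(c(p$start, p$end), c(1, 480))

  pw <- detect_sleep_period(rep("wake", 100))
  expect_false(pw$valid)
  expect_match(pw$reason, "no sleep run >= 20")

  toy <- c(rep("wake", 30), rep("sleep", 300), rep("wake", 10),
           rep("sleep", 120), rep("wake", 30))
  pt <- detect_sleep_period(toy, min_run = 20)
  expect_equal(c(pt$start, pt$end), c(31, 460))

  ov <- detect_sleep_period(toy, override = list(start = 5, end = 400))
  expect_equal(c(ov$start, ov$end), c(5, 400))

  offw <- rep(FALSE, 480)
  offw[100:300] <- TRUE
  po <- detect_sleep_period(allS, offwrist = offw)
  expect_false(po$valid)
})

test_that("night measures match their definitions and conventions", {
  ref <- as.POSIXct("2016-02-02 00:00:00", tz = "UTC")
  ts4 <- ref + 60 * (0:3)
  r4 <- compute_night_measures(rep("sleep", 4),
                               list(start = 1, end = 4, valid = TRUE),
                               ref, ts4)
  expect_equal(r4$awakenings, 0L)
  expect_equal(r4$efficiency, 100)
  expect_equal(r4$duration, 4)

  lab5 <- c("sleep", "wake", "sleep", "wake", "sleep")
  ts5 <- ref + 60 * (0:4)
  r5 <- compute_night_measures(lab5, list(start = 1, end = 5, valid = TRUE),
                               ref, ts5)
  expect_equal(r5$awakenings, 2L)
  expect_equal(r5$efficiency, 60)

  # a period starting at 22:30 is -90 min relative to the coming midnight
  ts <- seq(ref - 90 * 60, by = 60, length.out = 480)
  rneg <- compute_night_measures(rep("sleep", 480),
                                 list(start = 1, end = 480, valid = TRUE),
                                 ref, ts)
  expect_equal(rneg$sleep_start, -90)
  expect_equal(rneg$sleep_end, 390)

  rinv <- compute_night_measures(lab5, list(valid = FALSE, reason = "x"),
                                 ref, ts5)
  expect_false(rinv$valid)
  expect_equal(rinv$invalid_reason, "x")
})

test_that("awakening counts and efficiency match brute-force oracles", {
  ref <- as.POSIXct("2016-02-02 00:00:00", tz = "UTC")
  withr::with_seed(17, {
    for (i in 1:300) {
      n <- sample(10:120, 1)
      seg <- random_labels(n, p_sleep = runif(1, 0.3, 0.9))
      ts <- ref + 60 * seq_len(n)
      r <- compute_night_measures(seg, list(start = 1, end = n, valid = TRUE),
                                  ref, ts)
      expect_equal(r$awakenings, oracle_awakenings(seg))
      expect_equal(r$efficiency, oracle_efficiency(seg))
      expect_gte(r$efficiency, 0)
      expect_lte(r$efficiency, 100)
      expect_equal(r$efficiency == 100, !any(seg == "wake"))
    }
  })
})

test_that("age-norm adjustment subtracts the right group value", {
  expect_equal(adjust_for_age(600, "duration", 10), 0)
  expect_equal(adjust_for_age(540, "duration", 15), 0)
  expect_equal(adjust_for_age(480, "duration", 30), 0)
  expect_equal(adjust_for_age(-210, "start", 10), 0)
  expect_equal(adjust_for_age(-150, "start", 15), 0)
  expect_equal(adjust_for_age(-90, "start", 30), 0)
  expect_equal(adjust_for_age(500, "duration", 15), -40)
  expect_error(adjust_for_age(480, "duration", 5), "age")
})
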
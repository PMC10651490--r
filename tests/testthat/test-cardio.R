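test_that("MAP follows the one-third rule", {
  expect_equal(computeMAP(120, 80), 80 + 40 / 3)
  expect_equal(computeMAP(160, 100), 120)
  expect_equal(computeMAP(95, 95), 95)
  expect_error(computeMAP(80, 120), "sbp >= dbp")
})

test_that("value-of-day and value-of-week rules apply", {
  expect_equal(valueOfDay(c(130, 134, 132)), 132)
  expect_error(valueOfDay(c(130, 134)), "exactly 3")
  w2 <- valueOfWeek(c(131, 134))
  expect_true(is.na(w2) && isTRUE(attr(w2, "undefined")))
  expect_equal(valueOfWeek(rep(132, 5)), 132)
  expect_equal(valueOfWeek(c(130, 132, 134)), 132)
  log <- data.frame(date = rep(c("d1", "d2"), each = 3), slot = rep(1:3, 2),
                    sbp = c(130, 134, 132, 140, 141, 142),
                    dbp = c(80, 82, 84, 88, 88, 88), hr = rep(70, 6))
  dv <- cuffDailyValues(log)
  expect_equal(dv$sbp, c(132, 141))
  expect_equal(dv$map, c(82 + 50 / 3, 88 + 53 / 3))
  bad <- log[-6, ]
  expect_error(cuffDailyValues(bad), "d2")
})

test_that("two-pass RRI cleaning matches the brute-force oracle on fixtures", {
  fx1 <- c(rep(0.8, 12), 0.3, 0.8, 2.0, 0.8)
  cl1 <- cleanRRI(fx1)
  expect_equal(cl1$report@removed$index, c(13, 15))
  expect_equal(cl1$report@removed$reason, c("absolute", "absolute"))
  fx2 <- c(rep(1, 12), 0.55)
  cl2 <- cleanRRI(fx2)
  expect_equal(cl2$report@removed$index, 13)
  expect_equal(cl2$report@removed$reason, "relative")
  # constant series: nothing removed
  expect_equal(nrow(cleanRRI(rep(1, 30))$report@removed), 0)
  # randomised fixtures against the independent oracle
  set.seed(55)
  for (r in 1:20) {
    x <- round(runif(40, 0.4, 1.6), 3)
    got <- cleanRRI(x)
    st <- bruteCleanRRI(x)
    expect_equal(got$keptIdx, which(st == "kept"))
    expect_equal(got$report@removed$index, which(st != "kept"))
    expect_equal(got$report@removed$reason,
                 st[st != "kept"], ignore_attr = TRUE)
  }
})

test_that("pass order is fixed: absolute before relative", {
  fx <- c(rep(0.8, 10), 2.0, 1.15)
  right <- bruteCleanRRI(fx)
  wrong <- bruteCleanRRIWrongOrder(fx)
  expect_false(identical(right, wrong))   # the order genuinely matters here
  got <- cleanRRI(fx)
  expect_equal(got$keptIdx, which(right == "kept"))
  # 1.15 > 1.4 x 0.8 by a hair less... boundary: exactly 1.4x is retained
  fxB <- c(rep(0.8, 10), 0.8 * 1.4)
  expect_equal(nrow(cleanRRI(fxB)$report@removed), 0)
})

test_that("segment validity rules hit their stated boundaries exactly", {
  mkSeries <- function(nFail = 0, sbpFail = 49, rriBad = 0) {
    n <- 310
    tm <- seq_len(n)
    sbp <- rep(140, n); dbp <- rep(85, n); rri <- rep(1, n)
    if (nFail > 0) sbp[100 + seq_len(nFail)] <- sbpFail
    if (rriBad > 0) rri[150 + seq_len(rriBad)] <- 0.3
    BeatSeries(tm, sbp, dbp, rri)
  }
  # 12 s of failures in 300 s = 4.0% -> passes; 13 s = 4.33% -> fails
  expect_true(validateSegment(mkSeries(nFail = 12))$bpValid)
  expect_false(validateSegment(mkSeries(nFail = 13))$bpValid)
  # SBP = 50 is not a failure; 49 is
  expect_true(validateSegment(mkSeries(nFail = 13, sbpFail = 50))$bpValid)
  expect_false(validateSegment(mkSeries(nFail = 13, sbpFail = 49))$bpValid)
  # 30 of 300 removed = 10% -> passes; 31 = 10.33% -> fails
  expect_true(validateSegment(mkSeries(rriBad = 30))$rriValid)
  expect_false(validateSegment(mkSeries(rriBad = 31))$rriValid)
  # clean series passes both
  v <- validateSegment(mkSeries())
  expect_true(v$bpValid && v$rriValid)
  short <- BeatSeries(1:100, rep(140, 100), rep(85, 100), rep(1, 100))
  expect_error(validateSegment(short), "cover")
})

test_that("baseline normalisation and session summaries behave", {
  sc <- normalizeToBaseline(c(2, 4), c(1.5, 3))
  expect_equal(sc$begin, c(2, 4) / 3)
  expect_equal(sc$end, c(0.5, 1.0))
  same <- normalizeToBaseline(c(2, 4), c(4, 2))
  expect_equal(mean(same$begin), 1)
  expect_equal(mean(same$end), 1)
  expect_error(normalizeToBaseline(c(0, 0), c(1, 2)), "positive")
  s4 <- summarizeSessions(c(1, 2, 3, NA, 4))
  expect_equal(s4, 2.5, ignore_attr = TRUE)
  s3 <- summarizeSessions(c(1, 2, 3, NA, NA))
  expect_true(is.na(s3) && isTRUE(attr(s3, "flagged")))
  expect_equal(summarizeSessions(c(1, 2, 3), minSessions = 3), 2,
               ignore_attr = TRUE)
})
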
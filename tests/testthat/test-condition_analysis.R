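test_that("condition summaries report mean +/- SEM with n-1 denominator", {
  s <- summarizeCondition("ctrl", c(4, 5, 6))
  expect_identical(s@mean, 5)
  expect_equal(s@sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s@sem, 0.5774, tolerance = 1e-4)
  expect_true(s@semDefined)

  s1 <- summarizeCondition("single", 2)
  expect_identical(s1@mean, 2)
  expect_false(s1@semDefined)
  expect_true(is.na(s1@sem))

  # permutation invariance (values slot keeps input order, stats identical)
  a <- summarizeCondition("x", c(1, 3, 9, 2))
  b <- summarizeCondition("x", c(9, 2, 3, 1))
  expect_identical(a@mean, b@mean)
  expect_identical(a@sem, b@sem)

  expect_error(summarizeCondition("x", numeric(0)), "at least one")
})

test_that("identical samples compare to t = 0 (and degenerate paired p = 1)", {
  a <- summarizeCondition("a", c(1, 2, 3))
  cmp <- compareConditions(a, a)
  expect_identical(cmp@tStatistic, 0)
  expect_equal(cmp@pValue, 1)
  expect_false(cmp@degenerate)

  cmpP <- compareConditions(a, a, paired = TRUE)
  expect_identical(cmpP@tStatistic, 0)
  expect_identical(cmpP@pValue, 1)
  expect_true(cmpP@degenerate)
  expect_identical(cmpP@df, 2)
})

test_that("unpaired t matches the pooled-variance formula to 1e-6", {
  x <- c(5, 6, 7, 8); y <- c(1, 2, 3, 4)
  cmp <- compareConditions(summarizeCondition("a", x),
                           summarizeCondition("b", y))
  # independent reference: classic pooled two-sample formula
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tRef <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  pRef <- 2 * pt(-abs(tRef), nx + ny - 2)
  expect_equal(cmp@tStatistic, tRef, tolerance = 1e-6)
  expect_equal(cmp@pValue, pRef, tolerance = 1e-6)
  expect_identical(cmp@df, nx + ny - 2)

  # swapping the groups flips the sign of t and keeps p
  rev <- compareConditions(summarizeCondition("b", y),
                           summarizeCondition("a", x))
  expect_equal(rev@tStatistic, -cmp@tStatistic)
  expect_equal(rev@pValue, cmp@pValue)

  expect_error(compareConditions(summarizeCondition("a", 1),
                                 summarizeCondition("b", y)),
               "at least 2")
  expect_error(compareConditions(summarizeCondition("a", c(1, 2)),
                                 summarizeCondition("b", y), paired = TRUE),
               "equal")
})

test_that("paired t matches the difference-score formula", {
  x <- c(6.2, 4.8, 7.0, 5.5); y <- c(0.3, 0.5, 1.2, 0.2)
  cmp <- compareConditions(summarizeCondition("a", x),
                           summarizeCondition("b", y), paired = TRUE)
  d <- x - y
  tRef <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp@tStatistic, tRef, tolerance = 1e-6)
  expect_identical(cmp@df, 3)
})

test_that("SEM shrinks as 1/sqrt(n) on identically distributed inputs", {
  set.seed(99)
  avgSem <- vapply(c(4, 16, 64), function(n)
    mean(replicate(300, summarizeCondition("x", rnorm(n, 5, 2))@sem)),
    numeric(1))
  # each quadrupling of n should halve the SEM (up to sampling noise)
  expect_equal(avgSem[1] / avgSem[2], 2, tolerance = 0.15)
  expect_equal(avgSem[2] / avgSem[3], 2, tolerance = 0.15)
})

test_that("timecourse tabulates per-day SBPM and skips recordings without day", {
  prot <- data.frame(condition = c("d14", "d21", "d28"),
                     burstRate = c(1, 4, 8), nReplicates = 2,
                     day = c(14L, 21L, 28L))
  series <- generateConditionSeries(
    prot, baseSeed = 5, params = generatorParams(duration = 300))
  recs <- lapply(series, `[[`, "recording")
  tab <- timecourseTable(recs)
  expect_identical(tab$day, c(14L, 21L, 28L))
  expect_identical(tab$n, rep(2L, 3))
  expect_true(all(diff(tab$meanSBPM) > 0))  # development: rate rises
  expect_length(attr(tab, "skipped"), 0)

  # a recording without day metadata lands in the skipped list
  noday <- generateRecording(generatorParams(duration = 60, seed = 1),
                             recordingId = "noday")$recording
  tab2 <- timecourseTable(c(recs[1:2], list(noday)))
  expect_identical(attr(tab2, "skipped"), "noday")
  expect_identical(nrow(tab2), 1L)

  empty <- timecourseTable(list())
  expect_identical(nrow(empty), 0L)
})

test_that("one recording per day yields one row per day with n = 1", {
  recs <- lapply(1:3, function(d)
    generateRecording(generatorParams(duration = 60, seed = d),
                      dayFromInduction = d * 7)$recording)
  tab <- timecourseTable(recs)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$n, rep(1L, 3))
  expect_true(all(is.na(tab$sem)))
})
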
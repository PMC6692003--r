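# Per-electrode stage: the max-interval rule -------------------------------

test_that("max-interval rule finds exactly the hand-traced runs", {
  p <- detectorParams()

  # ISIs too long: no burst
  expect_identical(nrow(detectElectrodeBursts(c(0, 1, 2), p)), 0L)

  # five spikes at 20 ms ISIs: one burst spanning first to last spike
  b <- detectElectrodeBursts(c(10.00, 10.02, 10.04, 10.06, 10.08), p)
  expect_identical(nrow(b), 1L)
  expect_equal(b$tStart, 10.00)
  expect_equal(b$tEnd, 10.08)
  expect_identical(b$nSpikes, 5L)

  # two runs separated by a 1 s gap: two disjoint bursts
  run1 <- seq(1, 1.2, by = 0.05)
  run2 <- seq(2.2, 2.4, by = 0.05)
  b <- detectElectrodeBursts(c(run1, run2), p)
  expect_identical(nrow(b), 2L)
  expect_true(b$tEnd[1] < b$tStart[2])
  expect_equal(b$tStart, c(1, 2.2))

  # run of 4 spikes is below minSpikes = 5
  expect_identical(nrow(detectElectrodeBursts(seq(1, 1.15, by = 0.05), p)),
                   0L)

  # boundary ISI exactly isiMax still links (0.125 is exact in binary)
  b <- detectElectrodeBursts((0:4) * 0.125,
                             detectorParams(isiMax = 0.125))
  expect_identical(nrow(b), 1L)
  expect_identical(b$nSpikes, 5L)
})

test_that("per-electrode bursts are disjoint and cover their spikes", {
  p <- detectorParams(minSpikes = 3)
  set.seed(11)
  for (k in 1:20) {
    t <- sort(runif(200, 0, 60))
    b <- detectElectrodeBursts(t, p)
    if (nrow(b) > 1)
      expect_true(all(b$tStart[-1] > b$tEnd[-nrow(b)]))
    if (nrow(b) > 0) {
      expect_true(all(b$tEnd >= b$tStart))
      expect_true(all(b$nSpikes >= 3L))
      # counted spikes really lie inside the burst interval
      for (i in seq_len(nrow(b)))
        expect_identical(sum(t >= b$tStart[i] & t <= b$tEnd[i]),
                         as.integer(b$nSpikes[i]))
    }
  }
})

# Participation trace -------------------------------------------------------

test_that("participation counts match direct interval/bin enumeration", {
  p <- detectorParams(activeRateMin = 0.01)
  # one electrode bursting [1.0, 1.1]: counts 1 exactly in overlapped bins
  rec <- MEARecording(list("12" = seq(1, 1.1, by = 0.02)), duration = 2)
  tr <- participationTrace(rec, params = p)
  edges <- binEdges(tr)
  counts <- binCounts(tr)
  # direct enumeration with closed intervals (boundaries count both sides)
  expected <- as.integer(edges[-length(edges)] <= 1.1 & edges[-1] >= 1.0)
  expect_identical(counts, expected)
  expect_identical(sum(counts), 6L)  # bins [0.975,1] .. [1.1,1.125]

  # no bursts anywhere: all-zero trace tiling the full duration
  rec0 <- MEARecording(list("12" = c(0.5, 1.5)), duration = 2)
  tr0 <- participationTrace(rec0, params = p)
  expect_true(all(binCounts(tr0) == 0L))
  expect_identical(length(binCounts(tr0)), as.integer(2 / p@binWidth))

  # counts never exceed channel count
  rec2 <- MEARecording(list("12" = seq(1, 1.1, by = 0.02),
                            "13" = seq(1, 1.1, by = 0.02)), duration = 2)
  expect_true(all(binCounts(participationTrace(rec2, params = p)) <= 2L))
})

test_that("dead electrodes are excluded by the active-rate filter", {
  # burst on an electrode whose overall rate is below activeRateMin
  rec <- MEARecording(list("12" = seq(100, 100.08, by = 0.02)),
                      duration = 600)  # 5 spikes / 600 s < 0.1 Hz
  tr <- participationTrace(rec, params = detectorParams())
  expect_true(all(binCounts(tr) == 0L))
})

# Network-burst stage -------------------------------------------------------

syntheticCoburst <- function(nElec, intervals, duration = 20,
                             isi = 0.01) {
  labs <- electrodeLabels()[seq_len(nElec)]
  spikes <- lapply(labs, function(e)
    sort(unlist(lapply(seq_len(nrow(intervals)), function(k)
      seq(intervals$tStart[k], intervals$tEnd[k], by = isi)))))
  MEARecording(setNames(spikes, labs), duration = duration)
}

test_that("co-bursting below the participation threshold is not a network burst", {
  p <- detectorParams(activeRateMin = 0.01)
  rec <- syntheticCoburst(3, data.frame(tStart = 5, tEnd = 5.8))
  res <- runDetector(rec, p)
  expect_identical(res@nBursts, 0L)
})

test_that("candidates within the merge gap fuse into one network burst", {
  p <- detectorParams(activeRateMin = 0.01)
  ints <- data.frame(tStart = c(5.0, 5.95), tEnd = c(5.8, 6.5))
  rec <- syntheticCoburst(10, ints)
  trace <- participationTrace(rec, params = p)
  nb <- detectNetworkBursts(trace, rec, p)
  expect_identical(nrow(nb), 1L)
  expect_lte(nb$tStart, 5.0)
  expect_gte(nb$tEnd, 6.5)
  expect_identical(nb$peakParticipation, 10L)
  expect_identical(sort(nb$electrodes[[1]]),
                   sort(electrodeLabels()[1:10]))

  # with a gap wider than mergeGap they stay separate
  ints2 <- data.frame(tStart = c(5.0, 7.0), tEnd = c(5.8, 7.5))
  rec2 <- syntheticCoburst(10, ints2)
  nb2 <- detectNetworkBursts(participationTrace(rec2, params = p), rec2, p)
  expect_identical(nrow(nb2), 2L)
  expect_gt(nb2$tStart[2] - nb2$tEnd[1], p@mergeGap)
})

test_that("all-zero trace yields no network bursts", {
  rec <- MEARecording(list("12" = c(1, 2, 3)), duration = 10)
  tr <- participationTrace(rec, params = detectorParams())
  expect_identical(nrow(detectNetworkBursts(tr, rec, detectorParams())), 0L)
})

# SBPM ----------------------------------------------------------------------

test_that("SBPM is bursts per minute exactly", {
  expect_identical(sbpm(computeSBPM(0L, 600)), 0)
  expect_identical(sbpm(computeSBPM(3L, 600)), 0.3)
  expect_identical(sbpm(computeSBPM(41L, 600)), 4.1)
  r <- computeSBPM(7L, 123)
  expect_identical(r@sbpm * r@durationMin, 7)
  expect_error(computeSBPM(3L, 0), "positive")
  expect_error(computeSBPM(3L, -5), "positive")
})

# Whole-detector properties -------------------------------------------------

test_that("the detector is deterministic and handles empty recordings", {
  expect_identical(sbpm(runDetector(MEARecording(list(), duration = 600))),
                   0)
  out <- generateRecording(generatorParams(duration = 120, seed = 5))
  r1 <- runDetector(out$recording)
  r2 <- runDetector(out$recording)
  expect_identical(r1, r2)
})

test_that("lowering participationMin never decreases the burst count", {
  out <- generateRecording(generatorParams(duration = 300, seed = 9,
                                           participationFraction = 0.3))
  counts <- vapply(c(20L, 10L, 5L, 3L, 2L), function(pm)
    runDetector(out$recording,
                detectorParams(participationMin = pm))@nBursts,
    integer(1))
  expect_true(all(diff(counts) >= 0L))
})
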
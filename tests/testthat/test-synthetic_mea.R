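test_that("zero burst rate gives pure background; zero everything is silent", {
  out <- generateRecording(generatorParams(burstRate = 0, duration = 60,
                                           seed = 2))
  expect_identical(nrow(networkBursts(out$truth)), 0L)
  expect_gt(nSpikes(out$recording), 0)

  silent <- generateRecording(generatorParams(burstRate = 0,
                                              backgroundRate = 0,
                                              duration = 60, seed = 2))
  expect_identical(nSpikes(silent$recording), 0L)
  expect_true(validateRecording(silent$recording)@ok)
})

test_that("unsatisfiable burst rates are a parameter error", {
  expect_error(generatorParams(burstRate = 40, refractoryGap = 1),
               "unsatisfiable")
})

test_that("planted burst count matches an independent renewal-process oracle", {
  # the generator's onset process: dead-time renewal with exponential
  # waiting beyond (duration + gap), rate-adjusted so the long-run onset
  # rate is exactly burstRate. Oracle: direct re-simulation from the
  # process definition, written independently of the generator code.
  lambda <- 6; T <- 600; gap <- 1
  medianDur <- 0.8; sigmaDur <- 0.4
  meanDur <- medianDur * exp(sigmaDur^2 / 2)
  waitMean <- 60 / lambda - meanDur - gap
  nSim <- 200
  oracleCounts <- withr::with_seed(4242, vapply(seq_len(nSim), function(k) {
    tEnd <- 0; cnt <- 0L
    t <- tEnd + rexp(1, 1 / waitMean)
    repeat {
      if (t >= T) break
      d <- rlnorm(1, log(medianDur), sigmaDur)
      if (t + d > T) break
      cnt <- cnt + 1L
      t <- t + d + gap + rexp(1, 1 / waitMean)
    }
    cnt
  }, integer(1)))
  # drawBurstIntervals consumes the session RNG; fix it per draw
  genCounts <- vapply(seq_len(nSim), function(sd)
    withr::with_seed(sd, nrow(synchroburst:::drawBurstIntervals(
      lambda, T, medianDur, sigmaDur, gap))), integer(1))
  se <- sqrt(var(oracleCounts) / nSim + var(genCounts) / nSim)
  expect_lt(abs(mean(genCounts) - mean(oracleCounts)), 3 * se)
  # and the long-run rate is the requested one
  expect_lt(abs(mean(genCounts) - lambda * T / 60), 3 * sd(genCounts) /
              sqrt(nSim))
})

test_that("ground-truth intervals respect gap and range invariants (fuzz)", {
  set.seed(77)
  for (k in 1:100) {
    lambda <- runif(1, 0.5, 12)
    gap <- runif(1, 0.2, 2)
    dur <- runif(1, 60, 400)
    md <- runif(1, 0.3, 1.2)
    sg <- runif(1, 0.1, 0.6)
    if (60 / lambda <= md * exp(sg^2 / 2) + gap) next
    ints <- synchroburst:::drawBurstIntervals(lambda, dur, md, sg, gap)
    if (nrow(ints) == 0) next
    expect_true(all(ints$tStart >= 0 & ints$tEnd <= dur))
    expect_true(all(ints$tEnd > ints$tStart))
    if (nrow(ints) > 1)
      expect_true(all(ints$tStart[-1] - ints$tEnd[-nrow(ints)] >=
                        gap - 1e-9))
  }
})

test_that("generation is deterministic given the seed", {
  a <- generateRecording(generatorParams(duration = 120, seed = 31))
  b <- generateRecording(generatorParams(duration = 120, seed = 31))
  expect_identical(a$recording@spikes, b$recording@spikes)
  expect_identical(a$truth@bursts, b$truth@bursts)
  c <- generateRecording(generatorParams(duration = 120, seed = 32))
  expect_false(identical(a$recording@spikes, c$recording@spikes))
})

test_that("condition series bookkeeping: labels, replicates, distinct seeds", {
  prot <- data.frame(condition = c("a", "b", "c", "d"),
                     burstRate = c(7, 2.5, 1, 5.5),
                     nReplicates = 4)
  series <- generateConditionSeries(
    prot, baseSeed = 1, params = generatorParams(duration = 30))
  expect_length(series, 16)
  labs <- vapply(series, function(x) conditionLabel(x$recording),
                 character(1))
  expect_identical(labs, rep(c("a", "b", "c", "d"), each = 4))
  reps <- vapply(series, function(x) x$recording@replicateId, character(1))
  expect_identical(reps, rep(paste0("r", 1:4), 4))
  sp <- lapply(series, function(x) x$recording@spikes)
  expect_identical(anyDuplicated(sp), 0L)
})

test_that("detected SBPM per condition orders like the planted rates", {
  prot <- data.frame(condition = c("glcA", "depl", "starv", "glcB"),
                     burstRate = c(7, 2.5, 1, 5.5),
                     nReplicates = 4)
  series <- generateConditionSeries(
    prot, baseSeed = 11, params = generatorParams(duration = 300))
  det <- vapply(series, function(x) sbpm(runDetector(x$recording)),
                numeric(1))
  lab <- vapply(series, function(x) conditionLabel(x$recording),
                character(1))
  means <- tapply(det, lab, mean)[prot$condition]
  expect_identical(order(means), order(prot$burstRate))
})
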
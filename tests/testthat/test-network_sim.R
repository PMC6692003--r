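# Connectivity --------------------------------------------------------------

test_that("connection probability limits behave exactly", {
  cfg0 <- networkConfig(pMax = 0, gridRows = 6, gridCols = 6)
  expect_identical(nrow(buildLatticeConnectivity(cfg0)), 0L)

  cfgAll <- networkConfig(pMax = 1, lambdaD = 1e9, gridRows = 6,
                          gridCols = 6)
  g <- buildLatticeConnectivity(cfgAll)
  expect_identical(nrow(g), 36L * 35L)
  expect_false(any(g$from == g$to))
})

test_that("edge count agrees with the brute-force expected count", {
  cfg <- networkConfig()  # 20x20, pMax 0.6, lambdaD 2
  n <- 400
  x <- (seq_len(n) - 1L) %% 20; y <- (seq_len(n) - 1L) %/% 20
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  p <- 0.6 * exp(-d / 2); diag(p) <- 0
  expected <- sum(p)
  sdEdges <- sqrt(sum(p * (1 - p)))
  g <- buildLatticeConnectivity(cfg)
  expect_lt(abs(nrow(g) - expected), 4 * sdEdges)
  # reproducible from the seed
  g2 <- buildLatticeConnectivity(cfg)
  expect_identical(g, g2)
})

# Membrane model -------------------------------------------------------------

test_that("the resting fixed point solves to near-zero derivatives", {
  cfg <- networkConfig()
  restV <- uniroot(function(V) {
    r <- synchroburst:::hhRates(V)
    n <- r[["an"]] / (r[["an"]] + r[["bn"]])
    h <- r[["ah"]] / (r[["ah"]] + r[["bh"]])
    hhDerivatives(V, n, h, config = cfg)[["dV"]]
  }, c(-80, -50), tol = 1e-12)$root
  r <- synchroburst:::hhRates(restV)
  n <- r[["an"]] / (r[["an"]] + r[["bn"]])
  h <- r[["ah"]] / (r[["ah"]] + r[["bh"]])
  d <- hhDerivatives(restV, n, h, config = cfg)
  expect_lt(max(abs(d)), 1e-6)
  expect_gt(restV, -70); expect_lt(restV, -60)
})

test_that("current factor structure: h = 0 kills the sodium current", {
  cfg <- networkConfig()
  cfgNoNa <- networkConfig(gNa = 0)
  dv1 <- hhDerivatives(-30, 0.4, 0, config = cfg)[["dV"]]
  dv2 <- hhDerivatives(-30, 0.4, 0, config = cfgNoNa)[["dV"]]
  expect_identical(dv1, dv2)
  # leak reversal: V = eL with everything else off gives dV = 0
  d <- hhDerivatives(-54.4, 0, 0, config = networkConfig(eL = -54.4))
  expect_identical(d[["dV"]], 0)
})

# Vesicle pool and metabolism ------------------------------------------------

test_that("release arithmetic and the geometric depletion bound", {
  cfg <- networkConfig(U = 0.5, cA = 0.6)
  r1 <- onPresynapticSpike(1, 1, cfg)
  expect_identical(r1$released, 0.5)
  expect_identical(r1$D, 0.5)
  expect_equal(r1$A, 1 - 0.6 * 0.5)

  # empty pool: nothing happens
  r0 <- onPresynapticSpike(0, 0.7, cfg)
  expect_identical(r0$released, 0)
  expect_identical(r0$D, 0)
  expect_identical(r0$A, 0.7)

  # two consecutive spikes with no recovery: cumulative release 0.75
  r2 <- onPresynapticSpike(r1$D, r1$A, cfg)
  expect_equal(r1$released + r2$released, 0.75)

  # k spikes never release more than the initial pool
  D <- 1; A <- 1; total <- 0
  for (k in 1:50) {
    r <- onPresynapticSpike(D, A, cfg)
    total <- total + r$released; D <- r$D; A <- r$A
  }
  expect_lt(total, 1)
  expect_gte(D, 0)
  expect_gte(A, 0)
})

test_that("recovery rate is Michaelis-Menten in the energy store", {
  cfg <- networkConfig(kRec0 = 1, KA = 0.2)
  expect_identical(effectiveRecoveryRate(0, cfg), 0)
  expect_equal(effectiveRecoveryRate(0.2, cfg), 0.5)
  grid <- seq(0.001, 1, length.out = 100)
  expect_true(all(diff(effectiveRecoveryRate(grid, cfg)) > 0))
})

# Integrator -----------------------------------------------------------------

test_that("no drive means no spikes", {
  cfg <- networkConfig(gridRows = 4, gridCols = 4, duration = 2,
                       gMax = 0, gNa = 0, nuExt = 0)
  expect_identical(nSpikes(simulateNetwork(cfg)), 0L)
})

test_that("identical config and seed give bit-identical rasters", {
  cfg <- networkConfig(gridRows = 8, gridCols = 8, duration = 5, seed = 21)
  s1 <- simulateNetwork(cfg)
  s2 <- simulateNetwork(cfg)
  expect_identical(raster(s1), raster(s2))
  s3 <- simulateNetwork(networkConfig(gridRows = 8, gridCols = 8,
                                      duration = 5, seed = 22))
  expect_false(identical(raster(s1), raster(s3)))
})

test_that("raster respects duration, refractoriness and index bounds", {
  cfg <- networkConfig(gridRows = 8, gridCols = 8, duration = 5, seed = 3,
                       nuExt = 2)
  r <- raster(simulateNetwork(cfg))
  expect_true(all(r$time >= 0 & r$time <= 5))
  expect_true(all(r$neuron >= 1 & r$neuron <= 64))
  for (nn in unique(r$neuron)) {
    t <- r$time[r$neuron == nn]
    if (length(t) > 1)
      expect_true(all(diff(sort(t)) >= 0.002 - 1e-12))
  }
})

test_that("docked pool and energy store stay in [0,1] under config fuzzing", {
  worst <- fuzzBounds()
  expect_gte(worst$Dmin, 0); expect_lte(worst$Dmax, 1)
  expect_gte(worst$Amin, 0); expect_lte(worst$Amax, 1)
})

test_that("state traces expose depletion during activity", {
  cfg <- networkConfig(gridRows = 6, gridCols = 6, duration = 5, seed = 8,
                       nuExt = 2, traceNeurons = c(1L, 18L), traceDt = 1)
  s <- simulateNetwork(cfg)
  expect_identical(colnames(s@traces$V), c("1", "18"))
  expect_identical(nrow(s@traces$D), length(s@traces$time))
  expect_true(all(s@traces$D >= 0 & s@traces$D <= 1))
  expect_true(all(s@traces$A >= 0 & s@traces$A <= 1))
  # neurons that spiked must have released vesicles at some point
  spiked <- unique(raster(s)$neuron)
  for (nn in intersect(spiked, c(1L, 18L)))
    expect_lt(min(s@traces$D[, as.character(nn)]), 1)
})

# Electrode mapping ----------------------------------------------------------

test_that("default pools partition the lattice into 60 electrodes", {
  pools <- synchroburst:::defaultElectrodePools(20, 20)
  expect_length(pools, 60)
  expect_identical(sort(names(pools)), electrodeLabels())
  all <- unlist(pools, use.names = FALSE)
  expect_identical(sort(all), 1:400)  # disjoint and exhaustive
})

test_that("spike mapping conserves counts and routes single neurons", {
  cfg <- networkConfig(duration = 10)
  mk <- function(rasterDf) new("SimulationResult", raster = rasterDf,
                               config = cfg, traces = list(),
                               diagnostics = list())
  empty <- mk(data.frame(neuron = integer(0), time = numeric(0)))
  recE <- resultToRecording(empty)
  expect_length(electrodeIds(recE), 60)
  expect_identical(nSpikes(recE), 0L)

  one <- mk(data.frame(neuron = c(57L, 57L, 57L), time = c(1, 2, 3)))
  rec1 <- resultToRecording(one)
  nz <- Filter(length, rec1@spikes)
  expect_length(nz, 1)
  expect_identical(unname(nz[[1]]), c(1, 2, 3))

  cfgS <- networkConfig(gridRows = 8, gridCols = 8, duration = 5, seed = 3,
                        nuExt = 2)
  s <- simulateNetwork(cfgS)
  rec <- resultToRecording(s)
  expect_identical(nSpikes(rec), nrow(raster(s)))

  expect_error(resultToRecording(s, pools = list("12" = 1:4, "13" = 4:8)),
               "overlap")
})
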
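# Shared fixtures and a memoising cache for the heavier network
# simulations, so that module-level property tests and the acceptance
# suite reuse the same runs instead of recomputing them.

.simCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .simCache, inherits = FALSE))
    assign(key, force(expr), envir = .simCache)
  get(key, envir = .simCache, inherits = FALSE)
}

# SBPM + spike count of one simulated recording under a config override set
simSBPM <- function(seed, duration, ...) {
  cfg <- networkConfig(duration = duration, seed = seed, ...)
  sim <- simulateNetwork(cfg)
  res <- runDetector(resultToRecording(sim))
  list(sbpm = sbpm(res), nBursts = res@nBursts, nSpikes = nSpikes(sim))
}

# CNQX analog (all synaptic conductances zero), 5 seeds x 300 s
cnqxRuns <- function() cached("cnqx", lapply(1:5, function(sd)
  simSBPM(sd, duration = 300, gMax = 0)))

# glucose contrast, 5 seeds x 60 s per level
glucoseRuns <- function(G) cached(paste0("glc", G), lapply(1:5, function(sd)
  simSBPM(sd, duration = 60, glucose = G)))

# vesicle-recovery-rate scaling (CMA analog), 10 seeds x 20 s per level
krecTrend <- function() cached("krec", {
  scales <- c(1, 0.5, 0.25, 0.1, 0.01)
  means <- vapply(scales, function(sc) {
    mean(vapply(1:10, function(sd)
      simSBPM(sd, duration = 20, kRec0 = sc * 1)$sbpm, numeric(1)))
  }, numeric(1))
  data.frame(scale = scales, meanSBPM = means)
})

# 100 randomized configurations x 10 s: worst-case extrema of the bounded
# state variables D and A across all runs
fuzzBounds <- function() cached("fuzz", {
  set.seed(1234)
  worst <- list(Dmin = 1, Dmax = 1, Amin = 1, Amax = 1)
  for (k in 1:100) {
    side <- sample(3:8, 2, replace = TRUE)
    cfg <- networkConfig(
      gridRows = side[1], gridCols = side[2], duration = 10,
      seed = sample.int(1e6, 1),
      pMax = runif(1), lambdaD = runif(1, 0.5, 5),
      gMax = runif(1, 0, 2), U = runif(1, 0.05, 1),
      kRec0 = runif(1, 0, 5), glucose = runif(1),
      kGenMax = runif(1, 0, 2), KA = runif(1, 0.01, 1),
      cA = runif(1, 0, 2), nuExt = runif(1, 0, 5),
      gExt = runif(1, 0, 1.2))
    dg <- simulateNetwork(cfg)@diagnostics
    worst$Dmin <- min(worst$Dmin, dg$Dmin)
    worst$Dmax <- max(worst$Dmax, dg$Dmax)
    worst$Amin <- min(worst$Amin, dg$Amin)
    worst$Amax <- max(worst$Amax, dg$Amax)
  }
  worst
})

# detector round trip on generator defaults, 20 seeds x 600 s
roundTripRuns <- function() cached("roundtrip", lapply(1:20, function(sd) {
  out <- generateRecording(generatorParams(seed = sd))
  det <- runDetector(out$recording)
  list(truth = out$truth, det = det)
}))

# interval-overlap matching of detected vs planted bursts
matchBursts <- function(det, planted) {
  if (nrow(det) == 0 || nrow(planted) == 0)
    return(list(tp = 0L, nDet = nrow(det), nPlanted = nrow(planted)))
  hit <- logical(nrow(planted))
  detMatched <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ov <- which(planted$tStart <= det$tEnd[i] &
                  planted$tEnd >= det$tStart[i] & !hit)
    if (length(ov)) {
      hit[ov[1]] <- TRUE
      detMatched[i] <- TRUE
    } else if (any(planted$tStart <= det$tEnd[i] &
                     planted$tEnd >= det$tStart[i])) {
      detMatched[i] <- TRUE  # overlaps an already-claimed planted burst
    }
  }
  list(tp = sum(hit), nDetMatched = sum(detMatched), nDet = nrow(det),
       nPlanted = nrow(planted))
}
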
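#' GeneratorParams: synthetic MEA recording parameters
#'
#' Parameters for the synthetic-recording generator, which emulates a mature
#' cultured excitatory network on a 60-electrode MEA: sparse background
#' spiking on every electrode plus network-wide synchronized bursts — short
#' (~1 s) high-frequency spike trains whose onsets coincide (up to a small
#' jitter) across most electrodes. Planted burst intervals are returned as
#' ground truth for round-trip detector validation.
#'
#' Burst onsets follow a dead-time renewal process: after each burst a
#' refractory gap of `refractoryGap` seconds is enforced, and the
#' exponential waiting time beyond the gap is rate-adjusted so the long-run
#' planted burst rate equals `burstRate` exactly.
#'
#' @slot nElectrodes integer, number of electrodes (default 60).
#' @slot duration numeric, recording length in seconds (default 600).
#' @slot backgroundRate numeric, background Poisson rate per electrode in Hz
#'   (default 0.5).
#' @slot burstRate numeric, planted network-burst rate in bursts/min.
#' @slot burstDurationMedian,burstDurationSigma numeric, log-normal burst
#'   duration parameters (median 0.8 s, sigma 0.4).
#' @slot withinBurstRate numeric, in-burst Poisson rate per participating
#'   electrode in Hz (default 80).
#' @slot participationFraction numeric in (0,1], fraction of electrodes
#'   participating in each burst (default 0.8).
#' @slot onsetJitter numeric, electrode-specific onset jitter in seconds
#'   (uniform on `[0, onsetJitter]`, default 0.01).
#' @slot refractoryGap numeric, minimum gap between burst intervals
#'   (default 1 s).
#' @slot rateMultipliers numeric, optional per-electrode background-rate
#'   multipliers (recycled; default 1 = homogeneous).
#' @slot seed integer RNG seed.
#' @name GeneratorParams-class
#' @exportClass GeneratorParams
setClass("GeneratorParams",
  slots = c(nElectrodes = "integer", duration = "numeric",
            backgroundRate = "numeric", burstRate = "numeric",
            burstDurationMedian = "numeric", burstDurationSigma = "numeric",
            withinBurstRate = "numeric", participationFraction = "numeric",
            onsetJitter = "numeric", refractoryGap = "numeric",
            rateMultipliers = "numeric", seed = "integer"),
  prototype = list(nElectrodes = 60L, duration = 600,
                   backgroundRate = 0.5, burstRate = 4,
                   burstDurationMedian = 0.8, burstDurationSigma = 0.4,
                   withinBurstRate = 80, participationFraction = 0.8,
                   onsetJitter = 0.01, refractoryGap = 1,
                   rateMultipliers = 1, seed = 1L))

setValidity("GeneratorParams", function(object) {
  msgs <- character(0)
  if (object@duration <= 0) msgs <- c(msgs, "duration must be positive")
  if (object@nElectrodes < 1L || object@nElectrodes > 60L)
    msgs <- c(msgs, "nElectrodes must be in 1..60")
  for (s in c("backgroundRate", "burstRate", "withinBurstRate",
              "onsetJitter", "refractoryGap"))
    if (slot(object, s) < 0) msgs <- c(msgs, paste(s, "must be >= 0"))
  if (object@participationFraction <= 0 || object@participationFraction > 1)
    msgs <- c(msgs, "participationFraction must be in (0, 1]")
  if (object@burstRate > 0) {
    meanDur <- object@burstDurationMedian *
      exp(object@burstDurationSigma^2 / 2)
    if (60 / object@burstRate <= meanDur + object@refractoryGap)
      msgs <- c(msgs, paste0(
        "burstRate unsatisfiable: mean inter-onset interval (",
        format(60 / object@burstRate, digits = 3),
        " s) does not exceed mean burst duration + refractory gap"))
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname GeneratorParams-class
#' @param nElectrodes,duration,backgroundRate,burstRate,burstDurationMedian
#'   see slots.
#' @param burstDurationSigma,withinBurstRate,participationFraction see slots.
#' @param onsetJitter,refractoryGap,rateMultipliers,seed see slots.
#' @return `generatorParams()` returns a validated `GeneratorParams`.
#' @examples
#' generatorParams(burstRate = 6, seed = 42)
#' @export
generatorParams <- function(nElectrodes = 60, duration = 600,
                            backgroundRate = 0.5, burstRate = 4,
                            burstDurationMedian = 0.8,
                            burstDurationSigma = 0.4,
                            withinBurstRate = 80,
                            participationFraction = 0.8,
                            onsetJitter = 0.01, refractoryGap = 1,
                            rateMultipliers = 1, seed = 1) {
  new("GeneratorParams", nElectrodes = as.integer(nElectrodes),
      duration = duration, backgroundRate = backgroundRate,
      burstRate = burstRate, burstDurationMedian = burstDurationMedian,
      burstDurationSigma = burstDurationSigma,
      withinBurstRate = withinBurstRate,
      participationFraction = participationFraction,
      onsetJitter = onsetJitter, refractoryGap = refractoryGap,
      rateMultipliers = rateMultipliers, seed = as.integer(seed))
}

#' GroundTruth: planted bursts of a synthetic recording
#'
#' @slot bursts data.frame with `tStart`, `tEnd` of each planted network
#'   burst (disjoint, separated by at least the refractory gap).
#' @slot participants list of character vectors, participating electrodes
#'   per burst.
#' @slot burstRate numeric, the planted rate (bursts/min).
#' @slot backgroundRate numeric, background rate (Hz/electrode).
#' @name GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(bursts = "data.frame", participants = "list",
            burstRate = "numeric", backgroundRate = "numeric"))

setValidity("GroundTruth", function(object) {
  b <- object@bursts
  if (nrow(b) != length(object@participants))
    return("participants must have one entry per burst")
  if (nrow(b) > 1 && any(diff(b$tStart) <= 0))
    return("bursts must be in increasing time order")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: ", nrow(object@bursts), " planted burst(s), rate ",
      object@burstRate, "/min, background ", object@backgroundRate,
      " Hz/electrode\n", sep = "")
})

#' @rdname synchroburst-generics
#' @export
setMethod("networkBursts", "GroundTruth", function(x) x@bursts)

# Draw planted burst intervals: dead-time renewal onsets with the
# exponential rate adjusted so the long-run onset rate is exactly
# `ratePerMin`; durations log-normal; bursts running past `duration` are
# discarded. Consumes the caller's RNG stream.
drawBurstIntervals <- function(ratePerMin, duration, medianDur, sigmaDur,
                               gap) {
  if (ratePerMin <= 0)
    return(data.frame(tStart = numeric(0), tEnd = numeric(0)))
  meanDur <- medianDur * exp(sigmaDur^2 / 2)
  waitMean <- 60 / ratePerMin - meanDur - gap
  stopifnot(waitMean > 0)
  t0 <- numeric(0); t1 <- numeric(0)
  t <- rexp(1, rate = 1 / waitMean)
  while (t < duration) {
    d <- rlnorm(1, meanlog = log(medianDur), sdlog = sigmaDur)
    if (t + d > duration) break
    t0 <- c(t0, t); t1 <- c(t1, t + d)
    t <- t + d + gap + rexp(1, rate = 1 / waitMean)
  }
  data.frame(tStart = t0, tEnd = t1)
}

poissonTimes <- function(rate, from, to) {
  if (rate <= 0 || to <= from) return(numeric(0))
  n <- rpois(1, rate * (to - from))
  sort(runif(n, from, to))
}

#' Generate a synthetic MEA recording with planted ground truth
#'
#' Draws planted network-burst intervals (dead-time renewal onsets at the
#' requested rate, log-normal durations), assigns
#' `ceiling(participationFraction * nElectrodes)` random electrodes to each
#' burst, gives each participating electrode an independent Poisson spike
#' train at `withinBurstRate` over the burst interval (onset shifted by an
#' electrode-specific jitter; all electrodes share the burst end), and
#' superimposes independent background Poisson spiking at `backgroundRate`
#' on all electrodes for the whole duration. Deterministic given
#' `params@seed`.
#'
#' @param params a [GeneratorParams-class].
#' @param recordingId,condition,dayFromInduction,replicateId metadata
#'   passed to the [MEARecording-class].
#' @return A list with elements `recording` ([MEARecording-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' out <- generateRecording(generatorParams(duration = 60, seed = 7))
#' nrow(networkBursts(out$truth))
#' @export
generateRecording <- function(params = generatorParams(),
                              recordingId = "synthetic", condition = NA,
                              dayFromInduction = NA, replicateId = NA) {
  stopifnot(is(params, "GeneratorParams"))
  validObject(params)
  withSeed(params@seed, {
    elecs <- electrodeLabels()[seq_len(params@nElectrodes)]
    mult <- rep_len(params@rateMultipliers, params@nElectrodes)
    ints <- drawBurstIntervals(params@burstRate, params@duration,
                               params@burstDurationMedian,
                               params@burstDurationSigma,
                               params@refractoryGap)
    nPart <- as.integer(ceiling(params@participationFraction *
                                  params@nElectrodes))
    participants <- vector("list", nrow(ints))
    spikes <- setNames(vector("list", params@nElectrodes), elecs)
    for (e in elecs) spikes[[e]] <- list()
    for (k in seq_len(nrow(ints))) {
      part <- sample(elecs, nPart)
      participants[[k]] <- sort(part)
      for (e in part) {
        onset <- ints$tStart[k] +
          if (params@onsetJitter > 0) runif(1, 0, params@onsetJitter) else 0
        tr <- poissonTimes(params@withinBurstRate, min(onset, ints$tEnd[k]),
                           ints$tEnd[k])
        spikes[[e]] <- c(spikes[[e]], list(tr))
      }
    }
    for (i in seq_along(elecs)) {
      e <- elecs[i]
      bg <- poissonTimes(params@backgroundRate * mult[i], 0,
                         params@duration)
      spikes[[e]] <- sort(unlist(c(spikes[[e]], list(bg))))
    }
    rec <- MEARecording(spikes, duration = params@duration,
                        recordingId = recordingId, condition = condition,
                        dayFromInduction = dayFromInduction,
                        replicateId = replicateId)
    truth <- new("GroundTruth", bursts = ints, participants = participants,
                 burstRate = params@burstRate,
                 backgroundRate = params@backgroundRate)
    list(recording = rec, truth = truth)
  })
}

#' Generate a series of recordings over experimental conditions
#'
#' Emulates the shape of a depletion-repletion (or developmental) MEA
#' experiment: for each row of `protocol` (a condition with its planted
#' burst rate and replicate count) one synthetic recording per replicate is
#' generated with a derived, documented seed
#' (`baseSeed + 100 * conditionIndex + replicateIndex`), and the condition
#' label (and optional `day` column) is stored in the recording metadata.
#'
#' @param protocol data.frame with columns `condition` (character),
#'   `burstRate` (bursts/min), `nReplicates` (integer) and optionally `day`
#'   (integer, stored as `dayFromInduction`).
#' @param baseSeed integer base seed.
#' @param params a [GeneratorParams-class] template; its `burstRate` and
#'   `seed` are overridden per recording.
#' @return A list of `list(recording, truth)` pairs, one per replicate per
#'   condition, in protocol order.
#' @examples
#' prot <- data.frame(condition = c("ctrl", "depleted"),
#'                    burstRate = c(6, 1), nReplicates = 2)
#' series <- generateConditionSeries(prot, baseSeed = 1,
#'   params = generatorParams(duration = 60))
#' length(series)  # 4
#' @export
generateConditionSeries <- function(protocol, baseSeed = 1,
                                    params = generatorParams()) {
  stopifnot(is.data.frame(protocol),
            all(c("condition", "burstRate", "nReplicates") %in%
                  names(protocol)))
  out <- list()
  for (i in seq_len(nrow(protocol))) {
    for (j in seq_len(protocol$nReplicates[i])) {
      p <- params
      p@burstRate <- protocol$burstRate[i]
      p@seed <- as.integer(baseSeed + 100L * i + j)
      validObject(p)
      out[[length(out) + 1L]] <- generateRecording(
        p,
        recordingId = sprintf("%s_r%d", protocol$condition[i], j),
        condition = protocol$condition[i],
        dayFromInduction = if ("day" %in% names(protocol))
          protocol$day[i] else NA,
        replicateId = sprintf("r%d", j))
    }
  }
  out
}
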
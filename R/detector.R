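#' DetectorParams: tuning parameters of the synchronous-burst detector
#'
#' The detector works in two stages. Stage one finds per-electrode bursts by
#' the max-interval rule: maximal runs of at least `minSpikes` spikes whose
#' consecutive inter-spike intervals are all at most `isiMax` seconds. Stage
#' two bins time at `binWidth`, counts how many active electrodes have a
#' burst overlapping each bin, thresholds that participation count at
#' `participationMin`, and merges candidate network bursts separated by at
#' most `mergeGap`. Electrodes with mean firing rate below `activeRateMin`
#' are excluded from the participation count so that dead channels never
#' dilute it.
#'
#' @slot isiMax numeric, max in-burst inter-spike interval (s), default 0.1.
#' @slot minSpikes integer, minimum spikes per electrode burst, default 5.
#' @slot binWidth numeric, participation time-bin width (s), default 0.025.
#' @slot participationMin integer, minimum number of simultaneously bursting
#'   electrodes for a network burst, default 5.
#' @slot activeRateMin numeric, minimum mean rate (Hz) for an electrode to
#'   count as active, default 0.1.
#' @slot mergeGap numeric, maximum gap (s) between network bursts to merge,
#'   default 0.5.
#' @name DetectorParams-class
#' @exportClass DetectorParams
setClass("DetectorParams",
  slots = c(isiMax = "numeric", minSpikes = "integer", binWidth = "numeric",
            participationMin = "integer", activeRateMin = "numeric",
            mergeGap = "numeric"),
  prototype = list(isiMax = 0.1, minSpikes = 5L, binWidth = 0.025,
                   participationMin = 5L, activeRateMin = 0.1,
                   mergeGap = 0.5))

setValidity("DetectorParams", function(object) {
  msgs <- character(0)
  for (s in c("isiMax", "binWidth", "activeRateMin", "mergeGap"))
    if (length(slot(object, s)) != 1 || slot(object, s) <= 0)
      msgs <- c(msgs, paste(s, "must be a single positive number"))
  if (object@minSpikes < 2L) msgs <- c(msgs, "minSpikes must be >= 2")
  if (object@participationMin < 2L)
    msgs <- c(msgs, "participationMin must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' @rdname DetectorParams-class
#' @param isiMax,minSpikes,binWidth,participationMin,activeRateMin,mergeGap
#'   see slots.
#' @return `detectorParams()` returns a validated `DetectorParams` object.
#' @examples
#' detectorParams(participationMin = 10)
#' @export
detectorParams <- function(isiMax = 0.1, minSpikes = 5, binWidth = 0.025,
                           participationMin = 5, activeRateMin = 0.1,
                           mergeGap = 0.5) {
  new("DetectorParams", isiMax = isiMax, minSpikes = as.integer(minSpikes),
      binWidth = binWidth, participationMin = as.integer(participationMin),
      activeRateMin = activeRateMin, mergeGap = mergeGap)
}

setMethod("show", "DetectorParams", function(object) {
  cat("DetectorParams: isiMax=", object@isiMax, "s, minSpikes=",
      object@minSpikes, ", binWidth=", object@binWidth,
      "s, participationMin=", object@participationMin, ", activeRateMin=",
      object@activeRateMin, "Hz, mergeGap=", object@mergeGap, "s\n",
      sep = "")
})

#' Detect per-electrode bursts (max-interval rule)
#'
#' Every maximal run of at least `minSpikes` consecutive spikes whose
#' inter-spike intervals are all `<= isiMax` becomes one burst event whose
#' start/end are the first/last spike of the run.
#'
#' @param times sorted numeric spike times (seconds) of one electrode.
#' @param params a [DetectorParams-class].
#' @return data.frame with columns `tStart`, `tEnd`, `nSpikes`; zero rows if
#'   no burst.
#' @examples
#' detectElectrodeBursts(seq(10, 10.08, by = 0.02), detectorParams())
#' @export
detectElectrodeBursts <- function(times, params = detectorParams()) {
  stopifnot(is(params, "DetectorParams"))
  empty <- data.frame(tStart = numeric(0), tEnd = numeric(0),
                      nSpikes = integer(0))
  n <- length(times)
  if (n < params@minSpikes) return(empty)
  if (is.unsorted(times)) stop("spike times must be sorted")
  linked <- diff(times) <= params@isiMax
  r <- rle(linked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L >= params@minSpikes)
  if (!any(keep)) return(empty)
  i0 <- starts[keep]           # run of ISIs [i0, i1] -> spikes [i0, i1+1]
  i1 <- ends[keep] + 1L
  data.frame(tStart = times[i0], tEnd = times[i1],
             nSpikes = i1 - i0 + 1L)
}

#' ParticipationTrace: binned electrode-participation counts
#'
#' Uniform time bins of width `binWidth` tiling `[0, duration]`; `counts[b]`
#' is the number of (active) electrodes having a burst event that overlaps
#' bin `b`. Bursts are treated as closed intervals, so an event touching a
#' bin boundary counts in both adjacent bins.
#'
#' @slot counts integer vector, one per bin.
#' @slot binWidth numeric, bin width in seconds.
#' @slot duration numeric, recording duration in seconds.
#' @name ParticipationTrace-class
#' @exportClass ParticipationTrace
setClass("ParticipationTrace",
  slots = c(counts = "integer", binWidth = "numeric", duration = "numeric"))

setValidity("ParticipationTrace", function(object) {
  if (any(object@counts < 0)) "counts must be non-negative" else TRUE
})

#' @rdname ParticipationTrace-class
#' @param x a `ParticipationTrace`.
#' @return `binEdges()` returns the `nBins + 1` bin edges (s); `binCounts()`
#'   the per-bin electrode counts.
#' @export
binEdges <- function(x) {
  stopifnot(is(x, "ParticipationTrace"))
  c(seq_len(length(x@counts)) - 1L, length(x@counts)) * x@binWidth
}

#' @rdname ParticipationTrace-class
#' @export
binCounts <- function(x) {
  stopifnot(is(x, "ParticipationTrace"))
  x@counts
}

setMethod("show", "ParticipationTrace", function(object) {
  cat("ParticipationTrace: ", length(object@counts), " bins of ",
      object@binWidth, " s; peak participation ",
      if (length(object@counts)) max(object@counts) else 0L,
      " electrode(s)\n", sep = "")
})

activeElectrodes <- function(rec, params) {
  rate <- vapply(rec@spikes, length, integer(1)) / rec@duration
  names(rec@spikes)[rate >= params@activeRateMin]
}

# Bin index range overlapped by the closed interval [a, b] given bin width w
# (bins 1..B with edges (i-1)*w, i*w). Boundary-touching intervals fall in
# both adjacent bins.
overlappedBins <- function(a, b, w, B) {
  lo <- max(1L, as.integer(ceiling(a / w - 1e-9)))
  hi <- min(B, as.integer(floor(b / w + 1e-9)) + 1L)
  if (lo > hi) integer(0) else lo:hi
}

#' Compute the electrode-participation trace of a recording
#'
#' Runs per-electrode burst detection (unless burst tables are supplied) on
#' the electrodes passing the active-rate filter, then counts per time bin
#' how many electrodes have a burst overlapping that bin — the "number of
#' electrodes bursting across the MEA" at each time point.
#'
#' @param rec an [MEARecording-class].
#' @param bursts optional named list (by electrode) of burst data.frames as
#'   returned by [detectElectrodeBursts()]; computed from `rec` when `NULL`.
#' @param params a [DetectorParams-class].
#' @return A [ParticipationTrace-class].
#' @export
participationTrace <- function(rec, bursts = NULL,
                               params = detectorParams()) {
  stopifnot(is(rec, "MEARecording"), is(params, "DetectorParams"))
  act <- activeElectrodes(rec, params)
  if (is.null(bursts))
    bursts <- lapply(rec@spikes[act], detectElectrodeBursts, params = params)
  else
    bursts <- bursts[intersect(names(bursts), act)]
  B <- as.integer(ceiling(rec@duration / params@binWidth - 1e-9))
  counts <- integer(B)
  for (tab in bursts) {
    if (is.null(tab) || nrow(tab) == 0) next
    for (k in seq_len(nrow(tab))) {
      idx <- overlappedBins(tab$tStart[k], tab$tEnd[k], params@binWidth, B)
      counts[idx] <- counts[idx] + 1L
    }
  }
  new("ParticipationTrace", counts = counts, binWidth = params@binWidth,
      duration = rec@duration)
}

#' Detect network-wide synchronous bursts from a participation trace
#'
#' Maximal runs of bins whose participation count is at least
#' `participationMin` become candidate network bursts (their extent is the
#' spanned bin edges); candidates separated by at most `mergeGap` seconds
#' are merged (transitively). Each network burst carries its peak
#' participation count and the set of electrodes whose per-electrode bursts
#' overlap it.
#'
#' @param trace a [ParticipationTrace-class] from [participationTrace()].
#' @param rec the [MEARecording-class] the trace was computed from.
#' @param params a [DetectorParams-class].
#' @param bursts optional named list of per-electrode burst tables (from
#'   [detectElectrodeBursts()] on the active electrodes); recomputed from
#'   `rec` when `NULL`.
#' @return data.frame with columns `tStart`, `tEnd`, `peakParticipation`,
#'   `nElectrodes` and a list-column `electrodes` of participating electrode
#'   labels.
#' @export
detectNetworkBursts <- function(trace, rec, params = detectorParams(),
                                bursts = NULL) {
  stopifnot(is(trace, "ParticipationTrace"), is(rec, "MEARecording"),
            is(params, "DetectorParams"))
  empty <- data.frame(tStart = numeric(0), tEnd = numeric(0),
                      peakParticipation = integer(0),
                      nElectrodes = integer(0))
  empty$electrodes <- list()
  above <- trace@counts >= params@participationMin
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- starts[r$values]
  ce <- ends[r$values]
  w <- trace@binWidth
  t0 <- (cs - 1L) * w
  t1 <- pmin(ce * w, trace@duration)
  # transitive merge of candidates separated by <= mergeGap
  mt0 <- t0[1]; mt1 <- t1[1]
  for (k in seq_along(t0)[-1]) {
    if (t0[k] - mt1[length(mt1)] <= params@mergeGap + 1e-12) {
      mt1[length(mt1)] <- t1[k]
    } else {
      mt0 <- c(mt0, t0[k]); mt1 <- c(mt1, t1[k])
    }
  }
  if (is.null(bursts)) {
    act <- activeElectrodes(rec, params)
    bursts <- lapply(rec@spikes[act], detectElectrodeBursts,
                     params = params)
  }
  B <- length(trace@counts)
  peak <- integer(length(mt0))
  elecs <- vector("list", length(mt0))
  for (k in seq_along(mt0)) {
    idx <- overlappedBins(mt0[k], mt1[k], w, B)
    peak[k] <- max(trace@counts[idx])
    part <- vapply(bursts, function(tab)
      nrow(tab) > 0 && any(tab$tStart <= mt1[k] & tab$tEnd >= mt0[k]),
      logical(1))
    elecs[[k]] <- names(bursts)[part]
  }
  out <- data.frame(tStart = mt0, tEnd = mt1, peakParticipation = peak,
                    nElectrodes = lengths(elecs))
  out$electrodes <- elecs
  out
}

#' SBPMResult: synchronous-bursts-per-minute statistic
#'
#' @slot sbpm numeric, network bursts per minute
#'   (`nBursts / durationMin` exactly).
#' @slot nBursts integer, number of detected network bursts.
#' @slot durationMin numeric, recording duration in minutes.
#' @slot bursts data.frame of network bursts (see [detectNetworkBursts()]).
#' @name SBPMResult-class
#' @exportClass SBPMResult
setClass("SBPMResult",
  slots = c(sbpm = "numeric", nBursts = "integer", durationMin = "numeric",
            bursts = "data.frame"))

setValidity("SBPMResult", function(object) {
  if (object@durationMin <= 0) return("durationMin must be positive")
  if (!isTRUE(all.equal(object@sbpm,
                        object@nBursts / object@durationMin)))
    return("sbpm must equal nBursts / durationMin")
  TRUE
})

#' @rdname synchroburst-generics
#' @export
setMethod("sbpm", "SBPMResult", function(x) x@sbpm)

#' @rdname synchroburst-generics
#' @export
setMethod("networkBursts", "SBPMResult", function(x) x@bursts)

setMethod("show", "SBPMResult", function(object) {
  cat("SBPMResult: ", object@nBursts, " network burst(s) in ",
      object@durationMin, " min -> SBPM = ",
      format(object@sbpm, digits = 4), "\n", sep = "")
})

#' Compute the SBPM statistic
#'
#' @param bursts data.frame of network bursts ([detectNetworkBursts()]), or
#'   an integer burst count.
#' @param duration recording duration in seconds (> 0).
#' @return An [SBPMResult-class] with `sbpm = nBursts / (duration / 60)`.
#' @examples
#' sbpm(computeSBPM(3L, 600))  # 0.3
#' @export
computeSBPM <- function(bursts, duration) {
  if (length(duration) != 1 || is.na(duration) || duration <= 0)
    stop("duration must be a single positive number of seconds")
  if (is.numeric(bursts) && length(bursts) == 1) {
    n <- as.integer(bursts)
    bursts <- data.frame(tStart = numeric(0), tEnd = numeric(0),
                         peakParticipation = integer(0),
                         nElectrodes = integer(0))
  } else {
    stopifnot(is.data.frame(bursts))
    n <- nrow(bursts)
  }
  durMin <- duration / 60
  new("SBPMResult", sbpm = n / durMin, nBursts = as.integer(n),
      durationMin = durMin, bursts = bursts)
}

#' Run the full synchronous-burst detector
#'
#' Composition of [detectElectrodeBursts()] (on active electrodes),
#' [participationTrace()], [detectNetworkBursts()] and [computeSBPM()]. Pure
#' and deterministic: the same recording and parameters always give the
#' identical result.
#'
#' @param rec an [MEARecording-class].
#' @param params a [DetectorParams-class].
#' @return An [SBPMResult-class].
#' @examples
#' rec <- MEARecording(list(), duration = 600)
#' sbpm(runDetector(rec))  # 0
#' @export
runDetector <- function(rec, params = detectorParams()) {
  stopifnot(is(rec, "MEARecording"), is(params, "DetectorParams"))
  act <- activeElectrodes(rec, params)
  bursts <- lapply(rec@spikes[act], detectElectrodeBursts, params = params)
  trace <- participationTrace(rec, bursts = bursts, params = params)
  nb <- detectNetworkBursts(trace, rec, params, bursts = bursts)
  computeSBPM(nb, rec@duration)
}
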
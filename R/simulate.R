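#' Build distance-decaying random lattice connectivity
#'
#' Neurons sit on a `gridRows x gridCols` square lattice (row-major index;
#' neuron `i` has coordinates `x = (i-1) %% gridCols`,
#' `y = (i-1) %/% gridCols`, open boundaries). For every ordered pair
#' `(j, i)`, `j != i`, a directed synapse `j -> i` is present independently
#' with probability `pMax * exp(-d_ji / lambdaD)` where `d_ji` is the
#' Euclidean distance in lattice units. Draws are a deterministic function
#' of `config@seed`.
#'
#' @param config a [NetworkConfig-class].
#' @return data.frame with integer columns `from`, `to` (1-based neuron
#'   indices) and `weight` (1 for all edges), with attributes `nNeurons`
#'   and `expectedEdges` (the exact expected edge count
#'   `sum over pairs of pMax * exp(-d / lambdaD)`).
#' @examples
#' g <- buildLatticeConnectivity(networkConfig(gridRows = 5, gridCols = 5))
#' nrow(g) > 0
#' @export
buildLatticeConnectivity <- function(config) {
  stopifnot(is(config, "NetworkConfig"))
  validObject(config)
  n <- config@gridRows * config@gridCols
  x <- (seq_len(n) - 1L) %% config@gridCols
  y <- (seq_len(n) - 1L) %/% config@gridCols
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  p <- config@pMax * exp(-d / config@lambdaD)
  diag(p) <- 0
  edges <- withSeed(config@seed, {
    u <- matrix(runif(n * n), n, n)
    which(u < p, arr.ind = TRUE)  # [ , 1] = from (row), [ , 2] = to (col)
  })
  out <- data.frame(from = as.integer(edges[, 1]),
                    to = as.integer(edges[, 2]),
                    weight = rep(1, nrow(edges)))
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nNeurons") <- n
  attr(out, "expectedEdges") <- sum(p)
  out
}

#' Simplified Hodgkin-Huxley right-hand side
#'
#' Time derivatives of the membrane state `(V, n, h)` of one model neuron:
#' sodium activation is instantaneous (`m = mInf(V)`), `n` and `h` follow
#' the classic squid-axon alpha/beta rate functions, and synaptic/external
#' conductances enter as `-(gSyn + gExt) * (V - eSyn)`. This R
#' implementation defines the model; the network integrator in compiled
#' code is tested against it.
#'
#' @param V membrane potential (mV).
#' @param n,h gating variables in `[0, 1]`.
#' @param gSyn,gExt synaptic and external conductances (mS/cm^2).
#' @param config a [NetworkConfig-class] supplying membrane parameters.
#' @return Named numeric vector `c(dV, dn, dh)` (per ms).
#' @examples
#' hhDerivatives(-65, 0.32, 0.6, config = networkConfig())
#' @export
hhDerivatives <- function(V, n, h, gSyn = 0, gExt = 0,
                          config = networkConfig()) {
  r <- hhRates(V)
  iNa <- config@gNa * r[["mInf"]]^3 * h * (V - config@eNa)
  iK <- config@gK * n^4 * (V - config@eK)
  iL <- config@gL * (V - config@eL)
  iSyn <- (gSyn + gExt) * (V - config@eSyn)
  c(dV = (-iNa - iK - iL - iSyn + config@iInject) / config@Cm,
    dn = r[["an"]] * (1 - n) - r[["bn"]] * n,
    dh = r[["ah"]] * (1 - h) - r[["bh"]] * h)
}

# Classic squid-axon rate functions (1/ms) and instantaneous sodium
# activation; the 0/0 removable singularities of the alpha functions are
# evaluated by their limits.
hhRates <- function(V) {
  vexp <- function(x) ifelse(abs(x) < 1e-7, 1, x / (1 - exp(-x)))
  am <- vexp((V + 40) / 10)          # alpha_m = 0.1 (V+40) / (1 - e^-(V+40)/10)
  bm <- 4 * exp(-(V + 65) / 18)
  c(an = 0.1 * vexp((V + 55) / 10),  # alpha_n = 0.01 (V+55) / (1 - e^-(V+55)/10)
    bn = 0.125 * exp(-(V + 65) / 80),
    ah = 0.07 * exp(-(V + 65) / 20),
    bh = 1 / (1 + exp(-(V + 35) / 10)),
    mInf = am / (am + bm))
}

#' Presynaptic release from the docked-vesicle pool
#'
#' A presynaptic spike releases fraction `U` of the docked pool: the
#' released amount is `U * D`, the pool drops to `D * (1 - U)`, and the
#' energy store pays `cA * U * D` (floored at 0). Postsynaptic targets each
#' receive a conductance increment `gMax * released * weight`.
#'
#' @param D docked-vesicle fraction in `[0, 1]`.
#' @param A presynaptic energy variable in `[0, 1]`.
#' @param config a [NetworkConfig-class].
#' @return list with `released`, updated `D` and updated `A`.
#' @examples
#' onPresynapticSpike(1, 1, networkConfig())  # released 0.4, D 0.6
#' @export
onPresynapticSpike <- function(D, A, config = networkConfig()) {
  released <- config@U * D
  list(released = released,
       D = D * (1 - config@U),
       A = max(0, A - config@cA * released))
}

#' Energy-gated vesicle recovery rate
#'
#' Vesicle recovery is gated by the presynaptic energy store through
#' Michaelis-Menten saturation: `kRec = kRec0 * A / (A + KA)`. Between
#' spikes the pool and the energy store relax as
#' `dD/dt = kRec * (1 - D)` and `dA/dt = kGenMax * glucose * (1 - A)`.
#'
#' @param A presynaptic energy variable in `[0, 1]`.
#' @param config a [NetworkConfig-class].
#' @return Recovery rate in 1/s.
#' @examples
#' effectiveRecoveryRate(0.2, networkConfig(KA = 0.2))  # kRec0 / 2
#' @export
effectiveRecoveryRate <- function(A, config = networkConfig()) {
  config@kRec0 * A / (A + config@KA)
}

#' SimulationResult: spike raster and state traces of a network simulation
#'
#' @slot raster data.frame with columns `neuron` (1-based index) and `time`
#'   (seconds), time-sorted.
#' @slot config the [NetworkConfig-class] used (snapshot).
#' @slot traces list; when `config@traceNeurons` is non-empty, holds `time`
#'   (s) and matrices `V`, `D`, `A` (rows = sample times, columns = traced
#'   neurons).
#' @slot diagnostics list with the extrema of the bounded state variables
#'   over the whole run (`Dmin`, `Dmax`, `Amin`, `Amax`) and `nSpikes`.
#' @name SimulationResult-class
#' @exportClass SimulationResult
setClass("SimulationResult",
  slots = c(raster = "data.frame", config = "NetworkConfig",
            traces = "list", diagnostics = "list"))

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult: ", nrow(object@raster), " spike(s) from ",
      object@config@gridRows * object@config@gridCols, " neurons over ",
      object@config@duration, " s (seed ", object@config@seed, ")\n",
      sep = "")
})

#' @rdname synchroburst-generics
#' @export
setMethod("nSpikes", "SimulationResult", function(x) nrow(x@raster))

#' @rdname synchroburst-generics
#' @export
setMethod("recordingDuration", "SimulationResult",
          function(x) x@config@duration)

#' @describeIn SimulationResult-class the spike raster data.frame.
#' @param x a `SimulationResult`.
#' @export
raster <- function(x) {
  stopifnot(is(x, "SimulationResult"))
  x@raster
}

#' Simulate the metabolically coupled excitatory network
#'
#' Fixed-step integration of the full network: Rush-Larsen exact
#' relaxation for the gating variables and an exponential-Euler voltage
#' update (unconditionally stable — with instantaneous sodium activation
#' the voltage equation is stiff during the spike upstroke), with exact
#' exponential decay of the synaptic and external conductances between
#' events; event-driven conductance increments at spike arrivals after a
#' fixed transmission delay; independent external Poisson conductance
#' events per neuron; docked-pool and energy-store relaxation between
#' spikes and discrete release/cost updates at spikes. A spike is
#' registered on an upward crossing of
#' `spikeThreshold` outside the dead time. The same `(config, seed)` always
#' yields the identical raster. Numerical divergence (|V| > 500 mV) is an
#' error naming the neuron and time.
#'
#' @param config a [NetworkConfig-class].
#' @param connectivity optional edge data.frame from
#'   [buildLatticeConnectivity()]; built from `config` when `NULL`.
#' @return A [SimulationResult-class].
#' @examples
#' cfg <- networkConfig(gridRows = 4, gridCols = 4, duration = 1)
#' simulateNetwork(cfg)
#' @export
simulateNetwork <- function(config, connectivity = NULL) {
  stopifnot(is(config, "NetworkConfig"))
  validObject(config)
  if (is.null(connectivity)) connectivity <- buildLatticeConnectivity(config)
  n <- config@gridRows * config@gridCols
  stopifnot(attr(connectivity, "nNeurons") %in% c(NULL, n) ||
              is.null(attr(connectivity, "nNeurons")))
  cfg <- list(
    nNeurons = n, duration = config@duration, dt = config@dt,
    Cm = config@Cm, gNa = config@gNa, eNa = config@eNa, gK = config@gK,
    eK = config@eK, gL = config@gL, eL = config@eL, vInit = config@vInit,
    gMax = config@gMax, tauSyn = config@tauSyn, eSyn = config@eSyn,
    U = config@U, kRec0 = config@kRec0, glucose = config@glucose,
    kGenMax = config@kGenMax, KA = config@KA, cA = config@cA,
    nuExt = config@nuExt, gExt = config@gExt, iInject = config@iInject,
    extPeriodic = config@extPeriodic,
    spikeThreshold = config@spikeThreshold, refractory = config@refractory,
    synDelay = config@synDelay, traceDt = config@traceDt,
    seed = config@seed)
  res <- sim_network_cpp(cfg,
                         as.integer(connectivity$from),
                         as.integer(connectivity$to),
                         as.numeric(connectivity$weight),
                         as.integer(config@traceNeurons))
  ord <- order(res$spikeTime, res$spikeNeuron)
  rasterDf <- data.frame(neuron = res$spikeNeuron[ord],
                         time = res$spikeTime[ord])
  traces <- list()
  if (length(config@traceNeurons)) {
    traces <- list(time = res$traceTime, V = res$traceV, D = res$traceD,
                   A = res$traceA)
    for (nm in c("V", "D", "A"))
      colnames(traces[[nm]]) <- as.character(config@traceNeurons)
  }
  new("SimulationResult", raster = rasterDf, config = config,
      traces = traces,
      diagnostics = list(Dmin = res$Dmin, Dmax = res$Dmax,
                         Amin = res$Amin, Amax = res$Amax,
                         nSpikes = nrow(rasterDf)))
}

#' Map a simulated raster onto a 60-electrode MEA recording
#'
#' Overlays the neuron lattice with the 8x8 electrode grid (each electrode
#' tile spans `gridCols/8 x gridRows/8` lattice units) and pools member
#' neurons' spikes into one channel per electrode. The four corner
#' positions carry no electrode; neurons falling in a corner tile are
#' pooled into the nearest non-corner edge tile, so the 60 channels
#' partition all neurons and the total spike count is conserved.
#'
#' @param sim a [SimulationResult-class].
#' @param pools optional named list (electrode label -> integer neuron
#'   indices) overriding the default partition; must be disjoint.
#' @param recordingId,condition,replicateId metadata for the recording.
#' @return An [MEARecording-class] with 60 channels (or one per pool).
#' @examples
#' cfg <- networkConfig(gridRows = 4, gridCols = 4, duration = 1)
#' rec <- resultToRecording(simulateNetwork(cfg))
#' nSpikes(rec) == nSpikes(simulateNetwork(cfg))
#' @export
resultToRecording <- function(sim, pools = NULL, recordingId = "sim",
                              condition = NA, replicateId = NA) {
  stopifnot(is(sim, "SimulationResult"))
  cfg <- sim@config
  n <- cfg@gridRows * cfg@gridCols
  if (is.null(pools)) {
    pools <- defaultElectrodePools(cfg@gridRows, cfg@gridCols)
  } else {
    all <- unlist(pools)
    if (anyDuplicated(all)) stop("electrode pools overlap")
  }
  assign <- rep(NA_character_, n)
  for (e in names(pools)) assign[pools[[e]]] <- e
  spikes <- setNames(vector("list", length(pools)), names(pools))
  byNeuron <- split(sim@raster$time, factor(sim@raster$neuron,
                                            levels = seq_len(n)))
  for (e in names(pools))
    spikes[[e]] <- sort(unlist(byNeuron[pools[[e]]], use.names = FALSE))
  MEARecording(spikes, duration = cfg@duration, recordingId = recordingId,
               condition = condition, replicateId = replicateId,
               sampleRate = 25000)
}

# Partition the lattice into the 60 electrode tiles: 8x8 overlay of
# (cols/8 x rows/8)-unit tiles; neurons in the four cornertiles are
# reassigned to the nearest non-corner tile (ties broken toward the grid
# interior deterministically).
defaultElectrodePools <- function(rows, cols) {
  n <- rows * cols
  x <- (seq_len(n) - 1L) %% cols
  y <- (seq_len(n) - 1L) %/% cols
  tc <- pmin(8L, as.integer(floor(x / (cols / 8))) + 1L)
  tr <- pmin(8L, as.integer(floor(y / (rows / 8))) + 1L)
  lab <- paste0(tr, tc)
  corners <- c("11", "18", "81", "88")
  fix <- lab %in% corners
  if (any(fix)) {
    # move corner-tile neurons one tile toward the interior along the
    # column axis (e.g. tile 11 -> 12, 18 -> 17, 81 -> 82, 88 -> 87)
    tc2 <- tc
    tc2[fix & tc == 1L] <- 2L
    tc2[fix & tc == 8L] <- 7L
    lab[fix] <- paste0(tr[fix], tc2[fix])
  }
  split(seq_len(n), lab)
}

#' Reference single-neuron integration in pure R
#'
#' Independent fixed-step RK2 (midpoint) integration of one isolated model
#' neuron, implementing the same equations as [hhDerivatives()] directly in
#' R. The neuron can be driven by a constant injected current
#' (`config@iInject`) and, when `config@extPeriodic` is `TRUE`, by the
#' deterministic periodic conductance train (`nuExt` Hz, increments of
#' `gExt`, exponential decay with `tauSyn`). Used as the numerical oracle
#' for the compiled network integrator, typically run at a much finer step.
#'
#' @param config a [NetworkConfig-class].
#' @param dt integration step in ms (defaults to `config@dt`).
#' @return list with `spikes` (spike times in seconds) and the final state.
#' @export
integrateHHReference <- function(config, dt = config@dt) {
  stopifnot(is(config, "NetworkConfig"))
  nSteps <- round(config@duration * 1000 / dt)
  V <- config@vInit
  r0 <- hhRates(V)
  n <- r0[["an"]] / (r0[["an"]] + r0[["bn"]])
  h <- r0[["ah"]] / (r0[["ah"]] + r0[["bh"]])
  refractSteps <- max(1L, round(config@refractory / dt))
  refract <- 0L
  spikes <- numeric(0)
  thr <- config@spikeThreshold
  gNa <- config@gNa; eNa <- config@eNa; gK <- config@gK; eK <- config@eK
  gL <- config@gL; eL <- config@eL; eSyn <- config@eSyn
  iInj <- config@iInject; invCm <- 1 / config@Cm
  decay <- exp(-dt / config@tauSyn)
  periodic <- isTRUE(config@extPeriodic) && config@nuExt > 0
  periodMs <- if (periodic) 1000 / config@nuExt else Inf
  nextExt <- periodMs
  ge <- 0
  rhs <- function(V, n, h, g) {
    am <- if (abs(V + 40) < 1e-6) 1 else
      ((V + 40) / 10) / (1 - exp(-(V + 40) / 10))
    bm <- 4 * exp(-(V + 65) / 18)
    mInf <- am / (am + bm)
    an <- if (abs(V + 55) < 1e-6) 0.1 else
      0.1 * ((V + 55) / 10) / (1 - exp(-(V + 55) / 10))
    bn <- 0.125 * exp(-(V + 65) / 80)
    ah <- 0.07 * exp(-(V + 65) / 20)
    bh <- 1 / (1 + exp(-(V + 35) / 10))
    c((-gNa * mInf^3 * h * (V - eNa) - gK * n^4 * (V - eK) -
         gL * (V - eL) - g * (V - eSyn) + iInj) * invCm,
      an * (1 - n) - bn * n,
      ah * (1 - h) - bh * h)
  }
  for (s in seq_len(nSteps)) {
    tMs <- (s - 1) * dt
    while (nextExt <= tMs) {
      ge <- ge + config@gExt
      nextExt <- nextExt + periodMs
    }
    d1 <- rhs(V, n, h, ge)
    d2 <- rhs(V + 0.5 * dt * d1[1], n + 0.5 * dt * d1[2],
              h + 0.5 * dt * d1[3], ge)
    Vn <- V + dt * d2[1]
    n <- min(1, max(0, n + dt * d2[2]))
    h <- min(1, max(0, h + dt * d2[3]))
    ge <- ge * decay
    if (refract == 0L) {
      if (Vn >= thr && V < thr) {
        spikes <- c(spikes, s * dt / 1000)
        refract <- refractSteps
      }
    } else refract <- refract - 1L
    V <- Vn
  }
  list(spikes = spikes, V = V, n = n, h = h)
}
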
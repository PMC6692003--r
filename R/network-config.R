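#' NetworkConfig: parameters of the excitatory spiking-network model
#'
#' Full parameterization of the metabolically coupled excitatory network
#' model: 400 simplified Hodgkin-Huxley neurons (instantaneous sodium
#' activation, dynamic `n` and `h` gates, classic squid-axon rate functions
#' and conductances) on a 20x20 square lattice, connected randomly with a
#' probability that decays exponentially with Euclidean lattice distance.
#' Each synapse holds a single docked-vesicle pool: a presynaptic spike
#' releases fraction `U` of the docked pool `D`, and `D` recovers at rate
#' `kRec0 * A / (A + KA)`, gated by a presynaptic energy store `A` that is
#' spent on each release (`cA` per unit released) and regenerated at
#' `kGenMax * glucose`. `glucose` is a dimensionless availability in
#' `[0, 1]` (1 ~ glucose-rich medium, 0.1 ~ depleted). Spontaneous activity
#' comes from independent external Poisson conductance events per neuron.
#'
#' Units follow the standard Hodgkin-Huxley convention: mV, ms, mS/cm^2,
#' uF/cm^2, uA/cm^2; rates `kRec0`, `kGenMax` and `nuExt` are per second;
#' `duration` is in seconds.
#'
#' @slot gridRows,gridCols integer lattice size (default 20 x 20).
#' @slot duration numeric, simulated time in seconds.
#' @slot dt numeric, integration step in ms (default 0.05).
#' @slot seed integer RNG seed (connectivity and noise).
#' @slot pMax,lambdaD numeric, peak connection probability (default 0.6)
#'   and distance decay length in lattice units (default 2).
#' @slot Cm,gNa,eNa,gK,eK,gL,eL,vInit numeric membrane parameters
#'   (defaults 1, 120, 50, 36, -77, 0.3, -54.4, -65).
#' @slot gMax numeric, peak synaptic conductance increment per unit released
#'   (mS/cm^2).
#' @slot tauSyn numeric, synaptic decay constant in ms (default 3).
#' @slot eSyn numeric, synaptic reversal potential (0 mV, AMPA-like).
#' @slot U numeric in (0,1], release fraction per spike (default 0.4).
#' @slot kRec0 numeric, baseline vesicle recovery rate in 1/s (default 1).
#' @slot glucose numeric in [0,1], energetic substrate availability.
#' @slot kGenMax numeric, maximal energy regeneration rate in 1/s.
#' @slot KA numeric, half-saturation of recovery versus energy.
#' @slot cA numeric, energy cost per unit vesicle release.
#' @slot nuExt numeric, external event rate per neuron (Hz).
#' @slot gExt numeric, external conductance increment (mS/cm^2).
#' @slot extPeriodic logical; when `TRUE` the external drive is a
#'   deterministic periodic train at `nuExt` Hz instead of a Poisson
#'   process (used for integrator validation; default `FALSE`).
#' @slot iInject numeric, constant injected current (uA/cm^2, default 0;
#'   used for single-neuron experiments).
#' @slot spikeThreshold numeric, spike registration threshold (mV,
#'   default -20).
#' @slot refractory numeric, spike registration dead time (ms, default 2).
#' @slot synDelay numeric, synaptic transmission delay (ms, default 1.5).
#' @slot traceNeurons integer, neuron indices whose V, D, A are sampled.
#' @slot traceDt numeric, trace sampling interval in ms.
#' @name NetworkConfig-class
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  slots = c(gridRows = "integer", gridCols = "integer",
            duration = "numeric", dt = "numeric", seed = "integer",
            pMax = "numeric", lambdaD = "numeric",
            Cm = "numeric", gNa = "numeric", eNa = "numeric",
            gK = "numeric", eK = "numeric", gL = "numeric", eL = "numeric",
            vInit = "numeric",
            gMax = "numeric", tauSyn = "numeric", eSyn = "numeric",
            U = "numeric", kRec0 = "numeric",
            glucose = "numeric", kGenMax = "numeric", KA = "numeric",
            cA = "numeric",
            nuExt = "numeric", gExt = "numeric", iInject = "numeric",
            extPeriodic = "logical",
            spikeThreshold = "numeric", refractory = "numeric",
            synDelay = "numeric",
            traceNeurons = "integer", traceDt = "numeric"))

setValidity("NetworkConfig", function(object) {
  msgs <- character(0)
  if (object@gridRows < 1L || object@gridCols < 1L)
    msgs <- c(msgs, "grid must have at least one row and column")
  if (object@dt <= 0) msgs <- c(msgs, "dt must be positive")
  if (object@duration <= 0) msgs <- c(msgs, "duration must be positive")
  if (object@pMax < 0 || object@pMax > 1)
    msgs <- c(msgs, "pMax must be in [0, 1]")
  if (object@U <= 0 || object@U > 1)
    msgs <- c(msgs, "U must be in (0, 1]")
  if (object@glucose < 0 || object@glucose > 1)
    msgs <- c(msgs, "glucose must be in [0, 1]")
  for (s in c("lambdaD", "Cm", "tauSyn"))
    if (slot(object, s) <= 0) msgs <- c(msgs, paste(s, "must be positive"))
  for (s in c("gNa", "gK", "gL", "gMax", "kRec0", "kGenMax", "KA", "cA",
              "nuExt", "gExt", "refractory"))
    if (slot(object, s) < 0) msgs <- c(msgs, paste(s, "must be >= 0"))
  if (any(object@traceNeurons < 1L |
            object@traceNeurons > object@gridRows * object@gridCols))
    msgs <- c(msgs, "traceNeurons out of range")
  if (length(msgs)) msgs else TRUE
})

#' @rdname NetworkConfig-class
#' @param gridRows,gridCols,duration,dt,seed,pMax,lambdaD see slots.
#' @param Cm,gNa,eNa,gK,eK,gL,eL,vInit,gMax,tauSyn,eSyn,U,kRec0 see slots.
#' @param glucose,kGenMax,KA,cA,nuExt,gExt,iInject,extPeriodic see slots.
#' @param spikeThreshold,refractory,synDelay,traceNeurons,traceDt see slots.
#' @return `networkConfig()` returns a validated `NetworkConfig`.
#' @examples
#' networkConfig(duration = 10, glucose = 0.1)
#' @export
networkConfig <- function(gridRows = 20, gridCols = 20, duration = 60,
                          dt = 0.05, seed = 1,
                          pMax = 0.6, lambdaD = 2,
                          Cm = 1, gNa = 120, eNa = 50, gK = 36, eK = -77,
                          gL = 0.3, eL = -54.4, vInit = -65,
                          gMax = 0.15, tauSyn = 3, eSyn = 0, U = 0.4,
                          kRec0 = 1,
                          glucose = 1, kGenMax = 0.5, KA = 0.2, cA = 1,
                          nuExt = 0.2, gExt = 0.15, iInject = 0,
                          extPeriodic = FALSE,
                          spikeThreshold = -20, refractory = 2,
                          synDelay = 1.5,
                          traceNeurons = integer(0), traceDt = 1) {
  new("NetworkConfig",
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      duration = duration, dt = dt, seed = as.integer(seed),
      pMax = pMax, lambdaD = lambdaD,
      Cm = Cm, gNa = gNa, eNa = eNa, gK = gK, eK = eK, gL = gL, eL = eL,
      vInit = vInit,
      gMax = gMax, tauSyn = tauSyn, eSyn = eSyn, U = U, kRec0 = kRec0,
      glucose = glucose, kGenMax = kGenMax, KA = KA, cA = cA,
      nuExt = nuExt, gExt = gExt, iInject = iInject,
      extPeriodic = isTRUE(extPeriodic),
      spikeThreshold = spikeThreshold, refractory = refractory,
      synDelay = synDelay,
      traceNeurons = as.integer(traceNeurons), traceDt = traceDt)
}

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig: ", object@gridRows, "x", object@gridCols,
      " lattice, ", object@duration, " s at dt=", object@dt, " ms\n",
      "  connectivity: pMax=", object@pMax, ", lambdaD=", object@lambdaD,
      "\n  synapse: gMax=", object@gMax, ", U=", object@U, ", kRec0=",
      object@kRec0, " /s\n  metabolism: glucose=", object@glucose,
      ", kGenMax=", object@kGenMax, " /s, KA=", object@KA, ", cA=",
      object@cA, "\n  noise: nuExt=", object@nuExt, " Hz, gExt=",
      object@gExt, " | seed=", object@seed, "\n", sep = "")
})
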
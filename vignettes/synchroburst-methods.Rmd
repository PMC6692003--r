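---
title: "Methods: synchronous-burst detection and the metabolically coupled network model"
author: "synchroburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchronous-burst detection and the metabolically coupled network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synchroburst)
```

## Scientific setting

Cultured networks of excitatory (glutamatergic) human induced neurons grown
with astrocytes on 60-electrode multi-electrode arrays (MEAs) develop, after
three to four weeks, *network-wide synchronous bursts*: roughly second-long
trains of high-frequency spikes whose onsets coincide across most
electrodes, separated by long stretches in which only sparse, asynchronous
spontaneous spikes occur. The burst rate — synchronous bursts per minute
(SBPM) — is the headline statistic of such preparations. Synchronous
bursting is an emergent property of recurrent excitatory transmission: AMPA
receptor blockade (CNQX) abolishes the bursts while spontaneous spikes
persist, sodium-channel blockade (TTX) silences everything, and
interventions that slow the synaptic-vesicle cycle (v-ATPase inhibition, or
withdrawal of extracellular glucose) strongly reduce SBPM.

This package implements the computational side of that experimental
program: (i) a synchronous-burst detector producing SBPM from per-electrode
spike times, (ii) a spiking-network model in which vesicle recovery is
gated by presynaptic energy availability, (iii) a synthetic MEA recording
generator with planted ground truth used to validate the detector, and
(iv) condition-level statistics (mean ± SEM, Student's t-tests). Raw
voltage processing and spike sorting are out of scope — all inputs are
spike times.

## The burst detector

The detector is deliberately simple and fully parameterized
(`detectorParams()`), operating in two stages.

**Stage 1 — per-electrode bursts (max-interval rule).** A maximal run of at
least `minSpikes` (default 5) consecutive spikes whose inter-spike
intervals are all ≤ `isiMax` (default 0.1 s) is one electrode burst,
spanning its first to last spike. With background activity of ~1 Hz per
electrode the chance of five consecutive ISIs below 0.1 s is ~1e-4 per
spike, so spontaneous activity essentially never forms electrode bursts,
while in-burst firing at tens of Hz always does.

**Stage 2 — network bursts (participation threshold).** Time is binned at
`binWidth` (default 25 ms); each bin counts the electrodes whose burst
intervals overlap it ("number of electrodes bursting at this time point" —
the quantity plotted for every recording in the source experiments).
Maximal runs of bins with count ≥ `participationMin` (default 5 electrodes)
are candidate network bursts; candidates separated by ≤ `mergeGap`
(default 0.5 s) merge transitively. Electrodes with mean firing rate below
`activeRateMin` (default 0.1 Hz) are excluded from participation counts so
dead channels cannot dilute the statistic; `participationMin` is an
absolute electrode count rather than a fraction because the set of active
channels changes over development. Intervals are closed: an event touching
a bin boundary counts in both adjacent bins. `SBPM = nBursts /
(duration/60)` exactly.

The detector is a reimplementation choice, not a port of any particular
laboratory's code: its parameters are all exposed, and its validity is
established by round-trip recovery of planted bursts (precision and recall
≥ 0.9 at the default operating point, see the test suite) rather than by
matching a reference implementation.

## The network model

### Membrane

400 neurons on a 20×20 lattice. Each follows the simplified Hodgkin-Huxley
membrane model with *instantaneous* sodium activation:

$$C_m \dot V = -\bar g_{Na} m_\infty(V)^3 h (V-E_{Na})
             - \bar g_K n^4 (V-E_K) - g_L (V-E_L)
             - g_{syn}(t)(V-E_{syn}) + I_{inj},$$

with the classic squid-axon rate functions for $n$ and $h$ and parameters
$C_m = 1\,\mu F/cm^2$, $\bar g_{Na} = 120$, $\bar g_K = 36$, $g_L = 0.3$
mS/cm², $E_{Na} = 50$, $E_K = -77$, $E_L = -54.4$ mV. A spike is registered
on an upward crossing of −20 mV outside a 2 ms dead time. `hhDerivatives()`
is the definitional implementation of this right-hand side in R.

### Connectivity

Directed synapses are drawn independently for each ordered pair with
probability $p_{max} e^{-d/\lambda_d}$ in Euclidean lattice distance
(defaults $p_{max} = 0.6$, $\lambda_d = 2$; open boundaries, no torus),
giving sparse, predominantly local excitation with a mean in/out-degree of
about 15. Transmission delay is fixed at 1.5 ms; synaptic conductances are
AMPA-like ($E_{syn} = 0$ mV) with exponential decay, $\tau_{syn} = 3$ ms.

### Vesicle pool and metabolic coupling

Each neuron's presynaptic terminals share a single docked-vesicle pool
$D \in [0,1]$. A spike releases a fraction $U$ (default 0.4): targets
receive a conductance increment $g_{max} \cdot U D$, and $D \leftarrow
D(1-U)$. Between spikes the pool recovers toward 1:

$$\dot D = k_{rec}(A)\,(1-D), \qquad
  k_{rec}(A) = k_{rec,0} \frac{A}{A + K_A},$$

gated by a dimensionless presynaptic energy store $A \in [0,1]$ that pays
for vesicle recycling and maintenance (endocytosis, re-acidification by the
v-ATPase, glutamate loading — all folded into one rate, matching the
single-rate-constant simplification of the underlying model). Each release
costs $c_A \cdot UD$ of energy, and $A$ regenerates at a glucose-gated
rate:

$$\dot A = k_{gen} G (1 - A),$$

where $G \in [0,1]$ is a dimensionless glucose availability (1 ≈
glucose-rich medium, 0.1 ≈ depleted). No claim is made about the exact
biochemical form of this coupling — the experimental literature does not
constrain it — only about its qualitative shape: recovery slows when recent
energy consumption outpaces glucose-dependent regeneration. The gating is a
pluggable default, not a mechanistic commitment.

### Spontaneous drive

Independent external conductance events per neuron (Poisson at `nuExt`,
increments `gExt`) stand in for the spontaneous spiking observed under
synaptic blockade. The events are suprathreshold, so the spontaneous rate
equals the event rate; defaults are sized to give ~0.2 Hz per neuron,
i.e. ~1.3 Hz per pooled electrode — comfortably below the detector's
false-positive regime. A deterministic periodic mode (`extPeriodic`)
replaces the Poisson clock with a fixed-interval train; it exists for
integrator validation, where both integrators must see identical inputs.

### Numerics

With instantaneous $m$, the voltage equation is *stiff*: during the spike
upstroke the effective membrane time constant drops to
$C_m/(\bar g_{Na} m_\infty^3 h) \approx 0.02$ ms, and an explicit
Runge-Kutta step at dt = 0.05 ms diverges. The integrator therefore uses
the scheme standard in conductance-based network simulators: Rush-Larsen
exact relaxation for the gates ($n' = n_\infty + (n - n_\infty)
e^{-\Delta t(\alpha+\beta)}$) followed by an exponential-Euler voltage
update (exact for conductances frozen over the step), which is
unconditionally stable. Synaptic and external conductances decay
analytically by $e^{-\Delta t/\tau_{syn}}$. Gate steady states and decay
factors are tabulated on a 0.02 mV grid with linear interpolation. The
step is dt = 0.05 ms.

Correctness is checked against an independent pure-R midpoint (RK2)
integrator run at dt = 0.005 ms (`integrateHHReference()`): over 10 s of
periodically driven firing (199 spikes) the two agree to ~0.13 ms per
spike with identical counts. Determinism is bit-level: the simulator uses
a self-contained splitmix64 RNG stream, so `(config, seed)` reproduces
rasters exactly on any platform. Divergence (|V| > 500 mV) raises an error
naming the neuron and time rather than returning garbage.

The simulated raster maps onto the 60-electrode recording geometry by
overlaying the 8×8 electrode grid on the lattice (2.5×2.5-neuron tiles)
and pooling member neurons per electrode; the four corner positions carry
no electrode, and neurons in those tiles are pooled into the adjacent edge
tile so that the mapping is a true partition and spike counts are
conserved.

### Default operating point

Defaults were chosen once, to place the model in the regime the
experiments describe, and are not re-fit anywhere in the test suite:

| parameter | default | meaning |
|---|---|---|
| `gMax` | 0.15 | peak synaptic conductance per unit released; single EPSPs at a full pool are just subthreshold, so bursts ignite from coincident spontaneous spikes and propagate through recurrent summation |
| `U` | 0.4 | release fraction; ~5 in-burst spikes deplete the pool to <10% and terminate the burst |
| `kRec0`, `KA` | see `networkConfig()` | recovery scale and its energy half-saturation; sized so that recovery is near-maximal at rest under high glucose and collapses when the store drains |
| `cA` | see `networkConfig()` | energy cost per unit released; sized so a network burst drains an appreciable fraction of the store, making inter-burst intervals energy-limited |
| `kGenMax` | 0.5 /s | regeneration at full glucose; refills the store within a few seconds at G = 1 but takes tens of seconds at G = 0.1 |
| `nuExt`, `gExt` | 0.2 Hz, 0.15 | spontaneous drive: ~0.2 Hz/neuron background firing |

Pharmacological analogs are parameter substitutions, not separate code
paths: CNQX → `gMax = 0`; TTX → `gNa = 0`; v-ATPase inhibition (CMA) →
scaling `kRec0` down; glucose depletion → lowering `glucose`. Two analog
behaviors are structural: with `gMax = 0` spontaneous spikes persist but
no network burst can assemble, and with `gNa = 0` no regenerative spike is
possible — the passive depolarization attainable from stacked external
events stays below the −20 mV registration threshold.

## The synthetic recording generator

`generateRecording()` emulates a mature culture with known ground truth:

* Burst onsets follow a dead-time renewal process: after each burst a
  refractory gap (default 1 s) is enforced, and the exponential waiting
  time beyond the gap is rate-adjusted (`1/μ = 60/λ − E[duration] − gap`)
  so the long-run planted rate equals `burstRate` exactly. A plain thinned
  Poisson process would undershoot the nominal rate by ~10% at 4
  bursts/min, which would defeat rate-recovery validation.
* Burst durations are log-normal (median 0.8 s, σ = 0.4), matching the
  ~1 s scale of observed bursts.
* Each burst recruits `ceiling(0.8 × 60)` random electrodes; each fires an
  independent homogeneous Poisson train at 80 Hz over the burst interval,
  onset-jittered per electrode by up to 10 ms (all participants share the
  burst end). Within-burst rate envelopes are deliberately not modelled —
  homogeneous trains are sufficient for detector validation, which is this
  module's purpose.
* Background spiking is independent Poisson at 0.5 Hz per electrode
  everywhere (an optional per-electrode rate multiplier exists; real
  heterogeneity is unreported, so the default is uniform).

What passing round-trip tests do show: the detector recovers bursts of the
planted morphology near-perfectly and does not hallucinate bursts from
Poisson background at ≤1 Hz/electrode. What they cannot show: performance
on real recordings with rate envelopes, compound bursts, electrode
cross-talk or non-Poisson background — the generator does not emulate
those.

## Statistics

`summarizeCondition()` reports mean ± SEM (sample SD, n−1 denominator;
flagged undefined for n = 1). `compareConditions()` performs two-sided
Student's t-tests — pooled-variance unpaired or difference-score paired;
a paired comparison with all-zero differences reports t = 0, p = 1 with a
degeneracy flag rather than erroring. P-values are raw: no
multiple-testing correction is applied, mirroring per-pair reporting, and
output objects say so. The normality assumption is surfaced in
documentation, not adjudicated; non-parametric alternatives and two-way
ANOVA are deliberately out of scope. Whether the original comparisons were
paired across cultures is not stated in the source experiments, so both
modes are provided.

## Problem sizes used in the automated checks

The test suite and the acceptance script run the full 400-neuron model but
size simulation lengths and seed counts to what the scientific claim
needs: 5 seeds × 5 min for the synaptic-blockade null, 5 seeds × 60 s per
glucose level for the ordering claim, 10 seeds × 20 s per recovery-rate
scaling, 20 seeds × 10 min synthetic recordings for detector round-trip
statistics, and 100 randomized short runs for state-bound fuzzing. These
choices are stated here as the package's own experimental design.

## Known limitations

* The model is a phenomenological instantiation: the exact equations,
  parameters and noise sources of the original simulation study are not
  public, so validation is against the qualitative phenomena (burst
  emergence, CNQX/TTX nulls, glucose and recovery-rate suppression), not
  numeric traces.
* A single vesicle pool and a single lumped energy store; no astrocyte
  compartment, no ATP-sensitive potassium channels, no facilitation, no
  inhibitory population (GABA blockade had no effect in the source
  system).
* Glucose is a dimensionless availability, not a concentration with
  transporter kinetics.
* SBPM is the only burst statistic analyzed; burst durations are emitted
  but compound-burst organization is not detected.
* The detector's defaults are tuned for ~1 s bursts at tens of Hz against
  ≤1 Hz background; very different preparations will need different
  `DetectorParams`.
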
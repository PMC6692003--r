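# synchroburst

Synchronous-burst analysis and metabolically coupled network simulation
for multi-electrode array (MEA) recordings of cultured excitatory
neuronal networks.

## The problem

Mature cultures of excitatory (glutamatergic) neurons on 60-electrode
MEAs exhibit *network-wide synchronous bursts*: ~1 s trains of
high-frequency spikes whose onsets coincide across most electrodes,
riding on sparse spontaneous background spiking. The burst rate —
**synchronous bursts per minute (SBPM)** — is the standard readout, and
it is exquisitely sensitive to synaptic energetics: blocking AMPA
receptors (CNQX) abolishes bursts while spontaneous spikes persist,
blocking sodium channels (TTX) silences everything, and slowing the
synaptic-vesicle cycle — pharmacologically (v-ATPase inhibition) or by
withdrawing extracellular glucose — collapses the burst rate.

`synchroburst` provides, for experimentalists and modellers working with
such preparations:

* **`runDetector()`** — a two-stage synchronous-burst detector
  (per-electrode max-interval bursts → binned electrode-participation
  threshold → merge) producing an SBPM statistic with per-burst tables;
* **`simulateNetwork()`** — a conductance-based model of 400 simplified
  Hodgkin-Huxley neurons (instantaneous sodium activation) on a 20×20
  lattice with distance-decaying random excitatory connectivity, a
  single docked-vesicle pool per neuron (release fraction *U*, recovery
  rate *k*<sub>rec</sub>), and a presynaptic energy store *A* that pays
  for each release and is regenerated at a glucose-gated rate *G* —
  giving `dD/dt = k_rec0 · A/(A+K_A) · (1−D)` and
  `dA/dt = k_gen · G · (1−A)`;
* **`generateRecording()`** — a synthetic MEA recording generator with
  planted ground-truth bursts, used to validate the detector end to end;
* **`summarizeCondition()` / `compareConditions()` /
  `timecourseTable()`** — mean ± SEM summaries and Student's t-tests
  across biological conditions;
* **`runPipeline()` / `replayManifest()`** — a declarative,
  seed-explicit workflow (simulate-or-generate → detect → analyze) whose
  reports replay byte-identically from their manifest;
* plain-text spike-table I/O (`readSpikeTable()` / `writeSpikeTable()`)
  and an optional thin command-line wrapper in `inst/scripts/`.

Pharmacology maps onto model parameters, not special code paths:
CNQX → `gMax = 0`, TTX → `gNa = 0`, v-ATPase inhibition → scaling
`kRec0` down, glucose depletion → lowering `glucose`.

## Worked example

```r
library(synchroburst)

## a 10-minute synthetic recording with 4 planted bursts/min
out <- generateRecording(generatorParams(burstRate = 4, duration = 600,
                                         seed = 1))
res <- runDetector(out$recording)
out$recording
#> MEARecording 'synthetic'
#>   duration: 600 s | channels: 60 | spikes: 141888
res
#> SBPMResult: 39 network burst(s) in 10 min -> SBPM = 3.9
nrow(networkBursts(out$truth))   # 39 planted — all recovered
#> [1] 39

## the glucose effect in the network model (1 min per condition)
hi <- simulateNetwork(networkConfig(duration = 60, glucose = 1.0, seed = 1))
lo <- simulateNetwork(networkConfig(duration = 60, glucose = 0.1, seed = 1))
sbpm(runDetector(resultToRecording(hi)))   # 44 bursts/min
sbpm(runDetector(resultToRecording(lo)))   # 19 bursts/min

## condition-level statistics (SBPM values per replicate)
a <- summarizeCondition("glucose",  c(44, 38, 41))
b <- summarizeCondition("depleted", c(19, 22, 15))
compareConditions(a, b)
#> PairwiseComparison (unpaired Student's t): glucose vs depleted
#>   t = 8.375, df = 4, p = 0.001112
#>   note: raw p-value, no multiple-testing correction applied
```

The detector recovers the planted burst count exactly in this example
(39/39) and the simulated network sustains roughly twice the burst rate
under full glucose as under 10% availability, with synchronous bursts
vanishing entirely under the CNQX analog (`gMax = 0`) while spontaneous
spiking persists.

See `vignettes/synchroburst-methods.Rmd` for the model equations, the
detector's design, parameter meanings and defaults, numerical choices,
and known limitations.

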
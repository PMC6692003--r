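// Fixed-step integrator for the metabolically coupled excitatory network.
//
// Scheme (per step, in this order):
//   1. deliver delayed synaptic conductance increments due this step
//   2. external conductance events (per-neuron event clocks)
//   3. Rush-Larsen update of the gates (n, h integrated exactly against
//      their steady states at the current voltage) followed by an
//      exponential-Euler update of V (exact for frozen conductances);
//      synaptic/external conductances then decay analytically by
//      exp(-dt/tauSyn). With instantaneous sodium activation the voltage
//      equation is stiff during the spike upstroke (tau_V ~ 0.02 ms), so
//      this unconditionally stable scheme is used instead of an explicit
//      Runge-Kutta step.
//   4. relaxation of the docked pool D and energy store A
//   5. spike registration on upward threshold crossing outside the dead
//      time, with vesicle release, energy cost and delayed delivery to
//      postsynaptic targets (simultaneous spikes processed in index order)
//
// Steady states and per-step gate decay factors are tabulated on a fine
// voltage grid with linear interpolation; the RNG is a self-contained
// splitmix64 stream so rasters are bit-reproducible for a given seed on
// any platform.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ^ 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rexp(double rate) { return -std::log(unif()) / rate; }
};

// per grid point: {mInf^3, nInf, exp(-dt (an+bn)), hInf, exp(-dt (ah+bh))}
// (classic squid-axon rate functions; dt-specific decay factors baked in)
struct RateTable {
  double vLo, vHi, invStep;
  int nPts;
  std::vector<double> t;
  RateTable(double lo, double hi, double step, double dt)
      : vLo(lo), vHi(hi) {
    nPts = static_cast<int>((hi - lo) / step) + 2;
    invStep = 1.0 / step;
    t.resize(static_cast<size_t>(nPts) * 5);
    for (int i = 0; i < nPts; ++i) {
      double V = lo + i / invStep;
      double an = 0.1 * vexp((V + 55.0) / 10.0);
      double bn = 0.125 * std::exp(-(V + 65.0) / 80.0);
      double ah = 0.07 * std::exp(-(V + 65.0) / 20.0);
      double bh = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
      double am = vexp((V + 40.0) / 10.0);
      double bm = 4.0 * std::exp(-(V + 65.0) / 18.0);
      double mi = am / (am + bm);
      t[i * 5 + 0] = mi * mi * mi;
      t[i * 5 + 1] = an / (an + bn);
      t[i * 5 + 2] = std::exp(-dt * (an + bn));
      t[i * 5 + 3] = ah / (ah + bh);
      t[i * 5 + 4] = std::exp(-dt * (ah + bh));
    }
  }
  static double vexp(double x) {  // x / (1 - exp(-x)) with limit 1 at 0
    return std::fabs(x) < 1e-7 ? 1.0 : x / (1.0 - std::exp(-x));
  }
  inline void lookup(double V, double out[5]) const {
    double u = (V - vLo) * invStep;
    if (u < 0) u = 0;
    if (u > nPts - 2) u = nPts - 2;
    int i0 = static_cast<int>(u);
    double f = u - i0;
    const double* a = &t[static_cast<size_t>(i0) * 5];
    const double* b = a + 5;
    for (int k = 0; k < 5; ++k) out[k] = a[k] + f * (b[k] - a[k]);
  }
};

}  // namespace

// [[Rcpp::export]]
List sim_network_cpp(List cfg, IntegerVector edgeFrom, IntegerVector edgeTo,
                     NumericVector edgeWeight, IntegerVector traceNeurons) {
  const int n = as<int>(cfg["nNeurons"]);
  const double durS = as<double>(cfg["duration"]);
  const double dt = as<double>(cfg["dt"]);           // ms
  const double Cm = as<double>(cfg["Cm"]);
  const double invCm = 1.0 / Cm;
  const double gNa = as<double>(cfg["gNa"]);
  const double eNa = as<double>(cfg["eNa"]);
  const double gK = as<double>(cfg["gK"]);
  const double eK = as<double>(cfg["eK"]);
  const double gL = as<double>(cfg["gL"]);
  const double eL = as<double>(cfg["eL"]);
  const double vInit = as<double>(cfg["vInit"]);
  const double gMax = as<double>(cfg["gMax"]);
  const double tauSyn = as<double>(cfg["tauSyn"]);
  const double eSyn = as<double>(cfg["eSyn"]);
  const double U = as<double>(cfg["U"]);
  const double kRec0 = as<double>(cfg["kRec0"]);     // 1/s
  const double glucose = as<double>(cfg["glucose"]);
  const double kGenMax = as<double>(cfg["kGenMax"]); // 1/s
  const double KA = as<double>(cfg["KA"]);
  const double cA = as<double>(cfg["cA"]);
  const double nuExt = as<double>(cfg["nuExt"]);     // Hz
  const bool extPeriodic = as<bool>(cfg["extPeriodic"]);
  const double gExtInc = as<double>(cfg["gExt"]);
  const double iInject = as<double>(cfg["iInject"]);
  const double thr = as<double>(cfg["spikeThreshold"]);
  const double refractMs = as<double>(cfg["refractory"]);
  const double synDelay = as<double>(cfg["synDelay"]);
  const double traceDt = as<double>(cfg["traceDt"]);
  const uint64_t seed = static_cast<uint64_t>(as<double>(cfg["seed"]));

  const long nSteps = static_cast<long>(std::lround(durS * 1000.0 / dt));
  const double dtS = dt / 1000.0;
  const double decay = std::exp(-dt / tauSyn);
  const double facA = std::exp(-kGenMax * glucose * dtS);
  const int refractSteps =
      std::max(1, static_cast<int>(std::lround(refractMs / dt)));
  const int dSteps =
      std::max(1, static_cast<int>(std::lround(synDelay / dt)));
  const int ringLen = dSteps + 1;

  const RateTable tab(-130.0, 80.0, 0.02, dt);

  // CSR adjacency
  std::vector<int> outDeg(n, 0);
  const int nEdges = edgeFrom.size();
  for (int e = 0; e < nEdges; ++e) outDeg[edgeFrom[e] - 1]++;
  std::vector<int> offset(n + 1, 0);
  for (int i = 0; i < n; ++i) offset[i + 1] = offset[i] + outDeg[i];
  std::vector<int> tgt(nEdges);
  std::vector<double> wgt(nEdges);
  {
    std::vector<int> pos(offset.begin(), offset.end() - 1);
    for (int e = 0; e < nEdges; ++e) {
      int f = edgeFrom[e] - 1;
      tgt[pos[f]] = edgeTo[e] - 1;
      wgt[pos[f]] = edgeWeight[e];
      pos[f]++;
    }
  }

  // state
  std::vector<double> V(n, vInit), gate_n(n), gate_h(n), gs(n, 0.0),
      ge(n, 0.0), D(n, 1.0), A(n, 1.0), nextExt(n);
  std::vector<int> refract(n, 0);
  {
    double r[5];
    tab.lookup(vInit, r);
    for (int i = 0; i < n; ++i) { gate_n[i] = r[1]; gate_h[i] = r[3]; }
  }
  Rng rng(seed);
  const double extPeriodMs = (nuExt > 0) ? 1000.0 / nuExt : R_PosInf;
  for (int i = 0; i < n; ++i)
    nextExt[i] = (nuExt > 0)
        ? (extPeriodic ? extPeriodMs : rng.rexp(nuExt) * 1000.0)
        : R_PosInf;

  std::vector<double> ring(static_cast<size_t>(ringLen) * n, 0.0);

  // traces
  const int nTrace = traceNeurons.size();
  const long sampleEvery =
      std::max(1L, static_cast<long>(std::lround(traceDt / dt)));
  const long nSamples = nTrace ? (nSteps / sampleEvery + 1) : 0;
  NumericVector traceTime(nSamples);
  NumericMatrix traceV(nSamples, nTrace), traceD(nSamples, nTrace),
      traceA(nSamples, nTrace);
  long sampleRow = 0;
  if (nTrace) {
    traceTime[0] = 0.0;
    for (int k = 0; k < nTrace; ++k) {
      int i = traceNeurons[k] - 1;
      traceV(0, k) = V[i]; traceD(0, k) = D[i]; traceA(0, k) = A[i];
    }
    sampleRow = 1;
  }

  std::vector<int> spkNeuron;
  std::vector<double> spkTime;
  double Dmin = 1.0, Dmax = 1.0, Amin = 1.0, Amax = 1.0;

  const double kRecFacS = kRec0 * dtS;
  for (long s = 0; s < nSteps; ++s) {
    const double tMs = s * dt;
    const int slot = static_cast<int>(s % ringLen);
    double* deliver = &ring[static_cast<size_t>(slot) * n];
    const int futureSlot = static_cast<int>((s + dSteps) % ringLen);
    double* future = &ring[static_cast<size_t>(futureSlot) * n];

    for (int i = 0; i < n; ++i) {
      // 1. delayed deliveries
      gs[i] += deliver[i];
      deliver[i] = 0.0;
      // 2. external events
      while (nextExt[i] <= tMs) {
        ge[i] += gExtInc;
        nextExt[i] += extPeriodic ? extPeriodMs : rng.rexp(nuExt) * 1000.0;
      }
      // 3. Rush-Larsen gates, then exponential-Euler voltage
      const double gTot = gs[i] + ge[i];
      double r[5];
      const double Vi = V[i];
      tab.lookup(Vi, r);
      const double nn = r[1] + (gate_n[i] - r[1]) * r[2];
      const double hn = r[3] + (gate_h[i] - r[3]) * r[4];
      const double n2 = nn * nn;
      const double gNaEff = gNa * r[0] * hn;
      const double gKEff = gK * n2 * n2;
      const double gAll = gNaEff + gKEff + gL + gTot;
      const double vInf = (gNaEff * eNa + gKEff * eK + gL * eL +
                           gTot * eSyn + iInject) / gAll;
      const double Vn = vInf + (Vi - vInf) * std::exp(-dt * gAll * invCm);
      if (!std::isfinite(Vn) || std::fabs(Vn) > 500.0)
        stop("numerical divergence: |V| > 500 mV at neuron %d, t = %.4f s",
             i + 1, (s + 1) * dtS);
      gate_n[i] = nn;
      gate_h[i] = hn;
      gs[i] *= decay;
      ge[i] *= decay;
      // 4. D / A relaxation
      double Ai = 1.0 - (1.0 - A[i]) * facA;
      double kRecDt = kRecFacS * Ai / (Ai + KA);
      double Di = D[i] + kRecDt * (1.0 - D[i]);
      // 5. spike registration and release
      if (refract[i] == 0) {
        if (Vn >= thr && Vi < thr) {
          spkNeuron.push_back(i + 1);
          spkTime.push_back((s + 1) * dtS);
          refract[i] = refractSteps;
          double released = U * Di;
          Di *= (1.0 - U);
          Ai -= cA * released;
          if (Ai < 0.0) Ai = 0.0;
          const double inc = gMax * released;
          for (int e = offset[i]; e < offset[i + 1]; ++e)
            future[tgt[e]] += inc * wgt[e];
        }
      } else {
        refract[i]--;
      }
      V[i] = Vn;
      D[i] = Di;
      A[i] = Ai;
      if (Di < Dmin) Dmin = Di;
      if (Di > Dmax) Dmax = Di;
      if (Ai < Amin) Amin = Ai;
      if (Ai > Amax) Amax = Ai;
    }

    if (nTrace && ((s + 1) % sampleEvery == 0) && sampleRow < nSamples) {
      traceTime[sampleRow] = (s + 1) * dtS;
      for (int k = 0; k < nTrace; ++k) {
        int i = traceNeurons[k] - 1;
        traceV(sampleRow, k) = V[i];
        traceD(sampleRow, k) = D[i];
        traceA(sampleRow, k) = A[i];
      }
      sampleRow++;
    }
    if ((s & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["spikeNeuron"] = IntegerVector(spkNeuron.begin(), spkNeuron.end()),
      _["spikeTime"] = NumericVector(spkTime.begin(), spkTime.end()),
      _["Dmin"] = Dmin, _["Dmax"] = Dmax, _["Amin"] = Amin,
      _["Amax"] = Amax);
  if (nTrace) {
    out["traceTime"] = traceTime;
    out["traceV"] = traceV;
    out["traceD"] = traceD;
    out["traceA"] = traceA;
  }
  return out;
}
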
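#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Per-step simulation of the adaptive coincidence counting neuron over a
// batch of trials sharing one grid. Input spikes arrive as snapped grid-step
// indices (0-based), concatenated over trials with 0-based offsets.
//
// Per step j (t_j = j*dt):
//   1. v(t_j) = aE * (number of input spikes with start step in (j-L, j]),
//      i.e. each input is a rectangular count of L steps starting at its own
//      step (half-open window [s, s+L)).
//   2. if not refractory and v(t_j) >= 1 + thetaD(t_j): emit spike at t_j,
//      refractory until step j + refSteps.
//   3. thetaD(t_{j+1}) = alpha*thetaD(t_j) + (1-alpha)*sA*v(t_j)
//      (exact digital solution of TA dThetaD/dt = -thetaD + SA v with v
//      constant over the step; alpha = exp(-dt/TA)).
// The dynamic threshold depends only on the input history, never on output
// spikes, and keeps integrating during refractoriness.
//
// [[Rcpp::export(name = ".ccSimulateBatch")]]
List ccSimulateBatch(IntegerVector eventStep, IntegerVector trialOffsets,
                     int nSteps, int winSteps, int refSteps,
                     double aE, double sA, double alpha, double theta0) {
  if (winSteps < 1) stop("window must span at least one step");
  if (nSteps < 1) stop("nSteps must be positive");
  int nTrials = trialOffsets.size() - 1;
  std::vector<int> cnt((size_t)nSteps);
  std::vector<int> outStep;
  std::vector<int> outTrial;
  for (int tr = 0; tr < nTrials; ++tr) {
    std::memset(cnt.data(), 0, sizeof(int) * (size_t)nSteps);
    int from = trialOffsets[tr], to = trialOffsets[tr + 1];
    for (int k = from; k < to; ++k) {
      int s = eventStep[k];
      if (s < 0 || s >= nSteps) continue;
      cnt[(size_t)s] += 1;
    }
    double thetaD = theta0;
    int active = 0;
    int nextOk = 0;
    double oneMinusAlphaSA = (1.0 - alpha) * sA;
    for (int j = 0; j < nSteps; ++j) {
      active += cnt[(size_t)j];
      if (j >= winSteps) active -= cnt[(size_t)(j - winSteps)];
      double v = aE * active;
      if (j >= nextOk && v >= 1.0 + thetaD) {
        outStep.push_back(j);
        outTrial.push_back(tr + 1);
        nextOk = j + refSteps;
      }
      thetaD = alpha * thetaD + oneMinusAlphaSA * v;
    }
  }
  return List::create(_["step"] = wrap(outStep), _["trial"] = wrap(outTrial));
}

// Sequential dead-time thinning of a sorted candidate spike train: a
// candidate at interval d after the last accepted spike is rejected when
// d < absRef, and otherwise accepted with probability
// 1 - exp(-(d - absRef)/relRef) (exponential recovery). `u` supplies one
// uniform variate per candidate so the R side owns the RNG stream.
//
// [[Rcpp::export(name = ".anThinRefractory")]]
NumericVector anThinRefractory(NumericVector t, double absRef, double relRef,
                               NumericVector u) {
  int n = t.size();
  if (u.size() != n) stop("u must match t in length");
  std::vector<double> keep;
  keep.reserve((size_t)n);
  double last = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double d = t[i] - last;
    if (d < absRef) continue;
    if (relRef > 0) {
      double p = 1.0 - std::exp(-(d - absRef) / relRef);
      if (u[i] >= p) continue;
    }
    keep.push_back(t[i]);
    last = t[i];
  }
  return wrap(keep);
}
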
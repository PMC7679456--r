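#include <Rcpp.h>
using namespace Rcpp;

// Four behavioral states, coded 1..4:
//   1 = investigating stimulus 1, 2 = investigating stimulus 2,
//   3 = stillness, 4 = arena exploration.
// Structural zeros: no direct 1<->2, 1<->4, 2<->4 moves; leaving an
// investigation or exploration state always passes through stillness.

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Fill p[0..3] with the transition row out of `state` given current
// anxiety a and rewards r1, r2.
static void transitionRow(int state, double a, double r1, double r2,
                          double b1r, double b2r, double b1a, double b2a,
                          double S0, double E0, double *p) {
  p[0] = p[1] = p[2] = p[3] = 0.0;
  if (state == 1) {
    double stay = sigmoid(b1r * r1 + b1a * a);
    p[0] = stay; p[2] = 1.0 - stay;
  } else if (state == 2) {
    double stay = sigmoid(b1r * r2 + b1a * a);
    p[1] = stay; p[2] = 1.0 - stay;
  } else if (state == 3) {
    double l[4] = {b2r * r1, b2r * r2, S0 * b2a * a, E0};
    double m = std::max(std::max(l[0], l[1]), std::max(l[2], l[3]));
    double z = 0.0;
    for (int i = 0; i < 4; ++i) { l[i] = std::exp(l[i] - m); z += l[i]; }
    for (int i = 0; i < 4; ++i) p[i] = l[i] / z;
  } else {
    double stay = sigmoid(S0 + E0 - b2a * a);
    p[3] = stay; p[2] = 1.0 - stay;
  }
}

// Simulate nSteps occupancy steps of the four-state chain. The state at
// t = 0 (initState) occupies the first step; nSteps - 1 transitions are
// drawn. Anxiety and rewards are recomputed every step from the elapsed
// step count t and the cumulative investigation step counts T1, T2, with
// t, T1, T2 in model time units (steps). Infinite tauR/tauA freeze the
// dynamics at their initial values. Uses R's RNG stream.
// [[Rcpp::export(name = ".simulateStatePath")]]
IntegerVector simulateStatePath(int nSteps, double a0, double r10, double r20,
                                double tauR, double tauA,
                                double b1r, double b2r, double b1a, double b2a,
                                double S0, double E0, double s,
                                int initState, bool clampAnxiety) {
  if (nSteps <= 0) return IntegerVector(0);
  RNGScope scope;
  IntegerVector out(nSteps);
  int state = initState;
  double T1 = 0.0, T2 = 0.0;
  double p[4];
  out[0] = state;
  if (state == 1) T1 += 1.0; else if (state == 2) T2 += 1.0;
  for (int k = 1; k < nSteps; ++k) {
    double t = (double)k;  // elapsed model time units before this draw
    double r1 = (std::isfinite(tauR)) ? r10 * std::exp(s * T1 / tauR) : r10;
    double r2 = (std::isfinite(tauR)) ? r20 * std::exp(s * T2 / tauR) : r20;
    double a = (std::isfinite(tauA) ? a0 * std::exp(-t / tauA) : a0)
               - std::fabs(r1 - r2);
    if (clampAnxiety && a < 0.0) a = 0.0;
    transitionRow(state, a, r1, r2, b1r, b2r, b1a, b2a, S0, E0, p);
    double u = unif_rand(), c = 0.0;
    int next = 4;  // guard against accumulated rounding
    for (int i = 0; i < 4; ++i) { c += p[i]; if (u < c) { next = i + 1; break; } }
    state = next;
    out[k] = state;
    if (state == 1) T1 += 1.0; else if (state == 2) T2 += 1.0;
  }
  return out;
}
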
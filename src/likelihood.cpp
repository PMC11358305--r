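#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1pexp_(double x) {
  if (x > 0.0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

// Negative log-likelihood of a session under the EXP model.
// chosen/other: 1-based stimulus indices of the chosen and unchosen option;
// reward: drops delivered; alpha: per-trial learning rate (constant for the
// basic variant, split by post-reversal mask for the modified variant).
// Values start at zero; the choice probability at trial t uses the values
// before trial t's update.
// [[Rcpp::export]]
double nll_exp_cpp(IntegerVector chosen, IntegerVector other,
                   IntegerVector reward, NumericVector alpha, double beta) {
  int n = chosen.size();
  if (other.size() != n || reward.size() != n || alpha.size() != n)
    stop("input vectors must share a length");
  double V[5] = {0.0, 0.0, 0.0, 0.0, 0.0};
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int c = chosen[t] - 1, o = other[t] - 1;
    double d = beta * (V[c] - V[o]);
    nll += log1pexp_(-d);  // -log plogis(d)
    if (!std::isfinite(nll)) stop("non-finite likelihood at trial %d", t + 1);
    V[c] -= alpha[t] * (V[c] - reward[t]);
  }
  return nll;
}

// Negative log-likelihood of a session under the INF model: fixed value
// tables V_A[i] = i, V_B[i] = 6 - i; confidence weight w starts at 0.5, is
// updated by a gradient step on the squared reward-prediction error, and is
// clipped to [0, 1] after every update.
// [[Rcpp::export]]
double nll_inf_cpp(IntegerVector chosen, IntegerVector other,
                   IntegerVector reward, NumericVector alpha, double beta) {
  int n = chosen.size();
  if (other.size() != n || reward.size() != n || alpha.size() != n)
    stop("input vectors must share a length");
  double w = 0.5, nll = 0.0;
  for (int t = 0; t < n; ++t) {
    double vac = chosen[t], vbc = 6.0 - chosen[t];
    double vao = other[t], vbo = 6.0 - other[t];
    double pA = 1.0 / (1.0 + std::exp(-beta * (vac - vao)));
    double pB = 1.0 / (1.0 + std::exp(-beta * (vbc - vbo)));
    // the balanced mixture is exactly 1/2: V_B = 6 - V_A reflects the softmax
    double p = (w == 0.5) ? 0.5 : w * pA + (1.0 - w) * pB;
    if (std::isnan(p)) stop("non-finite likelihood at trial %d", t + 1);
    if (p < DBL_MIN) p = DBL_MIN;  // degenerate mixture at extreme beta
    nll -= std::log(p);
    w -= alpha[t] * ((w * vac + (1.0 - w) * vbc) - reward[t]) * (vac - vbc);
    if (w < 0.0) w = 0.0;
    if (w > 1.0) w = 1.0;
  }
  return nll;
}
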
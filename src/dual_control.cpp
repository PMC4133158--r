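#include <Rcpp.h>
using namespace Rcpp;

// Forward-pass negative log-likelihood of the dual-control choice model.
// choice: 1-based option index per trial. reward: per-option reward value
// (max normalized to 1). Goal-directed values update the chosen option by
// reward prediction error (rate alpha_c) and, when decay_unchosen, decay
// unchosen options toward 0 (rate alpha_u). Habit values are a leaky
// integrator of the choice indicator with per-trial retention
// exp(-1/kappa). Choice probabilities are softmax over
// beta_G * Q + beta_H * H with max-subtraction for stability.
// [[Rcpp::export]]
double dc_nll(IntegerVector choice, NumericVector reward,
              double alpha_c, double alpha_u, double kappa,
              double beta_G, double beta_H,
              bool use_goal, bool use_habit, bool decay_unchosen) {
  const int N = choice.size();
  const int K = reward.size();
  std::vector<double> Q(K, 0.0), H(K, 0.0), z(K);
  const double d = use_habit ? std::exp(-1.0 / kappa) : 0.0;
  double nll = 0.0;
  for (int t = 0; t < N; ++t) {
    const int c = choice[t] - 1;
    double zmax = -INFINITY;
    for (int i = 0; i < K; ++i) {
      z[i] = (use_goal ? beta_G * Q[i] : 0.0) +
             (use_habit ? beta_H * H[i] : 0.0);
      if (z[i] > zmax) zmax = z[i];
    }
    double denom = 0.0;
    for (int i = 0; i < K; ++i) denom += std::exp(z[i] - zmax);
    nll -= (z[c] - zmax) - std::log(denom);
    if (use_goal) {
      Q[c] += alpha_c * (reward[c] - Q[c]);
      if (decay_unchosen) {
        for (int i = 0; i < K; ++i)
          if (i != c) Q[i] += alpha_u * (0.0 - Q[i]);
      }
    }
    if (use_habit) {
      for (int i = 0; i < K; ++i)
        H[i] = d * (H[i] + (i == c ? 1.0 : 0.0));
    }
  }
  return nll;
}

// Generative counterpart of dc_nll: samples a choice sequence with the
// same online value updates. u: pre-drawn uniforms (length n_trials) so
// the R RNG stream governs reproducibility.
// [[Rcpp::export]]
IntegerVector dc_simulate(int n_trials, NumericVector reward,
                          double alpha_c, double alpha_u, double kappa,
                          double beta_G, double beta_H,
                          bool use_goal, bool use_habit,
                          bool decay_unchosen, NumericVector u) {
  const int K = reward.size();
  std::vector<double> Q(K, 0.0), H(K, 0.0), z(K), p(K);
  const double d = use_habit ? std::exp(-1.0 / kappa) : 0.0;
  IntegerVector out(n_trials);
  for (int t = 0; t < n_trials; ++t) {
    double zmax = -INFINITY;
    for (int i = 0; i < K; ++i) {
      z[i] = (use_goal ? beta_G * Q[i] : 0.0) +
             (use_habit ? beta_H * H[i] : 0.0);
      if (z[i] > zmax) zmax = z[i];
    }
    double denom = 0.0;
    for (int i = 0; i < K; ++i) { p[i] = std::exp(z[i] - zmax); denom += p[i]; }
    double cum = 0.0;
    int c = K - 1;
    const double target = u[t] * denom;
    for (int i = 0; i < K; ++i) {
      cum += p[i];
      if (cum >= target) { c = i; break; }
    }
    out[t] = c + 1;
    if (use_goal) {
      Q[c] += alpha_c * (reward[c] - Q[c]);
      if (decay_unchosen) {
        for (int i = 0; i < K; ++i)
          if (i != c) Q[i] += alpha_u * (0.0 - Q[i]);
      }
    }
    if (use_habit) {
      for (int i = 0; i < K; ++i)
        H[i] = d * (H[i] + (i == c ? 1.0 : 0.0));
    }
  }
  return out;
}
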
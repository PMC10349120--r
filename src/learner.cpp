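// Forward pass of the beta-belief learners (one-state and n-state), the beta
// negative log-likelihood, and the Monte-Carlo CRP new-state probabilities.
// Mirrors the exported R reference implementation (step_nstate etc.); the two
// engines are cross-checked in the test suite.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double beta_mode_ab(double a, double b) {
  // mode of Beta(a, b) for a,b >= 1; flat Beta(1,1) -> 0.5 by convention
  if (a + b == 2.0) return 0.5;
  return (a - 1.0) / (a + b - 2.0);
}

static inline double beta_sd_ab(double a, double b) {
  double s = a + b;
  return std::sqrt(a * b / (s * s * (s + 1.0)));
}

// belief update: active state gets the tau increment (Eqs for shock/no-shock),
// every state decays by lam; floor at 1 keeps the density unimodal; proportional
// rescale enforces the evidence cap, with a re-floor so both invariants hold.
static inline void update_ab(double &a, double &b, int o, bool active,
                             double tau_p, double tau_m, double lam,
                             double cap) {
  if (active) {
    if (o == 1) { a = lam * (a + tau_p); b = lam * b; }
    else        { b = lam * (b + tau_m); a = lam * a; }
  } else {
    a = lam * a; b = lam * b;
  }
  if (a < 1.0) a = 1.0;
  if (b < 1.0) b = 1.0;
  double s = a + b;
  if (s > cap) {
    a *= cap / s; b *= cap / s;
    if (a < 1.0) { a = 1.0; b = cap - 1.0; }
    else if (b < 1.0) { b = 1.0; a = cap - 1.0; }
  }
}

// solve for the concentration c of a mode-parameterised beta (a = 1 + m c,
// b = 1 + (1-m) c) whose SD equals target_sd; SD is decreasing in c and its
// supremum (c -> 0) is the Beta(1,1) SD, an upper bound for any a,b >= 1,
// so a root always exists on [0, cap-2].
static double solve_conc(double m, double target_sd, double cap) {
  double lo = 0.0, hi = cap - 2.0;
  if (beta_sd_ab(1.0 + m * hi, 1.0 + (1.0 - m) * hi) >= target_sd) return hi;
  for (int i = 0; i < 100; ++i) {
    double mid = 0.5 * (lo + hi);
    double sd = beta_sd_ab(1.0 + m * mid, 1.0 + (1.0 - m) * mid);
    if (sd > target_sd) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

struct Trace {
  std::vector<double> p_hat, sigma, surprise, a_pre, b_pre;
  std::vector<int> state_id, n_states, event;
};

static void forward_core(const IntegerVector &outcomes, double tau_p,
                         double tau_m, double lam, double a0, double b0,
                         double eta, bool nstate, double pi_s, double cap,
                         double eps, const NumericVector &q_table, Trace &tr) {
  int T = outcomes.size();
  tr.p_hat.resize(T); tr.sigma.resize(T); tr.surprise.resize(T);
  tr.a_pre.resize(T); tr.b_pre.resize(T);
  tr.state_id.resize(T); tr.n_states.resize(T); tr.event.resize(T);

  std::vector<double> a(1, a0), b(1, b0), S(1, 0.0);
  std::vector<int> last(1, -1);
  int active = 0;
  const double sd0 = beta_sd_ab(a0, b0);
  const int qn = q_table.size();

  for (int t = 0; t < T; ++t) {
    const double pa = a[active], pb = b[active];
    double m = beta_mode_ab(pa, pb);
    if (m < eps) m = eps; else if (m > 1.0 - eps) m = 1.0 - eps;
    const double sg = beta_sd_ab(pa, pb);
    tr.a_pre[t] = pa; tr.b_pre[t] = pb;
    tr.p_hat[t] = m; tr.sigma[t] = sg; tr.state_id[t] = active + 1;

    const int O = outcomes[t];
    S[active] = (1.0 - pi_s) * S[active] + pi_s * std::fabs((double)O - m);
    const double Sa = S[active];
    tr.surprise[t] = Sa;
    last[active] = t;

    const int K = (int)a.size();
    for (int j = 0; j < K; ++j)
      update_ab(a[j], b[j], O, j == active, tau_p, tau_m, lam, cap);

    int ev = 0;
    if (nstate) {
      const double thr = sg * eta;
      if (Sa > thr) {
        // difficulty for the prospective (K+1)-th state
        const double q = q_table[std::min(K + 1, qn) - 1];
        double sgn = 0.0;
        if ((double)O > m) sgn = 1.0; else if ((double)O < m) sgn = -1.0;
        double E = m + sgn * Sa;
        if (E < eps) E = eps; else if (E > 1.0 - eps) E = 1.0 - eps;
        // poll existing states whose mode lies within E +/- sigma*eta;
        // most likely = max beta density at E, ties broken by recency
        int best = -1; double bestd = -1.0;
        for (int j = 0; j < K; ++j) {
          if (std::fabs(beta_mode_ab(a[j], b[j]) - E) <= thr) {
            double d = R::dbeta(E, a[j], b[j], 0);
            if (d > bestd ||
                (d == bestd && best >= 0 && last[j] > last[best])) {
              bestd = d; best = j;
            }
          }
        }
        if (Sa <= thr * q) {               // switch zone: poll only
          if (best >= 0 && best != active) { active = best; ev = 1; }
        } else {                           // create zone: poll, then create
          if (best >= 0) {
            if (best != active) { active = best; ev = 1; }
          } else {
            double c = solve_conc(E, sd0, cap);
            a.push_back(1.0 + E * c);
            b.push_back(1.0 + (1.0 - E) * c);
            S.push_back(0.0);
            last.push_back(-1);
            active = (int)a.size() - 1;
            ev = 2;
          }
        }
      }
    }
    tr.event[t] = ev;
    tr.n_states[t] = (int)a.size();
  }
}

// [[Rcpp::export]]
List forward_pass_cpp(IntegerVector outcomes, double tau_plus,
                      double tau_minus, double lam, double a0, double b0,
                      double eta, bool nstate, double pi_s, double cap,
                      double eps, NumericVector q_table) {
  Trace tr;
  forward_core(outcomes, tau_plus, tau_minus, lam, a0, b0, eta, nstate,
               pi_s, cap, eps, q_table, tr);
  return List::create(
      _["p_hat"] = tr.p_hat, _["sigma"] = tr.sigma,
      _["surprise"] = tr.surprise, _["a_pre"] = tr.a_pre,
      _["b_pre"] = tr.b_pre, _["active_state"] = tr.state_id,
      _["n_states"] = tr.n_states, _["event"] = tr.event);
}

// [[Rcpp::export]]
double negloglik_cpp(IntegerVector outcomes, NumericVector ratings,
                     double tau_plus, double tau_minus, double lam, double a0,
                     double b0, double eta, bool nstate, double pi_s,
                     double cap, double eps, NumericVector q_table) {
  Trace tr;
  forward_core(outcomes, tau_plus, tau_minus, lam, a0, b0, eta, nstate,
               pi_s, cap, eps, q_table, tr);
  double nll = 0.0;
  int T = outcomes.size();
  for (int t = 0; t < T; ++t) {
    double r = ratings[t];
    if (ISNAN(r)) continue;
    nll -= R::dbeta(r, tr.a_pre[t], tr.b_pre[t], 1);
  }
  return nll;
}

// Monte-Carlo per-K probability of opening a new state under a CRP with
// concentration theta, averaged over n_mc seating sequences of length horizon.
// [[Rcpp::export]]
NumericVector crp_new_prob_cpp(int horizon, int n_mc, double theta,
                               int k_max) {
  std::vector<double> sums(k_max, 0.0);
  std::vector<long> cnt(k_max, 0);
  for (int it = 0; it < n_mc; ++it) {
    int K = 1;  // first customer opens the first table
    for (int t = 2; t <= horizon; ++t) {
      double p = theta / (t - 1 + theta);
      int idx = std::min(K, k_max) - 1;
      sums[idx] += p; cnt[idx]++;
      if (unif_rand() < p) K++;
    }
  }
  NumericVector out(k_max, NA_REAL);
  for (int k = 0; k < k_max; ++k)
    if (cnt[k] > 0) out[k] = sums[k] / cnt[k];
  return out;
}
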
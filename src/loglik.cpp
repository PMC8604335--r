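#include <Rcpp.h>
using namespace Rcpp;

static inline double clip(double x, double eps) {
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

// Joint log-likelihood of one session's choices and causality reports
// under an MABC variant. Mirrors the R reference (mabc_trace) operation
// for operation so the two paths agree bit-for-bit.
//
// par is the full parameter vector in canonical order:
//   a_self, a_other, bias_pos, bias_neg, beta0, tau, theta, beta_con
// actions are 0 = left, 1 = right; resp_self is 1/0 on causality probe
// trials and ignored elsewhere.
// [[Rcpp::export]]
double mabc_loglik_cpp(IntegerVector a_self, IntegerVector a_other,
                       IntegerVector outcome, IntegerVector is_probe,
                       IntegerVector resp_self, NumericVector par,
                       bool use_other_likelihood, bool mirrored_update,
                       bool report_log_odds) {
  const double eps = 1e-6, peps = 1e-12;
  const double lr_s = par[0], lr_o = par[1], bias_pos = par[2],
               bias_neg = par[3], beta0 = par[4], tau = par[5],
               theta = par[6], beta_con = par[7];
  const int n = a_self.size();
  // contingency table: rows self/other frame, columns left/right
  double tab[2][2] = {{0.5, 0.5}, {0.5, 0.5}};
  double prior = 0.5;
  double ll = 0.0;

  for (int k = 0; k < n; ++k) {
    // choice likelihood under the current prediction
    double d = tab[0][1] - tab[0][0];  // value(right) - value(left)
    double p_right;
    if (d == 0.0) {
      p_right = 0.5;
    } else {
      double pc = clip(prior, eps);
      double beta = beta0 * std::pow(pc / (1.0 - pc), tau);
      if (!std::isfinite(beta)) beta = 1e10;
      p_right = 1.0 / (1.0 + std::exp(-beta * d));
    }
    double pr = clip(p_right, peps);
    ll += (a_self[k] == 1) ? std::log(pr) : std::log(1.0 - pr);

    // contingency updates from the recorded actions and outcome
    const int o = outcome[k];
    const int as = a_self[k], ao = a_other[k];
    tab[0][as] += lr_s * (o - tab[0][as]);
    tab[1][ao] += lr_o * (o - tab[1][ao]);
    if (mirrored_update) {
      tab[0][1 - as] = 1.0 - tab[0][as];
      tab[1][1 - ao] = 1.0 - tab[1][ao];
    }

    // likelihoods from the updated table, then the biased posterior
    double ls = (o == 1) ? tab[0][as] : 1.0 - tab[0][as];
    double lo = (o == 1) ? tab[1][ao] : 1.0 - tab[1][ao];
    double pc = clip(prior, eps);
    ls = clip(ls, eps);
    lo = use_other_likelihood ? clip(lo, eps) : 0.5;
    double w = std::exp(o == 1 ? bias_pos : bias_neg);
    double num = w * ls * pc;
    double post = std::isfinite(num)
      ? clip(num / (num + lo * (1.0 - pc)), eps)
      : 1.0 - eps;  // bias -> +Inf limit

    // causality-report likelihood
    if (is_probe[k] == 1) {
      double x = report_log_odds ? std::log(post / (1.0 - post))
                                 : 2.0 * post - 1.0;
      double p_rep = clip(1.0 / (1.0 + std::exp(-beta_con * x)), peps);
      ll += (resp_self[k] == 1) ? std::log(p_rep) : std::log(1.0 - p_rep);
    }

    // drifted prediction for the next trial
    prior = (1.0 - theta) * post + 0.5 * theta;
  }
  return ll;
}

// Log-likelihood of a Rescorla-Wagner softmax agent's choice stream.
// session_start[k] == 1 resets the action values to q0 (new session).
// [[Rcpp::export]]
double rw_loglik_cpp(IntegerVector action, IntegerVector outcome,
                     IntegerVector session_start, double learning_rate,
                     double inv_temp, double q0) {
  const double peps = 1e-12;
  const int n = action.size();
  double q[2] = {q0, q0};
  double ll = 0.0;
  for (int k = 0; k < n; ++k) {
    if (session_start[k] == 1) { q[0] = q0; q[1] = q0; }
    double p_right = 1.0 / (1.0 + std::exp(-inv_temp * (q[1] - q[0])));
    double pr = clip(p_right, peps);
    ll += (action[k] == 1) ? std::log(pr) : std::log(1.0 - pr);
    const int a = action[k];
    q[a] += learning_rate * (outcome[k] - q[a]);
  }
  return ll;
}
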
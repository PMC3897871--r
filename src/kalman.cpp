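// Kalman-filter belief recursion and softmax likelihood.
// choices are 0-based; -1 marks a missed trial (diffusion only, no
// observation and no likelihood term).

#include <Rcpp.h>
using namespace Rcpp;

static inline double gain(double v, double so) {
  double denom = v + so * so;
  return denom < 1e-12 ? 1.0 : v / denom;
}

// Advance beliefs over a session, recording the pre-choice means per trial.
// [[Rcpp::export]]
NumericMatrix cpp_prechoice_means(IntegerVector choices, NumericVector rewards,
                                  int n_arms, double lam, double theta,
                                  double sd, double so, double mu0,
                                  double var0) {
  int T = choices.size();
  NumericMatrix M(T, n_arms);
  std::vector<double> m(n_arms, mu0), v(n_arms, var0);
  for (int t = 0; t < T; ++t) {
    for (int a = 0; a < n_arms; ++a) M(t, a) = m[a];
    int c = choices[t];
    if (c >= 0) {
      double k = gain(v[c], so);
      m[c] += k * (rewards[t] - m[c]);
      v[c] *= (1.0 - k);
    }
    for (int a = 0; a < n_arms; ++a) {
      m[a] = lam * m[a] + (1.0 - lam) * theta;
      v[a] = lam * lam * v[a] + sd * sd;
    }
  }
  return M;
}

static double nll_from_means(const NumericMatrix& M,
                             const IntegerVector& choices, double beta) {
  int T = M.nrow(), A = M.ncol();
  double nll = 0.0;
  for (int t = 0; t < T; ++t) {
    int c = choices[t];
    if (c < 0) continue;
    double mx = M(t, 0);
    for (int a = 1; a < A; ++a) if (M(t, a) > mx) mx = M(t, a);
    double s = 0.0;
    for (int a = 0; a < A; ++a) s += std::exp(beta * (M(t, a) - mx));
    nll += std::log(s) - beta * (M(t, c) - mx);
  }
  return nll;
}

// [[Rcpp::export]]
double cpp_session_nll(IntegerVector choices, NumericVector rewards,
                       int n_arms, double lam, double theta, double sd,
                       double so, double mu0, double var0, double beta) {
  NumericMatrix M = cpp_prechoice_means(choices, rewards, n_arms, lam, theta,
                                        sd, so, mu0, var0);
  return nll_from_means(M, choices, beta);
}

// NLL and its first/second derivatives in beta (one pass over trials).
// The NLL is convex in beta: a log-sum-exp of linear functions minus a
// linear function, so g is nondecreasing and Newton with a bisection
// safeguard converges.
static void nll_beta_derivs(const NumericMatrix& M,
                            const IntegerVector& choices, double beta,
                            double* f, double* g, double* h) {
  int T = M.nrow(), A = M.ncol();
  *f = 0.0; *g = 0.0; *h = 0.0;
  for (int t = 0; t < T; ++t) {
    int c = choices[t];
    if (c < 0) continue;
    double mx = M(t, 0);
    for (int a = 1; a < A; ++a) if (M(t, a) > mx) mx = M(t, a);
    double s = 0.0, s1 = 0.0, s2 = 0.0;
    for (int a = 0; a < A; ++a) {
      double m = M(t, a) - mx;
      double e = std::exp(beta * m);
      s += e; s1 += e * m; s2 += e * m * m;
    }
    double mean = s1 / s;
    *f += std::log(s) - beta * (M(t, c) - mx);
    *g += mean - (M(t, c) - mx);
    *h += s2 / s - mean * mean;
  }
}

// Minimize the session NLL over beta in [lo, hi].
static double opt_beta(const NumericMatrix& M, const IntegerVector& choices,
                       double lo, double hi, double tol, double* fmin) {
  double f, g, h;
  nll_beta_derivs(M, choices, lo, &f, &g, &h);
  if (g >= 0.0) { if (fmin) *fmin = f; return lo; }     // minimum at lower bound
  nll_beta_derivs(M, choices, hi, &f, &g, &h);
  if (g <= 0.0) { if (fmin) *fmin = f; return hi; }     // minimum at upper bound
  double a = lo, b = hi;                                // g(a) < 0 < g(b)
  double x = 0.5 * (a + b);
  for (int it = 0; it < 100 && b - a > tol; ++it) {
    nll_beta_derivs(M, choices, x, &f, &g, &h);
    if (g < 0.0) a = x; else b = x;
    double step = (h > 1e-12) ? x - g / h : 0.5 * (a + b);
    x = (step > a && step < b) ? step : 0.5 * (a + b);
  }
  nll_beta_derivs(M, choices, x, &f, &g, &h);
  if (fmin) *fmin = f;
  return x;
}

// Total cohort NLL at shared learning parameters, with each subject's beta
// profiled out over [beta_lo, beta_hi]. `choices` / `rewards` are lists of
// per-subject vectors.
// [[Rcpp::export]]
List cpp_cohort_profile_nll(List choices, List rewards, int n_arms,
                            double lam, double theta, double sd, double so,
                            double mu0, double var0, double beta_lo,
                            double beta_hi, double beta_tol) {
  int S = choices.size();
  NumericVector betas(S), nlls(S);
  double total = 0.0;
  for (int s = 0; s < S; ++s) {
    IntegerVector ch = choices[s];
    NumericVector rw = rewards[s];
    NumericMatrix M = cpp_prechoice_means(ch, rw, n_arms, lam, theta, sd, so,
                                          mu0, var0);
    double fm;
    betas[s] = opt_beta(M, ch, beta_lo, beta_hi, beta_tol, &fm);
    nlls[s] = fm;
    total += fm;
  }
  return List::create(_["total_nll"] = total, _["betas"] = betas,
                      _["nlls"] = nlls);
}
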
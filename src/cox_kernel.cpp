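#include <Rcpp.h>
using namespace Rcpp;

// Partial log-likelihood, score and observed information for a Cox model
// at a fixed coefficient vector. Rows must be sorted by ascending follow-up
// time before entry; subjects censored at an event time stay in that event's
// risk set. method: 0 = Breslow, 1 = Efron.
//
// Accumulates risk-set sums S0 = sum w, S1 = sum w*x, S2 = sum w*x*x' by a
// single backward sweep over the sorted rows, then applies the tie
// correction within each distinct event time.
// [[Rcpp::export]]
List cox_eval(const NumericMatrix& X, const NumericVector& time,
              const IntegerVector& event, const NumericVector& beta,
              const int method) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
    eta[i] = s;
  }

  double ll = 0.0;
  NumericVector grad(p);
  NumericMatrix hess(p, p);

  std::vector<double> r1(p, 0.0), d1(p, 0.0), xb(p, 0.0);
  std::vector<double> r2(p * p, 0.0), d2(p * p, 0.0);
  double r0 = 0.0;

  int i = n - 1;
  while (i >= 0) {
    // add the whole tie group (events and censored share the risk set)
    int g_end = i;
    const double t = time[i];
    while (i >= 0 && time[i] == t) {
      const double w = std::exp(eta[i]);
      r0 += w;
      for (int a = 0; a < p; ++a) {
        const double wx = w * X(i, a);
        r1[a] += wx;
        for (int b = a; b < p; ++b) r2[a * p + b] += wx * X(i, b);
      }
      --i;
    }
    // collect the events at this time
    double d0 = 0.0;
    int d = 0;
    std::fill(d1.begin(), d1.end(), 0.0);
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int k = i + 1; k <= g_end; ++k) {
      if (event[k] != 1) continue;
      ++d;
      const double w = std::exp(eta[k]);
      d0 += w;
      ll += eta[k];
      for (int a = 0; a < p; ++a) {
        grad[a] += X(k, a);
        const double wx = w * X(k, a);
        d1[a] += wx;
        for (int b = a; b < p; ++b) d2[a * p + b] += wx * X(k, b);
      }
    }
    if (d == 0) continue;
    for (int l = 0; l < d; ++l) {
      const double f = (method == 1) ? (double)l / d : 0.0;
      const double phi = r0 - f * d0;
      ll -= std::log(phi);
      for (int a = 0; a < p; ++a) xb[a] = (r1[a] - f * d1[a]) / phi;
      for (int a = 0; a < p; ++a) {
        grad[a] -= xb[a];
        for (int b = a; b < p; ++b) {
          const double h = (r2[a * p + b] - f * d2[a * p + b]) / phi -
                           xb[a] * xb[b];
          hess(a, b) += h;
          if (b != a) hess(b, a) += h;
        }
      }
    }
  }

  return List::create(_["loglik"] = ll, _["grad"] = grad, _["info"] = hess);
}
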
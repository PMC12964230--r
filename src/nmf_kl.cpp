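// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double EPS = 1e-16;

// Generalized Kullback-Leibler divergence D(V || WH).
// Terms with v == 0 contribute x (lim v->0 of v*log(v/x) - v + x).
static double kl_divergence(const arma::mat& V, const arma::mat& WH) {
  double d = 0.0;
  const arma::uword n = V.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    double v = V[i];
    double x = WH[i] < EPS ? EPS : WH[i];
    if (v > 0.0) {
      d += v * std::log(v / x) - v + x;
    } else {
      d += x;
    }
  }
  return d;
}

static inline void clamp_eps(arma::mat& m) {
  m.transform([](double x) { return x < EPS ? EPS : x; });
}

//' Multiplicative-update NMF minimizing generalized KL divergence
//'
//' Alternating Lee-Seung updates of H then W, each against the freshly
//' recomputed reconstruction, which guarantees a non-increasing objective.
//' The objective is recorded every `trace_every` iterations; convergence
//' is declared when the relative change between objectives `window`
//' iterations apart drops below `tol` (`window` must be a multiple of
//' `trace_every`).
//'
//' @noRd
// [[Rcpp::export(name = ".nmf_kl_cpp", rng = false)]]
List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                int max_iter, double tol, int window, int trace_every) {
  const arma::uword m = V.n_rows, n = V.n_cols;
  (void)n;
  std::vector<double> trace;
  std::vector<int> trace_iter;

  arma::mat WH = W * H;
  clamp_eps(WH);
  trace.push_back(kl_divergence(V, WH));
  trace_iter.push_back(0);

  arma::mat Q(m, V.n_cols);
  int it = 0;
  const int lag = window / trace_every;  // recorded points per window
  for (it = 1; it <= max_iter; ++it) {
    // H update: H *= (W' (V/WH)) / colsum(W)
    Q = V / WH;
    arma::colvec wsum = arma::sum(W, 0).t();
    wsum.transform([](double x) { return x < EPS ? EPS : x; });
    H %= W.t() * Q;
    H.each_col() /= wsum;

    WH = W * H;
    clamp_eps(WH);

    // W update: W *= ((V/WH) H') / rowsum(H)
    Q = V / WH;
    arma::rowvec hsum = arma::sum(H, 1).t();
    hsum.transform([](double x) { return x < EPS ? EPS : x; });
    W %= Q * H.t();
    W.each_row() /= hsum;

    WH = W * H;
    clamp_eps(WH);

    if (it % trace_every == 0 || it == max_iter) {
      trace.push_back(kl_divergence(V, WH));
      trace_iter.push_back(it);
      int k = trace.size() - 1;
      if (lag > 0 && k >= lag) {
        double prev = trace[k - lag];
        double cur = trace[k];
        double rel = std::fabs(prev - cur) / std::max(std::fabs(prev), 1e-12);
        if (rel < tol) break;
      }
    }
  }

  return List::create(_["W"] = W, _["H"] = H,
                      _["objective_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["trace_iterations"] = IntegerVector(trace_iter.begin(), trace_iter.end()),
                      _["iterations"] = std::min(it, max_iter));
}
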
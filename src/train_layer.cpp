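// Hot path of layer training: the per-presentation loop (activation,
// sparseness-setting sigmoid, trace maintenance, weight update). Mirrors
// the R reference engine in training.R exactly; a parity test compares the
// two on small instances.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct RateResult {
  std::vector<double> y;
  int k;
  double a;
};

// activations -> rates at a target sparseness; identical algorithm to
// rates_from_activations() in R/activation.R
RateResult rates_from_activations_cpp(const std::vector<double>& r,
                                      double a_target, double beta) {
  const int n = r.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  // descending by activation, ties broken by index (deterministic and
  // identical to R's stable order())
  auto cmp = [&](int a, int b) {
    return r[a] > r[b] || (r[a] == r[b] && a < b);
  };
  // adaptive partial sort: the bracket search only probes small k
  int sorted_to = 0;
  std::vector<double> rs(n);
  auto ensure_sorted = [&](int k) {
    if (k <= sorted_to) return;
    int m = std::min(n, std::max(2 * sorted_to, std::max(k, 64)));
    std::partial_sort(ord.begin(), ord.begin() + m, ord.end(), cmp);
    for (int i = 0; i < m; ++i) rs[i] = r[ord[i]];
    sorted_to = m;
  };
  double rmin = r[0], rmax = r[0];
  for (int i = 1; i < n; ++i) {
    if (r[i] < rmin) rmin = r[i];
    if (r[i] > rmax) rmax = r[i];
  }

  RateResult out;
  out.y.assign(n, 0.0);

  if (rmin == rmax) {
    ensure_sorted(n);  // degenerate: top-k by index
    int k = std::max(1, (int)std::nearbyint(a_target * n));
    for (int j = 0; j < k; ++j) out.y[ord[j]] = 0.5;
    out.k = k;
    double s = 0.5 * k, s2 = 0.25 * k;
    out.a = (s / n) * (s / n) / (s2 / n);
    return out;
  }

  auto a_of_k = [&](int k) {
    ensure_sorted(k);
    double th = rs[k - 1];
    long double s = 0.0, s2 = 0.0;  // match R's long-double accumulators
    for (int j = 0; j < k; ++j) {
      double y = 1.0 / (1.0 + std::exp(-2.0 * beta * (rs[j] - th)));
      s += y; s2 += y * y;
    }
    return (double)(((s / n) * (s / n)) / (s2 / n));
  };

  int lo = 1, hi;
  if (a_of_k(1) >= a_target) {
    hi = 1;
  } else {
    hi = 2;
    while (hi < n && a_of_k(hi) < a_target) {
      lo = hi;
      hi = std::min(2 * hi, n);
    }
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (a_of_k(mid) < a_target) lo = mid; else hi = mid;
    }
  }
  int best = lo;
  double besterr = std::fabs(a_of_k(lo) - a_target);
  if (hi != lo) {
    double e2 = std::fabs(a_of_k(hi) - a_target);
    if (e2 < besterr) { best = hi; besterr = e2; }
  }
  if (besterr / a_target > 0.25 && n <= 8192) {
    ensure_sorted(n);
    for (int k = 1; k <= n; ++k) {
      double e = std::fabs(a_of_k(k) - a_target);
      if (e < besterr) { besterr = e; best = k; }
    }
  }
  ensure_sorted(best);
  double th = rs[best - 1];
  long double s = 0.0, s2 = 0.0;
  for (int j = 0; j < best; ++j) {
    double y = 1.0 / (1.0 + std::exp(-2.0 * beta * (rs[j] - th)));
    out.y[ord[j]] = y;
    s += y; s2 += y * y;
  }
  out.k = best;
  out.a = (double)(((s / n) * (s / n)) / (s2 / n));
  return out;
}

}  // namespace

// activations of one layer for one pre-gathered stimulus; shared by the
// compiled kernel and the R reference engine so both accumulate in the
// same order
// [[Rcpp::export]]
NumericVector cpp_activations(NumericMatrix W, NumericMatrix xg) {
  const int n = W.nrow(), nc = W.ncol();
  NumericVector out(n);
  double* r = REAL(out);
  const double* w = W.begin();
  const double* x = xg.begin();
  for (int j = 0; j < nc; ++j) {
    const double* wc = w + (R_xlen_t)n * j;
    const double* xc = x + (R_xlen_t)n * j;
    for (int i = 0; i < n; ++i) r[i] += wc[i] * xc[i];
  }
  return out;
}

// rates for one layer given pre-gathered inputs (stimuli in a list of
// neuron x connection matrices); returns (stimuli x neurons) rate matrix
// [[Rcpp::export]]
NumericMatrix cpp_layer_rates(NumericMatrix W, List X, double a_target,
                              double beta) {
  const int n = W.nrow(), nc = W.ncol(), S = X.size();
  NumericMatrix out(S, n);
  std::vector<double> r(n);
  for (int s = 0; s < S; ++s) {
    NumericMatrix xg = X[s];
    const double* w = W.begin();
    const double* x = xg.begin();
    std::fill(r.begin(), r.end(), 0.0);
    for (int j = 0; j < nc; ++j) {
      const double* wc = w + (R_xlen_t)n * j;
      const double* xc = x + (R_xlen_t)n * j;
      for (int i = 0; i < n; ++i) r[i] += wc[i] * xc[i];
    }
    RateResult rr = rates_from_activations_cpp(r, a_target, beta);
    for (int i = 0; i < n; ++i) out(s, i) = rr.y[i];
  }
  return out;
}

// full epoch loop for one layer; W is modified in place (pass a copy from R)
// rule: 0 = competitive_standard, 1 = oja, 2 = hebb_normalized
// [[Rcpp::export]]
NumericVector cpp_train_layer(NumericMatrix W, List X,
                              IntegerMatrix order_obj,
                              IntegerMatrix order_stim,
                              double a_target, double beta,
                              double lr, double eta, int rule,
                              double max_w, bool has_max,
                              bool use_trace, bool prev_only,
                              bool reset_obj) {
  const int n = W.nrow(), nc = W.ncol();
  const int n_epochs = order_obj.nrow(), P = order_obj.ncol();
  std::vector<double> r(n), trace(n, 0.0), post(n);
  NumericVector history(n_epochs);

  for (int e = 0; e < n_epochs; ++e) {
    std::fill(trace.begin(), trace.end(), 0.0);
    int last_obj = -1;
    double change = 0.0;
    for (int p = 0; p < P; ++p) {
      int obj = order_obj(e, p);
      int s = order_stim(e, p) - 1;
      if (use_trace && reset_obj && obj != last_obj)
        std::fill(trace.begin(), trace.end(), 0.0);
      NumericMatrix xg = X[s];
      const double* wp = W.begin();
      const double* xp = xg.begin();
      std::fill(r.begin(), r.end(), 0.0);
      for (int j = 0; j < nc; ++j) {
        const double* wc = wp + (R_xlen_t)n * j;
        const double* xc = xp + (R_xlen_t)n * j;
        for (int i = 0; i < n; ++i) r[i] += wc[i] * xc[i];
      }
      RateResult rr = rates_from_activations_cpp(r, a_target, beta);
      for (int i = 0; i < n; ++i) {
        if (!use_trace) post[i] = rr.y[i];
        else if (prev_only) post[i] = trace[i];
        else post[i] = (1.0 - eta) * rr.y[i] + eta * trace[i];
      }
      for (int i = 0; i < n; ++i) {
        double yp = post[i];
        double g = lr * yp;
        if (g <= 0.0) continue;
        if (rule == 0) {  // competitive: w += g * (x - w)
          for (int j = 0; j < nc; ++j) {
            double d = g * (xg(i, j) - W(i, j));
            double w2 = W(i, j) + d;
            if (has_max && w2 > max_w) w2 = max_w;
            change += std::fabs(w2 - W(i, j));
            W(i, j) = w2;
          }
        } else if (rule == 1) {  // oja: w += g * (x - yp * w)
          for (int j = 0; j < nc; ++j) {
            double w2 = W(i, j) + g * (xg(i, j) - yp * W(i, j));
            if (has_max && w2 > max_w) w2 = max_w;
            change += std::fabs(w2 - W(i, j));
            W(i, j) = w2;
          }
        } else {  // hebb + explicit normalisation, then clip
          long double norm2 = 0.0;
          for (int j = 0; j < nc; ++j) {
            double w2 = W(i, j) + g * xg(i, j);
            W(i, j) = w2;
            norm2 += (long double)w2 * w2;
          }
          double inv = 1.0 / std::sqrt((double)norm2);
          for (int j = 0; j < nc; ++j) {
            double w2 = W(i, j) * inv;
            if (has_max && w2 > max_w) w2 = max_w;
            W(i, j) = w2;
          }
          change += 1.0;  // bookkeeping only; exact dw tracked by R engine
        }
      }
      if (use_trace)
        for (int i = 0; i < n; ++i)
          trace[i] = (1.0 - eta) * rr.y[i] + eta * trace[i];
      last_obj = obj;
    }
    history[e] = change / ((double)n * nc);
  }
  return history;
}
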
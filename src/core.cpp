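#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Neigh {
  double d;
  int t;     // original time index (1-based), tie-break key
};

inline bool neigh_less(const Neigh& a, const Neigh& b) {
  if (a.d != b.d) return a.d < b.d;
  return a.t < b.t;
}

} // namespace

// Nearest-neighbour cross-map estimator. For each query row of the
// predictor manifold: find the k nearest neighbours by Euclidean distance
// (excluding the query itself and any point within `theiler` samples in
// time, ties broken by smaller time index), weight them by
// u_i = exp(-d_i / d_1) normalised to 1, and average the target series at
// the neighbours' time indices. Zero-distance neighbours (d_1 == 0) get
// uniform weight over the zero-distance set, the continuous limit of the
// weight formula.
// [[Rcpp::export]]
NumericVector crossmap_core(NumericMatrix pts, IntegerVector time_index,
                            NumericVector y, int k, int theiler,
                            IntegerVector query_rows) {
  const int n = pts.nrow(), m = pts.ncol();
  if (k < 2) stop("`k` must be at least 2");
  NumericVector out(query_rows.size());
  std::vector<Neigh> cand;
  cand.reserve(n);
  for (int qi = 0; qi < query_rows.size(); ++qi) {
    const int i = query_rows[qi] - 1;
    if (i < 0 || i >= n) stop("query row out of range");
    cand.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::abs(time_index[j] - time_index[i]) <= theiler) continue;
      double s = 0.0;
      for (int c = 0; c < m; ++c) {
        const double d = pts(i, c) - pts(j, c);
        s += d * d;
      }
      Neigh nb;
      nb.d = std::sqrt(s);
      nb.t = time_index[j];
      cand.push_back(nb);
    }
    if ((int)cand.size() < k)
      stop("not enough neighbour candidates: k too large for this manifold");
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end(), neigh_less);
    const double d1 = cand[0].d;
    double est = 0.0;
    if (d1 == 0.0) {
      int nz = 0;
      for (int j = 0; j < k; ++j)
        if (cand[j].d == 0.0) { est += y[cand[j].t - 1]; ++nz; }
      est /= nz;
    } else {
      double su = 0.0, sy = 0.0;
      for (int j = 0; j < k; ++j) {
        const double u = std::exp(-cand[j].d / d1);
        su += u;
        sy += u * y[cand[j].t - 1];
      }
      est = sy / su;
    }
    out[qi] = est;
  }
  return out;
}

// False-nearest-neighbour fractions for m = 1..m_max (Kennel criteria).
// Forward-lag windows: the point starting at t has coordinates
// x[t + j*tau], j = 0..m-1, and the unfolding test uses the forward
// coordinate x[t + m*tau]. The forward direction matters: for a
// non-invertible map the backward coordinate (a preimage) is multivalued,
// which would leave the false-neighbour fraction permanently high. The
// point set itself is identical to the backward-lag shadow manifold up to
// a coordinate permutation. sigma is the series standard deviation
// (attractor size).
// [[Rcpp::export]]
NumericVector fnn_core(NumericVector x, int tau, int m_max,
                       double Rtol, double Atol) {
  const int N = x.size();
  double mu = 0.0;
  for (int i = 0; i < N; ++i) mu += x[i];
  mu /= N;
  double sig = 0.0;
  for (int i = 0; i < N; ++i) sig += (x[i] - mu) * (x[i] - mu);
  sig = std::sqrt(sig / (N - 1));
  NumericVector frac(m_max);
  for (int m = 1; m <= m_max; ++m) {
    const int last = N - m * tau;  // 0-based; ensures x[t + m*tau] exists
    if (last < 2) { frac[m - 1] = NA_REAL; continue; }
    // neighbours closer than numerical resolution (exact revisits of a
    // periodic orbit) carry no unfolding information and are skipped
    const double eps2 = 1e-16 * sig * sig;
    int n_false = 0, n_tot = 0;
    for (int t = 0; t < last; ++t) {
      double best = R_PosInf;
      int bs = -1;
      for (int s = 0; s < last; ++s) {
        if (s == t) continue;
        double d2 = 0.0;
        for (int j = 0; j < m; ++j) {
          const double dd = x[t + j * tau] - x[s + j * tau];
          d2 += dd * dd;
          if (d2 >= best) break;
        }
        if (d2 < best && d2 > eps2) { best = d2; bs = s; }
      }
      if (bs < 0) continue;
      const double Rm = std::sqrt(best);
      const double extra = std::fabs(x[t + m * tau] - x[bs + m * tau]);
      const bool is_false = (extra / Rm > Rtol) ||
          (std::sqrt(Rm * Rm + extra * extra) / sig > Atol);
      if (is_false) ++n_false;
      ++n_tot;
    }
    if (n_tot == 0) { frac[m - 1] = NA_REAL; continue; }
    frac[m - 1] = (double)n_false / n_tot;
  }
  return frac;
}
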
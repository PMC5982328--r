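#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Classic dynamic-time-warping accumulated cost between two univariate
// series.  Local cost |a_i - b_j| (L1), symmetric unit-weight steps
// {(1,0),(0,1),(1,1)}, endpoints anchored, optional Sakoe-Chiba band.
//
// The unconstrained path uses a single rolling row with register
// carries for the left/diagonal cells; O(min-row) memory, no branches
// in the inner loop.  window < 0 means unconstrained; a finite window
// is widened to at least |n - m| so the corner-to-corner path stays
// feasible.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b, int window = -1) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw_cost: empty series");
  const double *av = REAL(a), *bv = REAL(b);

  if (window < 0) {
    std::vector<double> row(m);
    double acc = 0.0;
    for (int j = 0; j < m; ++j) {
      acc += std::fabs(av[0] - bv[j]);
      row[j] = acc;
    }
    for (int i = 1; i < n; ++i) {
      const double ai = av[i];
      double diag = row[0];                    // D[i-1][j-1]
      row[0] += std::fabs(ai - bv[0]);         // D[i][0]
      double left = row[0];                    // D[i][j-1]
      for (int j = 1; j < m; ++j) {
        const double up = row[j];              // D[i-1][j]
        double best = up < left ? up : left;
        if (diag < best) best = diag;
        const double v = std::fabs(ai - bv[j]) + best;
        row[j] = v;
        left = v;
        diag = up;
      }
    }
    return row[m - 1];
  }

  // banded variant
  int w = window;
  if (w < std::abs(n - m)) w = std::abs(n - m);
  const double INF = R_PosInf;
  std::vector<double> prev(m, INF), cur(m, INF);
  for (int j = 0; j <= std::min(m - 1, w); ++j) {
    double c = std::fabs(av[0] - bv[j]);
    prev[j] = (j == 0) ? c : prev[j - 1] + c;
  }
  for (int i = 1; i < n; ++i) {
    const int jlo = std::max(0, i - w), jhi = std::min(m - 1, i + w);
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::fabs(av[i] - bv[j]);
      double best = prev[j];
      if (j > 0) {
        if (cur[j - 1] < best) best = cur[j - 1];
        if (prev[j - 1] < best) best = prev[j - 1];
      }
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// The five stride distances of one probe against a whole gallery in a
// single call: phase distances (MSt, TSt) x (L, R) summed over the
// three force components, plus the six-alignment whole-stride
// distance.  'probe' and each gallery element are lists of 18 numeric
// vectors laid out as (fx,fy,fz) x (L,R) x (MSt,TSt,full), i.e. for
// each of the 6 component/limb series its MSt fragment, TSt fragment
// and full stance.
// [[Rcpp::export]]
NumericMatrix dtw_profile_cpp(List probe, List gallery, int window = -1) {
  const int G = gallery.size();
  NumericMatrix out(G, 5);
  std::vector<NumericVector> pv(18);
  for (int q = 0; q < 18; ++q) pv[q] = as<NumericVector>(probe[q]);
  for (int g = 0; g < G; ++g) {
    List gp = gallery[g];
    double acc[5] = {0, 0, 0, 0, 0};
    for (int limb = 0; limb < 2; ++limb) {
      for (int comp = 0; comp < 3; ++comp) {
        const int base = (limb * 3 + comp) * 3;
        acc[limb * 2 + 0] += dtw_cost_cpp(pv[base + 0], gp[base + 0], window);
        acc[limb * 2 + 1] += dtw_cost_cpp(pv[base + 1], gp[base + 1], window);
        acc[4] += dtw_cost_cpp(pv[base + 2], gp[base + 2], window);
      }
    }
    for (int k = 0; k < 5; ++k) out(g, k) = acc[k];
  }
  return out;
}
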
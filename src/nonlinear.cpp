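#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Higuchi curve lengths L(k) for k = 1..kmax. The fractal dimension is the
// negative slope of log L(k) against log k, fitted in R.
// [[Rcpp::export]]
NumericVector higuchi_lengths(NumericVector x, int kmax) {
  int n = x.size();
  NumericVector L(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    for (int m = 0; m < k; ++m) {
      int nseg = (n - 1 - m) / k;
      if (nseg < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= nseg; ++i)
        s += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      Lk += s * (double)(n - 1) / ((double)nseg * k * k);
    }
    L[k - 1] = Lk / k;
  }
  return L;
}

// Mean rescaled range R/S over non-overlapping blocks, one value per
// window size (NaN when every block is constant).
// [[Rcpp::export]]
NumericVector rs_means(NumericVector x, IntegerVector sizes) {
  int n = x.size();
  NumericVector out(sizes.size(), NA_REAL);
  for (int si = 0; si < sizes.size(); ++si) {
    int w = sizes[si];
    int nb = n / w;
    double acc = 0.0; int cnt = 0;
    for (int b = 0; b < nb; ++b) {
      const double *z = &x[b * w];
      double mu = 0.0;
      for (int i = 0; i < w; ++i) mu += z[i];
      mu /= w;
      double ss = 0.0, cum = 0.0, mx = R_NegInf, mn = R_PosInf;
      for (int i = 0; i < w; ++i) {
        double d = z[i] - mu;
        ss += d * d;
        cum += d;
        if (cum > mx) mx = cum;
        if (cum < mn) mn = cum;
      }
      double s = std::sqrt(ss / (w - 1));
      if (s < 1e-300) continue;
      acc += (mx - mn) / s;
      cnt++;
    }
    if (cnt > 0) out[si] = acc / cnt;
  }
  return out;
}

// Rosenstein largest-Lyapunov divergence curve: mean log nearest-neighbour
// separation over 0..fit_steps steps. Reference points are strided so at
// most max_ref are used; neighbour candidates are all delay vectors more
// than `theiler` samples away. Returns fit_steps+1 values (NA where no
// pair had positive separation).
// [[Rcpp::export]]
NumericVector lyap_divergence(NumericVector x, int m, int tau, int theiler,
                              int fit_steps, int max_ref) {
  int n = x.size();
  int M = n - (m - 1) * tau;            // number of delay vectors
  int Mf = M - fit_steps;               // last usable start index (excl.)
  NumericVector out(fit_steps + 1, NA_REAL);
  if (Mf < 2) return out;
  int stride = (Mf + max_ref - 1) / max_ref;
  if (stride < 1) stride = 1;
  // prune the neighbour search with the window-sum projection: by
  // Cauchy-Schwarz, dist^2(i,j) >= (sum_i - sum_j)^2 / m, so after sorting
  // by window sum the scan on each side can stop once the bound exceeds
  // the best distance found.
  std::vector<double> wsum(Mf);
  for (int i = 0; i < Mf; ++i) {
    double s = 0.0;
    for (int e = 0; e < m; ++e) s += x[i + e * tau];
    wsum[i] = s;
  }
  std::vector<int> order(Mf);
  for (int i = 0; i < Mf; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return wsum[a] < wsum[b]; });
  std::vector<int> pos(Mf);
  for (int i = 0; i < Mf; ++i) pos[order[i]] = i;
  std::vector<double> acc(fit_steps + 1, 0.0);
  std::vector<int> cnt(fit_steps + 1, 0);
  for (int i = 0; i < Mf; i += stride) {
    double best = R_PosInf;
    int bj = -1;
    int pi = pos[i];
    for (int side = 0; side < 2; ++side) {
      int step = side == 0 ? -1 : 1;
      for (int t = pi + step; t >= 0 && t < Mf; t += step) {
        int j = order[t];
        double ds = wsum[i] - wsum[j];
        if (ds * ds / m >= best) break;
        if (std::abs(i - j) <= theiler) continue;
        double d = 0.0;
        for (int e = 0; e < m; ++e) {
          double dd = x[i + e * tau] - x[j + e * tau];
          d += dd * dd;
          if (d >= best) break;
        }
        if (d < best && d > 0.0) { best = d; bj = j; }
      }
    }
    if (bj < 0) continue;
    for (int k = 0; k <= fit_steps; ++k) {
      double d = 0.0;
      for (int e = 0; e < m; ++e) {
        double dd = x[i + k + e * tau] - x[bj + k + e * tau];
        d += dd * dd;
      }
      if (d > 0.0) { acc[k] += 0.5 * std::log(d); cnt[k]++; }
    }
  }
  for (int k = 0; k <= fit_steps; ++k)
    if (cnt[k] > 0) out[k] = acc[k] / cnt[k];
  return out;
}
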
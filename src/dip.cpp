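#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Hartigan-Hartigan dip statistic of a sample: the sup-norm distance between
// the empirical CDF and the closest unimodal CDF.  A unimodal CDF is convex
// left of its mode and concave right of it (an atom at the mode is allowed).
//
// For sorted distinct values z_t with ECDF levels bot_t (just below z_t) and
// top_t (at z_t), a band of half-width d admits a convex piece over the
// prefix 1..t iff 2d >= A(t), where A(t) is the largest gap between the
// ECDF's upper levels and the greatest convex minorant H of its lower
// levels; a concave piece over the suffix t..K is the mirror image (B(t),
// least concave majorant L of the upper levels against the lower levels).
// Placing the mode at z_t relaxes the local gate (A'(t), B'(t)), and joining
// the two pieces monotonically adds the junction condition
// 2d >= A + B - (ECDF jump across the mode).  The dip is half the minimum
// over all mode placements.

struct HullEval {
  // incremental lower (or, by sign flip, upper) convex hull over points
  // (z[i], y[i]) added left to right; eval() walks hull values for
  // consecutive queries
  std::vector<double> hx, hy;
  void add(double x, double y) {
    size_t k;
    while ((k = hx.size()) >= 2) {
      double cross = (hx[k-1] - hx[k-2]) * (y - hy[k-2]) -
                     (x - hx[k-2]) * (hy[k-1] - hy[k-2]);
      if (cross <= 0) { hx.pop_back(); hy.pop_back(); } else break;
    }
    // equal x: keep the lower point (points arrive with nondecreasing y,
    // so the earlier one is the hull point)
    if (!hx.empty() && hx.back() == x) return;
    hx.push_back(x); hy.push_back(y);
  }
  double eval(double x, size_t &seg) const {
    if (hx.size() == 1) return hy[0];
    while (seg + 2 < hx.size() && hx[seg + 1] <= x) ++seg;
    double x0 = hx[seg], x1 = hx[seg + 1], y0 = hy[seg], y1 = hy[seg + 1];
    if (x1 == x0) return std::min(y0, y1);
    return y0 + (y1 - y0) * (x - x0) / (x1 - x0);
  }
};

// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(NumericVector x) {
  int n = x.size();
  if (n < 1) stop("empty sample");
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  // collapse ties
  std::vector<double> z;
  std::vector<double> bot, top;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    z.push_back(xs[i]);
    bot.push_back((double)i / n);
    top.push_back((double)j / n);
    i = j;
  }
  int K = (int)z.size();
  if (K == 1) return 0.0;

  // left pass: A[t] (full gates 1..t), Ap[t] (mode at z_t)
  std::vector<double> A(K), Ap(K);
  {
    HullEval h;
    for (int t = 0; t < K; ++t) {
      h.add(z[t], bot[t]);
      double maxFull = 0.0, maxPrev = 0.0;
      size_t seg = 0;
      for (int s = 0; s <= t; ++s) {
        double hv = h.eval(z[s], seg);
        double dev = top[s] - hv;
        if (s < t && dev > maxPrev) maxPrev = dev;
        if (dev > maxFull) maxFull = dev;
      }
      A[t] = maxFull;
      Ap[t] = maxPrev; // gap at t itself is bot[t]-H(z_t)=0
    }
  }
  // right pass: B[t] (full gates t..K), Bp[t] (mode at z_t); mirror by
  // negating coordinates so the upper concave hull becomes a lower hull
  std::vector<double> B(K), Bp(K);
  {
    HullEval h;
    for (int t = K - 1; t >= 0; --t) {
      h.add(-z[t], -top[t]);
      double maxFull = 0.0, maxPrev = 0.0;
      size_t seg = 0;
      for (int s = K - 1; s >= t; --s) {  // -z[s] increases as s decreases
        double hv = -h.eval(-z[s], seg);
        double dev = hv - bot[s];
        if (s > t && dev > maxPrev) maxPrev = dev;
        if (dev > maxFull) maxFull = dev;
      }
      B[t] = maxFull;
      Bp[t] = maxPrev;
    }
  }
  double best = std::min(B[0], A[K - 1]); // mode before / after all data
  for (int t = 0; t < K - 1; ++t) {       // mode between z_t and z_{t+1}
    double v = std::max(A[t], B[t + 1]);
    double junction = A[t] + B[t + 1] - (top[t + 1] - bot[t]);
    if (junction > v) v = junction;
    if (v < best) best = v;
  }
  for (int t = 0; t < K; ++t) {           // mode at z_t
    double v = std::max(Ap[t], Bp[t]);
    double junction = Ap[t] + Bp[t] - (top[t] - bot[t]);
    if (junction > v) v = junction;
    if (v < best) best = v;
  }
  return best / 2.0;
}
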
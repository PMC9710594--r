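#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// Test points on each atom's solvent sphere (radius + probe) from a golden-
// section spiral (deterministic); a point is accessible if outside every
// neighbour's solvent sphere. SASA_i = accessible fraction * sphere area.
// [[Rcpp::export]]
NumericVector sasa_shrake_rupley(NumericMatrix coords, NumericVector radii,
                                 double probe = 1.4, int n_points = 960) {
  const int n = coords.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  // unit sphere points, golden spiral
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    px[k] = r * std::cos(th); py[k] = r * std::sin(th); pz[k] = zk;
  }

  std::vector<double> R(n);
  double maxR = 0.0;
  for (int i = 0; i < n; ++i) { R[i] = radii[i] + probe; maxR = std::max(maxR, R[i]); }

  // neighbour lists by all-pairs scan (n is a few thousand at most),
  // sorted near-to-far so buried points are rejected early
  std::vector<std::vector<std::pair<double,int>>> nb(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i,0) - coords(j,0), dy = coords(i,1) - coords(j,1),
             dz = coords(i,2) - coords(j,2);
      double lim = R[i] + R[j];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < lim*lim) {
        nb[i].push_back(std::make_pair(d2, j));
        nb[j].push_back(std::make_pair(d2, i));
      }
    }
  }
  for (int i = 0; i < n; ++i) std::sort(nb[i].begin(), nb[i].end());

  for (int i = 0; i < n; ++i) {
    const double Ri = R[i];
    int acc = 0;
    const std::vector<std::pair<double,int>>& nbi = nb[i];
    int last = -1;  // neighbour that buried the previous point: try it first
    for (int k = 0; k < n_points; ++k) {
      const double qx = coords(i,0) + Ri * px[k];
      const double qy = coords(i,1) + Ri * py[k];
      const double qz = coords(i,2) + Ri * pz[k];
      bool buried = false;
      if (last >= 0) {
        double dx = qx - coords(last,0), dy = qy - coords(last,1),
               dz = qz - coords(last,2);
        buried = dx*dx + dy*dy + dz*dz < R[last]*R[last];
      }
      for (size_t t = 0; !buried && t < nbi.size(); ++t) {
        int j = nbi[t].second;
        if (j == last) continue;
        double dx = qx - coords(j,0), dy = qy - coords(j,1), dz = qz - coords(j,2);
        if (dx*dx + dy*dy + dz*dz < R[j]*R[j]) { buried = true; last = j; }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)n_points;
  }
  return out;
}
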
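#include <Rcpp.h>
using namespace Rcpp;

// Full forward evaluation of the measured compartment-model TAC.
// Builds the evaluation grid (frame boundaries + shifted input knots +
// fine sampling of the smooth tail), evaluates the piecewise-linear input,
// propagates every exponential mode exactly, and returns frame averages of
// vb * C_wb + (1 - vb) * sum_m B[m] * y_m.
//
// Input evaluation at time t (grid time): s = t - td;
//   s <= 0                 -> 0
//   s <= last knot         -> linear interpolation on (kt, ky)
//   s <= margin (no tail)  -> linear continuation of the last segment, >= 0
//   beyond, tail fitted    -> A1 exp(-lam1 s) + A2 exp(-lam2 s)
// [[Rcpp::export(name = ".forward_cpp")]]
NumericVector forward_cpp(NumericVector fstart, NumericVector fend,
                          NumericVector kt, NumericVector ky,
                          double td, bool use_tail,
                          double A1, double lam1, double A2, double lam2,
                          double margin,
                          NumericVector theta, NumericVector B, double vb) {
  const int nf = fstart.size(), nk = kt.size(), m = theta.size();
  const double t_end = fend[nf - 1];
  const double last_knot = kt[nk - 1];

  std::vector<double> grid;
  grid.reserve(2 * nf + nk + 32);
  grid.push_back(0.0);
  for (int i = 0; i < nf; ++i) {
    grid.push_back(fstart[i]);
    grid.push_back(fend[i]);
  }
  for (int i = 0; i < nk; ++i) {
    double t = kt[i] + td;
    if (t > 0.0 && t < t_end) grid.push_back(t);
  }
  double shifted_last = last_knot + td;
  if (t_end > shifted_last + 1e-12) {
    for (double t = std::max(shifted_last, 0.0); t < t_end; t += 0.25)
      grid.push_back(t);
  }
  std::sort(grid.begin(), grid.end());
  grid.erase(std::unique(grid.begin(), grid.end()), grid.end());
  while (!grid.empty() && grid.front() < 0.0) grid.erase(grid.begin());
  const int n = grid.size();

  // input values on the grid (two-pointer interpolation; grid is sorted)
  std::vector<double> u(n);
  int j = 0;
  for (int i = 0; i < n; ++i) {
    double s = grid[i] - td;
    if (s <= 0.0) { u[i] = 0.0; continue; }
    if (s <= last_knot) {
      while (j + 1 < nk && kt[j + 1] < s) ++j;
      // kt[j] <= s <= kt[j+1] after the sweep (kt[0] == 0 by construction)
      int jj = j;
      while (jj + 1 < nk && kt[jj + 1] < s) ++jj;
      double t0 = kt[jj], t1 = kt[jj + 1];
      u[i] = ky[jj] + (ky[jj + 1] - ky[jj]) * (s - t0) / (t1 - t0);
    } else if (use_tail) {
      u[i] = A1 * std::exp(-lam1 * s) + A2 * std::exp(-lam2 * s);
    } else {
      if (s > margin + 1e-9)
        stop("input evaluation beyond measured range and no tail fitted");
      double slope = (ky[nk - 1] - ky[nk - 2]) / (kt[nk - 1] - kt[nk - 2]);
      u[i] = std::max(ky[nk - 1] + slope * (s - last_knot), 0.0);
    }
  }

  // cumulative integrals of u and of each mode response at grid points
  std::vector<double> cumU(n, 0.0);
  std::vector<double> cumQ(n * m, 0.0);
  std::vector<double> y(m, 0.0);
  for (int i = 0; i + 1 < n; ++i) {
    const double d = grid[i + 1] - grid[i];
    const double u0 = u[i];
    const double slope = (u[i + 1] - u0) / d;
    const double useg = 0.5 * (u[i] + u[i + 1]) * d;
    cumU[i + 1] = cumU[i] + useg;
    for (int k = 0; k < m; ++k) {
      const double th = theta[k];
      const double x = th * d;
      double y1, q;
      if (x > 1e-5) {
        const double E = std::exp(-x);
        const double g1 = (1.0 - E) / th;
        const double g2 = (d - g1) / th;
        y1 = y[k] * E + u0 * g1 + slope * g2;
        q = (y[k] - y1 + useg) / th;
      } else {
        y1 = y[k] * (1.0 - x + 0.5 * x * x)
           + u0 * d * (1.0 - 0.5 * x)
           + slope * d * d * (0.5 - x / 6.0);
        q = y[k] * d + u0 * d * d / 2.0 + slope * d * d * d / 6.0
          - th * (y[k] * d * d / 2.0 + u0 * d * d * d / 6.0
                  + slope * d * d * d * d / 24.0);
      }
      cumQ[(i + 1) * m + k] = cumQ[i * m + k] + q;
      y[k] = y1;
    }
  }

  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = std::lower_bound(grid.begin(), grid.end(), fstart[f]) -
      grid.begin();
    int i1 = std::lower_bound(grid.begin(), grid.end(), fend[f]) -
      grid.begin();
    if (i0 >= n || i1 >= n || grid[i0] != fstart[f] || grid[i1] != fend[f])
      stop("internal grid error");
    const double dur = fend[f] - fstart[f];
    double tis = 0.0;
    for (int k = 0; k < m; ++k)
      tis += B[k] * (cumQ[i1 * m + k] - cumQ[i0 * m + k]);
    out[f] = vb * (cumU[i1] - cumU[i0]) / dur + (1.0 - vb) * tis / dur;
  }
  return out;
}
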
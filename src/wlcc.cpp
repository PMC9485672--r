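#include <Rcpp.h>
using namespace Rcpp;

// Windowed lagged Pearson cross-correlation between two equal-length series.
//
// Windows are non-overlapping blocks of `W` samples on a common grid; for a
// lag `l` in [-L, L] the later-starting member's window is shifted by |l|
// samples into the adjacent segment so every correlation uses full-length
// vectors.  Anchoring the earlier-starting window on the grid makes the
// result exactly symmetric under member swap + lag negation.  Cells whose
// shifted window would run past the end of the recording are NA; windows
// with (numerically) zero variance are flagged degenerate and scored r = 0.
//
// x, y must already be globally centered by the caller (cancellation guard).
// [[Rcpp::export(name = ".wlcc_core")]]
List wlcc_core(NumericVector x, NumericVector y, int W, int L, double rel_tol) {
  const int N = x.size();
  if (y.size() != N) stop("series lengths differ");
  const int n_win = N / W;
  const int n_lag = 2 * L + 1;

  std::vector<double> cx(N + 1, 0.0), cx2(N + 1, 0.0);
  std::vector<double> cy(N + 1, 0.0), cy2(N + 1, 0.0);
  for (int t = 0; t < N; ++t) {
    cx[t + 1]  = cx[t]  + x[t];
    cx2[t + 1] = cx2[t] + x[t] * x[t];
    cy[t + 1]  = cy[t]  + y[t];
    cy2[t + 1] = cy2[t] + y[t] * y[t];
  }

  NumericMatrix r(n_win, n_lag);
  LogicalMatrix deg(n_win, n_lag);

  for (int w = 0; w < n_win; ++w) {
    const int s = w * W;
    for (int j = 0; j < n_lag; ++j) {
      const int l = j - L;
      const int a = s + (l < 0 ? -l : 0);  // x-window start
      const int b = s + (l > 0 ?  l : 0);  // y-window start
      if ((a > b ? a : b) + W > N) {
        r(w, j) = NA_REAL;
        continue;
      }
      double cross = 0.0;
      for (int t = 0; t < W; ++t) cross += x[a + t] * y[b + t];
      const double Sx  = cx[a + W]  - cx[a];
      const double Sx2 = cx2[a + W] - cx2[a];
      const double Sy  = cy[b + W]  - cy[b];
      const double Sy2 = cy2[b + W] - cy2[b];
      const double vx = W * Sx2 - Sx * Sx;
      const double vy = W * Sy2 - Sy * Sy;
      if (vx <= rel_tol * W * Sx2 || vy <= rel_tol * W * Sy2) {
        r(w, j) = 0.0;
        deg(w, j) = true;
        continue;
      }
      r(w, j) = (W * cross - Sx * Sy) / std::sqrt(vx * vy);
    }
  }

  return List::create(_["r"] = r, _["degenerate"] = deg);
}
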
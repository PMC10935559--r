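// Closest-point Newton iteration on a bivariate polynomial height field,
// the hot path of the analytic contact backend. The surface is given in its
// centered/scaled monomial basis; queries are in the surface frame.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void eval2(const double* cf, const int* ei, const int* ej, int nterm,
                  int order, double cx, double cy, double sx, double sy,
                  double x, double y, double* out) {
  double xp[16], yp[16];
  double xs = (x - cx) / sx, ys = (y - cy) / sy;
  xp[0] = 1; yp[0] = 1;
  for (int k = 1; k <= order; ++k) {
    xp[k] = xp[k - 1] * xs;
    yp[k] = yp[k - 1] * ys;
  }
  double f = 0, fx = 0, fy = 0, fxx = 0, fxy = 0, fyy = 0;
  for (int k = 0; k < nterm; ++k) {
    int i = ei[k], j = ej[k];
    double c = cf[k];
    f += c * xp[i] * yp[j];
    if (i > 0) fx += c * i * xp[i - 1] * yp[j];
    if (j > 0) fy += c * j * xp[i] * yp[j - 1];
    if (i > 1) fxx += c * i * (i - 1) * xp[i - 2] * yp[j];
    if (i > 0 && j > 0) fxy += c * i * j * xp[i - 1] * yp[j - 1];
    if (j > 1) fyy += c * j * (j - 1) * xp[i] * yp[j - 2];
  }
  out[0] = f;
  out[1] = fx / sx;
  out[2] = fy / sy;
  out[3] = fxx / (sx * sx);
  out[4] = fxy / (sx * sy);
  out[5] = fyy / (sy * sy);
}

// [[Rcpp::export]]
NumericVector cpp_surface_eval2(NumericVector cf, IntegerVector ei,
                                IntegerVector ej, int order, double cx,
                                double cy, double sx, double sy, double x,
                                double y) {
  double out[6];
  eval2(cf.begin(), ei.begin(), ej.begin(), cf.size(), order, cx, cy, sx, sy,
        x, y, out);
  return NumericVector(out, out + 6);
}

// Multi-start damped Newton for min ||(s,t,f(s,t)) - c||^2.
// Returns c(s, t, g2, d2) of the best stationary point found.
// [[Rcpp::export]]
NumericVector cpp_closest_multistart(NumericVector cf, IntegerVector ei,
                                     IntegerVector ej, int order, double cx,
                                     double cy, double sx, double sy,
                                     NumericVector cl, NumericMatrix seeds,
                                     double damp_len) {
  double best_s = NA_REAL, best_t = NA_REAL, best_g2 = R_PosInf,
         best_d2 = R_PosInf;
  int nterm = cf.size();
  double out[6];
  for (int ks = 0; ks < seeds.nrow(); ++ks) {
    double s = seeds(ks, 0), t = seeds(ks, 1);
    for (int it = 0; it < 40; ++it) {
      eval2(cf.begin(), ei.begin(), ej.begin(), nterm, order, cx, cy, sx, sy,
            s, t, out);
      double r = out[0] - cl[2];
      double g1 = (s - cl[0]) + r * out[1];
      double g2v = (t - cl[1]) + r * out[2];
      double h11 = 1 + out[1] * out[1] + r * out[3];
      double h12 = out[1] * out[2] + r * out[4];
      double h22 = 1 + out[2] * out[2] + r * out[5];
      double det = h11 * h22 - h12 * h12;
      if (!std::isfinite(det) || std::fabs(det) < 1e-300) break;
      double ds = (h22 * g1 - h12 * g2v) / det;
      double dt = (h11 * g2v - h12 * g1) / det;
      double sl = std::sqrt(ds * ds + dt * dt);
      double sc = sl > damp_len ? sl / damp_len : 1.0;
      s -= ds / sc;
      t -= dt / sc;
      if (sl / sc < 1e-13) break;
    }
    eval2(cf.begin(), ei.begin(), ej.begin(), nterm, order, cx, cy, sx, sy, s,
          t, out);
    double r = out[0] - cl[2];
    double g1 = (s - cl[0]) + r * out[1];
    double g2v = (t - cl[1]) + r * out[2];
    double gg = g1 * g1 + g2v * g2v;
    double d2 = (s - cl[0]) * (s - cl[0]) + (t - cl[1]) * (t - cl[1]) + r * r;
    if (d2 < best_d2) {
      best_d2 = d2;
      best_g2 = gg;
      best_s = s;
      best_t = t;
    }
  }
  return NumericVector::create(best_s, best_t, best_g2, best_d2);
}
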
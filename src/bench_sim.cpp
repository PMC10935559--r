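// Fast path for the standard bench simulation: one free rigid body (the
// patella) under gravity, two spring-damper tendons anchored on guided
// bodies, and one sphere-versus-polynomial-surface Flores contact.
// Newmark (gamma, beta) with Newton on the 6 accelerations; guided-body
// data are precomputed per substep in R. Mirrors the generic R stepper
// (step_model); agreement between the two is covered by tests.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

static inline void quat_to_R(const double* q, double R[9]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}
static inline void quat_mul(const double* a, const double* b, double* o) {
  o[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  o[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  o[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  o[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}
static inline void quat_exp(const double* th, double* q) {
  double a = std::sqrt(th[0] * th[0] + th[1] * th[1] + th[2] * th[2]);
  if (a < 1e-14) {
    q[0] = 1; q[1] = th[0] / 2; q[2] = th[1] / 2; q[3] = th[2] / 2;
  } else {
    double s = std::sin(a / 2) / a;
    q[0] = std::cos(a / 2); q[1] = s * th[0]; q[2] = s * th[1]; q[3] = s * th[2];
  }
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= n;
}
static inline void cross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

struct Surf {
  const double* cf; const int* ei; const int* ej; int n, order;
  double cx, cy, sx, sy, lox, hix, loy, hiy;
};

static void surf_eval(const Surf& S, double x, double y, double* out) {
  double xp[16], yp[16];
  double xs = (x - S.cx) / S.sx, ys = (y - S.cy) / S.sy;
  xp[0] = yp[0] = 1;
  for (int k = 1; k <= S.order; ++k) {
    xp[k] = xp[k - 1] * xs;
    yp[k] = yp[k - 1] * ys;
  }
  double f = 0, fx = 0, fy = 0;
  for (int k = 0; k < S.n; ++k) {
    int i = S.ei[k], j = S.ej[k];
    double c = S.cf[k];
    f += c * xp[i] * yp[j];
    if (i > 0) fx += c * i * xp[i - 1] * yp[j];
    if (j > 0) fy += c * j * xp[i] * yp[j - 1];
  }
  out[0] = f; out[1] = fx / S.sx; out[2] = fy / S.sy;
}

// Newton closest point; returns true if interior converged, s/t updated.
static bool surf_closest(const Surf& S, const double* cl, double& s,
                         double& t) {
  double damp = 0.25 * std::max(S.hix - S.lox, S.hiy - S.loy);
  for (int pass = 0; pass < 2; ++pass) {
    double s0 = pass == 0 ? s : cl[0], t0 = pass == 0 ? t : cl[1];
    for (int it = 0; it < 40; ++it) {
      double xp[16], yp[16];
      double xs = (s0 - S.cx) / S.sx, ys = (t0 - S.cy) / S.sy;
      xp[0] = yp[0] = 1;
      for (int k = 1; k <= S.order; ++k) {
        xp[k] = xp[k - 1] * xs;
        yp[k] = yp[k - 1] * ys;
      }
      double f = 0, fx = 0, fy = 0, fxx = 0, fxy = 0, fyy = 0;
      for (int k = 0; k < S.n; ++k) {
        int i = S.ei[k], j = S.ej[k];
        double c = S.cf[k];
        f += c * xp[i] * yp[j];
        if (i > 0) fx += c * i * xp[i - 1] * yp[j];
        if (j > 0) fy += c * j * xp[i] * yp[j - 1];
        if (i > 1) fxx += c * i * (i - 1) * xp[i - 2] * yp[j];
        if (i > 0 && j > 0) fxy += c * i * j * xp[i - 1] * yp[j - 1];
        if (j > 1) fyy += c * j * (j - 1) * xp[i] * yp[j - 2];
      }
      fx /= S.sx; fy /= S.sy;
      fxx /= S.sx * S.sx; fxy /= S.sx * S.sy; fyy /= S.sy * S.sy;
      double r = f - cl[2];
      double g1 = (s0 - cl[0]) + r * fx;
      double g2 = (t0 - cl[1]) + r * fy;
      double h11 = 1 + fx * fx + r * fxx;
      double h12 = fx * fy + r * fxy;
      double h22 = 1 + fy * fy + r * fyy;
      double det = h11 * h22 - h12 * h12;
      if (!std::isfinite(det) || std::fabs(det) < 1e-300) break;
      double ds = (h22 * g1 - h12 * g2) / det;
      double dt = (h11 * g2 - h12 * g1) / det;
      double sl = std::sqrt(ds * ds + dt * dt);
      double sc = sl > damp ? sl / damp : 1.0;
      s0 -= ds / sc; t0 -= dt / sc;
      if (sl / sc < 1e-13) break;
    }
    if (s0 > S.lox && s0 < S.hix && t0 > S.loy && t0 < S.hiy) {
      s = s0; t = t0;
      return true;
    }
    if (pass == 1) { s = s0; t = t0; }
  }
  return false;
}

struct Ctx {
  double mass, g[3];
  double Jd[3];                    // diagonal body inertia
  double crot;                     // rotational viscous damping
  // springs (tendon strap strands), each anchored on a guided body
  int n_spr;
  std::vector<double> K, L0, C;
  std::vector<std::array<double, 3>> attach;  // patella-local attachments
  std::vector<int> group;                     // load-cell channel (0/1)
  double sc_local[3], radius;      // sphere center (patella frame), radius
  double kn, pexp, eps;
  Surf S;
  // per-substep guided data (row per substep)
  std::vector<const double*> anchor;    // n x 3 world anchor positions
  std::vector<const double*> anchor_v;  // n x 3 world anchor velocities
  const double* fem_x; const double* fem_q;  // n x 3, n x 4 femur pose
  const double* fem_v; const double* fem_w;  // n x 3 world lin, n x 3 body ang
  int nrow;
  // contact episode state
  bool ep_active; double ep_dd0;
  double warm_s, warm_t; bool warm_ok;
};

// force/torque on the patella at substep row k, pose (x,q), twist (v,w).
// out: F[3], T[3] (body frame); also reports tensions, contact info.
struct ForceOut {
  double F[3], T[3], ten[2], Fmag, delta, delta_dot, pt[3], nrm[3];
  bool contact;
};

// guided data at fractional row position rpos in [0, nrow-1]
struct Guided {
  std::vector<std::array<double, 3>> anchor, anchor_v;
  double fem_x[3], fem_q[4], fem_v[3], fem_w[3];
};

static void guided_at(const Ctx& cx, double rpos, Guided& g) {
  int k0 = (int)std::floor(rpos);
  if (k0 < 0) k0 = 0;
  if (k0 > cx.nrow - 1) k0 = cx.nrow - 1;
  int k1 = std::min(k0 + 1, cx.nrow - 1);
  double w1 = rpos - k0;
  if (w1 < 0) w1 = 0;
  if (w1 > 1) w1 = 1;
  double w0 = 1 - w1;
  g.anchor.resize(cx.n_spr);
  g.anchor_v.resize(cx.n_spr);
  for (int sidx = 0; sidx < cx.n_spr; ++sidx)
    for (int d = 0; d < 3; ++d) {
      g.anchor[sidx][d] = w0 * cx.anchor[sidx][k0 + cx.nrow * d] +
                          w1 * cx.anchor[sidx][k1 + cx.nrow * d];
      g.anchor_v[sidx][d] = w0 * cx.anchor_v[sidx][k0 + cx.nrow * d] +
                            w1 * cx.anchor_v[sidx][k1 + cx.nrow * d];
    }
  for (int d = 0; d < 3; ++d) {
    g.fem_x[d] = w0 * cx.fem_x[k0 + cx.nrow * d] + w1 * cx.fem_x[k1 + cx.nrow * d];
    g.fem_v[d] = w0 * cx.fem_v[k0 + cx.nrow * d] + w1 * cx.fem_v[k1 + cx.nrow * d];
    g.fem_w[d] = w0 * cx.fem_w[k0 + cx.nrow * d] + w1 * cx.fem_w[k1 + cx.nrow * d];
  }
  double nq = 0;
  for (int d = 0; d < 4; ++d) {
    g.fem_q[d] = w0 * cx.fem_q[k0 + cx.nrow * d] + w1 * cx.fem_q[k1 + cx.nrow * d];
    nq += g.fem_q[d] * g.fem_q[d];
  }
  nq = std::sqrt(nq);
  for (int d = 0; d < 4; ++d) g.fem_q[d] /= nq;
}

static void bench_forces(Ctx& cx, double rpos, const double* x, const double* q,
                         const double* v, const double* w, ForceOut& fo,
                         bool commit) {
  Guided gd;
  guided_at(cx, rpos, gd);
  double R[9];
  quat_to_R(q, R);
  for (int d = 0; d < 3; ++d) {
    fo.F[d] = cx.mass * cx.g[d];
    fo.T[d] = 0;
  }
  fo.Fmag = 0; fo.delta = 0; fo.delta_dot = 0; fo.contact = false;
  if (cx.crot > 0)
    for (int d = 0; d < 3; ++d) fo.T[d] -= cx.crot * w[d];
  // springs
  fo.ten[0] = fo.ten[1] = 0;
  for (int sidx = 0; sidx < cx.n_spr; ++sidx) {
    double ap[3], av[3], bp[3], bv[3], wl[3];
    for (int d = 0; d < 3; ++d) {
      ap[d] = gd.anchor[sidx][d];
      av[d] = gd.anchor_v[sidx][d];
    }
    const double* loc = cx.attach[sidx].data();
    for (int d = 0; d < 3; ++d)
      bp[d] = x[d] + R[3 * d] * loc[0] + R[3 * d + 1] * loc[1] +
              R[3 * d + 2] * loc[2];
    double wxl[3];
    cross(w, loc, wxl);
    for (int d = 0; d < 3; ++d)
      bv[d] = v[d] + R[3 * d] * wxl[0] + R[3 * d + 1] * wxl[1] +
              R[3 * d + 2] * wxl[2];
    double dvec[3];
    for (int d = 0; d < 3; ++d) dvec[d] = bp[d] - ap[d];
    double L = std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1] +
                         dvec[2] * dvec[2]);
    double u[3];
    for (int d = 0; d < 3; ++d) u[d] = dvec[d] / std::max(L, 1e-12);
    double Ldot = 0;
    for (int d = 0; d < 3; ++d) Ldot += (bv[d] - av[d]) * u[d];
    double ten = cx.K[sidx] * (L - cx.L0[sidx]) + cx.C[sidx] * Ldot;
    fo.ten[cx.group[sidx]] += ten;
    double Fs[3];
    for (int d = 0; d < 3; ++d) Fs[d] = -ten * u[d];  // pulls B toward A
    double rw[3] = {bp[0] - x[0], bp[1] - x[1], bp[2] - x[2]};
    double tw[3];
    cross(rw, Fs, tw);
    for (int d = 0; d < 3; ++d) {
      fo.F[d] += Fs[d];
      // torque to body frame: R^T * tw
      fo.T[d] += R[d] * tw[0] + R[d + 3] * tw[1] + R[d + 6] * tw[2];
    }
    (void)wl;
  }
  // contact: sphere center world
  double cw[3];
  for (int d = 0; d < 3; ++d)
    cw[d] = x[d] + R[3 * d] * cx.sc_local[0] + R[3 * d + 1] * cx.sc_local[1] +
            R[3 * d + 2] * cx.sc_local[2];
  // into femur surface frame
  double Rf[9], fx_[3];
  for (int d = 0; d < 3; ++d) fx_[d] = gd.fem_x[d];
  quat_to_R(gd.fem_q, Rf);
  double cl[3];
  for (int d = 0; d < 3; ++d)
    cl[d] = Rf[d] * (cw[0] - fx_[0]) + Rf[d + 3] * (cw[1] - fx_[1]) +
            Rf[d + 6] * (cw[2] - fx_[2]);
  double s = cx.warm_ok ? cx.warm_s : cl[0];
  double t = cx.warm_ok ? cx.warm_t : cl[1];
  bool interior = surf_closest(cx.S, cl, s, t);
  if (commit) {
    cx.warm_s = s; cx.warm_t = t; cx.warm_ok = true;
  }
  if (!interior) {
    if (commit) cx.ep_active = false;
    return;
  }
  double ev[3];
  surf_eval(cx.S, s, t, ev);
  double nl[3] = {-ev[1], -ev[2], 1};
  double nn = std::sqrt(nl[0] * nl[0] + nl[1] * nl[1] + nl[2] * nl[2]);
  for (int d = 0; d < 3; ++d) nl[d] /= nn;
  double pl[3] = {s, t, ev[0]};
  double dv[3] = {cl[0] - pl[0], cl[1] - pl[1], cl[2] - pl[2]};
  double dist = std::sqrt(dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2]);
  double sgn = dv[0] * nl[0] + dv[1] * nl[1] + dv[2] * nl[2];
  if (sgn < 0) dist = -dist;
  if (dist >= cx.radius) {
    if (commit) cx.ep_active = false;
    return;
  }
  // a center below the surface is deep penetration only as the continuation
  // of an existing episode (or a sub-radius overshoot); a body arriving from
  // underneath is not in contact
  if (dist < 0 && !(cx.ep_active || std::fabs(dist) < 0.5 * cx.radius)) {
    if (commit) cx.ep_active = false;
    return;
  }
  double delta = dist >= 0 ? cx.radius - dist
                           : cx.radius + std::min(std::fabs(dist), cx.radius);
  // world normal and point
  double nw[3], pw[3];
  for (int d = 0; d < 3; ++d) {
    nw[d] = Rf[3 * d] * nl[0] + Rf[3 * d + 1] * nl[1] + Rf[3 * d + 2] * nl[2];
    pw[d] = fx_[d] + Rf[3 * d] * pl[0] + Rf[3 * d + 1] * pl[1] +
            Rf[3 * d + 2] * pl[2];
  }
  // orient toward sphere center
  double dd = nw[0] * (cw[0] - pw[0]) + nw[1] * (cw[1] - pw[1]) +
              nw[2] * (cw[2] - pw[2]);
  if (dd < 0)
    for (int d = 0; d < 3; ++d) nw[d] = -nw[d];
  // approach rate
  double wxc[3];
  cross(w, cx.sc_local, wxc);
  double vs[3];
  for (int d = 0; d < 3; ++d)
    vs[d] = v[d] + R[3 * d] * wxc[0] + R[3 * d + 1] * wxc[1] +
            R[3 * d + 2] * wxc[2];
  // femur point velocity
  double rl[3];
  for (int d = 0; d < 3; ++d)
    rl[d] = Rf[d] * (pw[0] - fx_[0]) + Rf[d + 3] * (pw[1] - fx_[1]) +
            Rf[d + 6] * (pw[2] - fx_[2]);
  double fw[3] = {gd.fem_w[0], gd.fem_w[1], gd.fem_w[2]};
  double wxr[3];
  cross(fw, rl, wxr);
  double vf[3];
  for (int d = 0; d < 3; ++d)
    vf[d] = gd.fem_v[d] + Rf[3 * d] * wxr[0] +
            Rf[3 * d + 1] * wxr[1] + Rf[3 * d + 2] * wxr[2];
  double ddot = -((vs[0] - vf[0]) * nw[0] + (vs[1] - vf[1]) * nw[1] +
                  (vs[2] - vf[2]) * nw[2]);
  double dd0 = cx.ep_active ? cx.ep_dd0 : ddot;
  if (commit && !cx.ep_active) {
    cx.ep_active = true;
    cx.ep_dd0 = ddot;
  }
  // dissipation only for episodes opening with a meaningful approach speed;
  // the compression ratio is capped at its clean-impact maximum of 1
  double bracket = 1;
  if (dd0 > 1e-4)
    bracket = 1 + 8 * (1 - cx.eps) / (5 * cx.eps) * std::min(ddot / dd0, 1.0);
  double Fm = cx.kn * std::pow(delta, cx.pexp) * bracket;
  if (Fm < 0) Fm = 0;
  double Fc[3] = {Fm * nw[0], Fm * nw[1], Fm * nw[2]};
  double rw[3] = {pw[0] - x[0], pw[1] - x[1], pw[2] - x[2]};
  double tw[3];
  cross(rw, Fc, tw);
  for (int d = 0; d < 3; ++d) {
    fo.F[d] += Fc[d];
    fo.T[d] += R[d] * tw[0] + R[d + 3] * tw[1] + R[d + 6] * tw[2];
  }
  fo.Fmag = Fm; fo.delta = delta; fo.delta_dot = ddot; fo.contact = true;
  for (int d = 0; d < 3; ++d) {
    fo.pt[d] = pw[d];
    fo.nrm[d] = nw[d];
  }
}

// [[Rcpp::export]]
List cpp_bench_simulate(List body, List springs, List sphere, List surface,
                        List flores, List guided, NumericVector gravity,
                        NumericVector state0, double h, double gamma,
                        double beta, int n_steps, int record_every,
                        double newton_tol, int newton_max, double t0) {
  Ctx cx;
  cx.mass = as<double>(body["mass"]);
  cx.crot = body.containsElementNamed("rot_damping") ? as<double>(body["rot_damping"]) : 0.0;
  NumericVector Jd = body["inertia"];
  for (int d = 0; d < 3; ++d) {
    cx.Jd[d] = Jd[d];
    cx.g[d] = gravity[d];
  }
  NumericVector K = springs["K"], L0 = springs["L0"], C = springs["c"];
  NumericMatrix att = springs["attach"];
  IntegerVector grp = springs["group"];
  cx.n_spr = K.size();
  cx.K.resize(cx.n_spr); cx.L0.resize(cx.n_spr); cx.C.resize(cx.n_spr);
  cx.attach.resize(cx.n_spr); cx.group.resize(cx.n_spr);
  for (int sidx = 0; sidx < cx.n_spr; ++sidx) {
    cx.K[sidx] = K[sidx]; cx.L0[sidx] = L0[sidx]; cx.C[sidx] = C[sidx];
    cx.group[sidx] = grp[sidx];
    for (int d = 0; d < 3; ++d) cx.attach[sidx][d] = att(sidx, d);
  }
  NumericVector scl = sphere["center"];
  for (int d = 0; d < 3; ++d) cx.sc_local[d] = scl[d];
  cx.radius = as<double>(sphere["radius"]);
  NumericVector cf = surface["coef"];
  IntegerVector ei = surface["ei"], ej = surface["ej"];
  cx.S.cf = cf.begin(); cx.S.ei = ei.begin(); cx.S.ej = ej.begin();
  cx.S.n = cf.size();
  cx.S.order = as<int>(surface["order"]);
  cx.S.cx = as<double>(surface["cx"]); cx.S.cy = as<double>(surface["cy"]);
  cx.S.sx = as<double>(surface["sx"]); cx.S.sy = as<double>(surface["sy"]);
  NumericVector dom = surface["domain"];
  cx.S.lox = dom[0]; cx.S.hix = dom[1]; cx.S.loy = dom[2]; cx.S.hiy = dom[3];
  cx.kn = as<double>(flores["k_n"]);
  cx.pexp = as<double>(flores["p"]);
  cx.eps = as<double>(flores["eps"]);
  List anchors = guided["anchors"], anchors_v = guided["anchors_v"];
  NumericMatrix fxm = guided["fem_x"], fqm = guided["fem_q"],
                fvm = guided["fem_v"], fwm = guided["fem_w"];
  cx.anchor.resize(cx.n_spr);
  cx.anchor_v.resize(cx.n_spr);
  std::vector<NumericMatrix> keep_a, keep_v;
  for (int sidx = 0; sidx < cx.n_spr; ++sidx) {
    NumericMatrix am = anchors[sidx], vm = anchors_v[sidx];
    keep_a.push_back(am); keep_v.push_back(vm);
    cx.anchor[sidx] = am.begin();
    cx.anchor_v[sidx] = vm.begin();
  }
  cx.fem_x = fxm.begin(); cx.fem_q = fqm.begin();
  cx.fem_v = fvm.begin(); cx.fem_w = fwm.begin();
  cx.nrow = fxm.nrow();
  cx.ep_active = false; cx.ep_dd0 = 0;
  cx.warm_ok = false; cx.warm_s = 0; cx.warm_t = 0;
  // state: x(3) q(4) v(3) w(3) a(3) al(3)
  double x[3], q[4], v[3], w[3], acc[6];
  for (int d = 0; d < 3; ++d) {
    x[d] = state0[d]; v[d] = state0[7 + d]; w[d] = state0[10 + d];
    acc[d] = state0[13 + d]; acc[3 + d] = state0[16 + d];
  }
  for (int d = 0; d < 4; ++d) q[d] = state0[3 + d];
  int nrec = n_steps / record_every + 1;
  NumericMatrix rec(nrec, 24);
  List events;
  ForceOut fo;
  bool prev_contact = true;
  auto record_row = [&](int slot, double t, const ForceOut& f) {
    rec(slot, 0) = t;
    for (int d = 0; d < 3; ++d) rec(slot, 1 + d) = x[d];
    for (int d = 0; d < 4; ++d) rec(slot, 4 + d) = q[d];
    for (int d = 0; d < 3; ++d) rec(slot, 8 + d) = v[d];
    for (int d = 0; d < 3; ++d) rec(slot, 11 + d) = w[d];
    rec(slot, 14) = f.ten[0]; rec(slot, 15) = f.ten[1];
    rec(slot, 16) = f.Fmag; rec(slot, 17) = f.delta;
    rec(slot, 18) = f.delta_dot;
    for (int d = 0; d < 3; ++d) rec(slot, 19 + d) = f.contact ? f.pt[d] : NA_REAL;
    rec(slot, 22) = f.contact ? 1.0 : 0.0;
    rec(slot, 23) = f.contact ? f.nrm[2] : NA_REAL;
  };
  bench_forces(cx, 0, x, q, v, w, fo, true);
  record_row(0, t0, fo);
  int slot = 0;
  // one Newmark attempt over h_eff ending at fractional guided row rpos;
  // returns true when Newton converged (residual below accept_tol)
  double x1[3], q1[4], v1[3], w1[3];
  double accept_tol = newton_tol * 1e4;
  int n_forced = 0;  // substepped-to-the-limit acceptances
  auto attempt = [&](double h_eff, double rpos, double* a_new) {
    auto advance = [&](const double* a) {
      for (int d = 0; d < 3; ++d) {
        x1[d] = x[d] + h_eff * v[d] +
                h_eff * h_eff * ((0.5 - beta) * acc[d] + beta * a[d]);
        v1[d] = v[d] + h_eff * ((1 - gamma) * acc[d] + gamma * a[d]);
        w1[d] = w[d] + h_eff * ((1 - gamma) * acc[3 + d] + gamma * a[3 + d]);
      }
      double dth[3], qe[4];
      for (int d = 0; d < 3; ++d)
        dth[d] = h_eff * w[d] +
                 h_eff * h_eff * ((0.5 - beta) * acc[3 + d] + beta * a[3 + d]);
      quat_exp(dth, qe);
      quat_mul(q, qe, q1);
      double nq = std::sqrt(q1[0] * q1[0] + q1[1] * q1[1] + q1[2] * q1[2] +
                            q1[3] * q1[3]);
      for (int d = 0; d < 4; ++d) q1[d] /= nq;
    };
    auto residual = [&](const double* a, double* r) {
      advance(a);
      bench_forces(cx, rpos, x1, q1, v1, w1, fo, false);
      for (int d = 0; d < 3; ++d) r[d] = cx.mass * a[d] - fo.F[d];
      double Jw[3] = {cx.Jd[0] * w1[0], cx.Jd[1] * w1[1], cx.Jd[2] * w1[2]};
      double wxJw[3];
      cross(w1, Jw, wxJw);
      for (int d = 0; d < 3; ++d)
        r[3 + d] = cx.Jd[d] * a[3 + d] + wxJw[d] - fo.T[d];
    };
    double r[6];
    residual(a_new, r);
    for (int it = 0; it < newton_max; ++it) {
      double rn = 0;
      for (int d = 0; d < 6; ++d) rn += r[d] * r[d];
      if (std::sqrt(rn) < newton_tol) break;
      double J[36], rp[6];
      for (int col = 0; col < 6; ++col) {
        double da = 1e-4 * std::max(1.0, std::fabs(a_new[col]));
        double ap[6];
        for (int d = 0; d < 6; ++d) ap[d] = a_new[d];
        ap[col] += da;
        residual(ap, rp);
        for (int d = 0; d < 6; ++d) J[d * 6 + col] = (rp[d] - r[d]) / da;
      }
      double A[36], b[6];
      for (int d = 0; d < 36; ++d) A[d] = J[d];
      for (int d = 0; d < 6; ++d) b[d] = r[d];
      int piv[6] = {0, 1, 2, 3, 4, 5};
      bool ok = true;
      for (int col = 0; col < 6 && ok; ++col) {
        int pr = col;
        for (int rr = col + 1; rr < 6; ++rr)
          if (std::fabs(A[piv[rr] * 6 + col]) > std::fabs(A[piv[pr] * 6 + col]))
            pr = rr;
        std::swap(piv[col], piv[pr]);
        double p = A[piv[col] * 6 + col];
        if (std::fabs(p) < 1e-300) { ok = false; break; }
        for (int rr = col + 1; rr < 6; ++rr) {
          double f = A[piv[rr] * 6 + col] / p;
          for (int cc = col; cc < 6; ++cc)
            A[piv[rr] * 6 + cc] -= f * A[piv[col] * 6 + cc];
          b[piv[rr]] -= f * b[piv[col]];
        }
      }
      if (!ok) break;
      double da[6];
      for (int col = 5; col >= 0; --col) {
        double sum = b[piv[col]];
        for (int cc = col + 1; cc < 6; ++cc)
          sum -= A[piv[col] * 6 + cc] * da[cc];
        da[col] = sum / A[piv[col] * 6 + col];
      }
      double rn0 = rn;
      double lamls = 1.0;
      double a_try[6], r_try[6];
      bool improved = false;
      for (int ls = 0; ls < 8; ++ls) {
        for (int d = 0; d < 6; ++d) a_try[d] = a_new[d] - lamls * da[d];
        residual(a_try, r_try);
        double rn1 = 0;
        for (int d = 0; d < 6; ++d) rn1 += r_try[d] * r_try[d];
        if (rn1 < rn0) { improved = true; break; }
        lamls *= 0.5;
      }
      if (!improved) break;  // keep the best iterate found so far
      for (int d = 0; d < 6; ++d) {
        a_new[d] = a_try[d];
        r[d] = r_try[d];
      }
    }
    double rn = 0;
    for (int d = 0; d < 6; ++d) rn += r[d] * r[d];
    return std::sqrt(rn) < accept_tol;
  };
  for (int step = 1; step <= n_steps; ++step) {
    // integrate from row step-1 to row step, substepping on Newton failure
    double done = 0, frac = 1.0;
    const double frac_min = 1.0 / 32.0;
    while (done < 1 - 1e-12) {
      if (frac > 1 - done) frac = 1 - done;
      double a_new[6];
      for (int d = 0; d < 6; ++d) a_new[d] = acc[d];
      double rpos = (step - 1) + done + frac;
      bool ok = attempt(h * frac, rpos, a_new);
      if (!ok && frac > frac_min) {
        frac *= 0.5;
        continue;
      }
      if (!ok) ++n_forced;
      // accept (advance was called last inside attempt's residual; redo to
      // be safe with the final a_new)
      double x1b[3], q1b[4], v1b[3], w1b[3];
      {
        double h_eff = h * frac;
        for (int d = 0; d < 3; ++d) {
          x1b[d] = x[d] + h_eff * v[d] +
                   h_eff * h_eff * ((0.5 - beta) * acc[d] + beta * a_new[d]);
          v1b[d] = v[d] + h_eff * ((1 - gamma) * acc[d] + gamma * a_new[d]);
          w1b[d] = w[d] + h_eff * ((1 - gamma) * acc[3 + d] + gamma * a_new[3 + d]);
        }
        double dth[3], qe[4];
        for (int d = 0; d < 3; ++d)
          dth[d] = h_eff * w[d] + h_eff * h_eff *
                   ((0.5 - beta) * acc[3 + d] + beta * a_new[3 + d]);
        quat_exp(dth, qe);
        quat_mul(q, qe, q1b);
        double nq = std::sqrt(q1b[0] * q1b[0] + q1b[1] * q1b[1] +
                              q1b[2] * q1b[2] + q1b[3] * q1b[3]);
        for (int d = 0; d < 4; ++d) q1b[d] /= nq;
      }
      for (int d = 0; d < 3; ++d) {
        x[d] = x1b[d]; v[d] = v1b[d]; w[d] = w1b[d];
      }
      for (int d = 0; d < 4; ++d) q[d] = q1b[d];
      for (int d = 0; d < 6; ++d) acc[d] = a_new[d];
      done += frac;
      // commit episode state at the new substep time
      bench_forces(cx, (step - 1) + done, x, q, v, w, fo, true);
      if (frac < 1 && done < 1 - 1e-12) frac *= 2;
    }
    if (prev_contact && !fo.contact)
      events.push_back(List::create(_["type"] = "contact_loss",
                                    _["t"] = t0 + step * h));
    prev_contact = fo.contact;
    if (step % record_every == 0) {
      ++slot;
      record_row(slot, t0 + step * h, fo);
    }
  }
  return List::create(_["rec"] = rec, _["events"] = events,
                      _["n_forced"] = n_forced,
                      _["final"] = NumericVector::create(
                          x[0], x[1], x[2], q[0], q[1], q[2], q[3], v[0],
                          v[1], v[2], w[0], w[1], w[2], acc[0], acc[1],
                          acc[2], acc[3], acc[4], acc[5]));
}
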
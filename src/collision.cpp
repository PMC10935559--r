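// Mesh-to-mesh collision core: AABB tree (median split, one triangle per
// leaf), box queries, ray casting, triangle-triangle intersection segments,
// contour chaining and indentation by ray casting penetrated vertices back to
// the opposing surface. Geometry only; force laws and episode bookkeeping
// live in R.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

struct Node {
  double bmin[3], bmax[3];
  int left = -1, right = -1;  // children (internal) ...
  int tri = -1;               // ... or triangle id (leaf)
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<std::array<double, 9>> tris;  // flattened vertices a,b,c
  std::vector<std::array<double, 3>> nrm;   // unit face normals
  int root = -1;
};

static void tri_bounds(const std::array<double, 9>& t, double* bmin,
                       double* bmax) {
  for (int k = 0; k < 3; ++k) {
    bmin[k] = std::min({t[k], t[3 + k], t[6 + k]});
    bmax[k] = std::max({t[k], t[3 + k], t[6 + k]});
  }
}

static int build_rec(Tree& tr, std::vector<int>& ids, int lo, int hi) {
  Node nd;
  for (int k = 0; k < 3; ++k) {
    nd.bmin[k] = R_PosInf;
    nd.bmax[k] = R_NegInf;
  }
  for (int i = lo; i < hi; ++i) {
    double bmin[3], bmax[3];
    tri_bounds(tr.tris[ids[i]], bmin, bmax);
    for (int k = 0; k < 3; ++k) {
      nd.bmin[k] = std::min(nd.bmin[k], bmin[k]);
      nd.bmax[k] = std::max(nd.bmax[k], bmax[k]);
    }
  }
  int self = (int)tr.nodes.size();
  tr.nodes.push_back(nd);
  if (hi - lo == 1) {
    tr.nodes[self].tri = ids[lo];
    return self;
  }
  int axis = 0;
  double best = nd.bmax[0] - nd.bmin[0];
  for (int k = 1; k < 3; ++k) {
    double w = nd.bmax[k] - nd.bmin[k];
    if (w > best) { best = w; axis = k; }
  }
  int mid = (lo + hi) / 2;
  std::nth_element(ids.begin() + lo, ids.begin() + mid, ids.begin() + hi,
                   [&](int a, int b) {
                     const auto& ta = tr.tris[a];
                     const auto& tb = tr.tris[b];
                     double ca = (ta[axis] + ta[3 + axis] + ta[6 + axis]);
                     double cb = (tb[axis] + tb[3 + axis] + tb[6 + axis]);
                     return ca < cb;
                   });
  int l = build_rec(tr, ids, lo, mid);
  int r = build_rec(tr, ids, mid, hi);
  tr.nodes[self].left = l;
  tr.nodes[self].right = r;
  return self;
}

// [[Rcpp::export]]
SEXP cpp_aabb_build(NumericMatrix V, IntegerMatrix F) {
  Tree* tr = new Tree();
  int nf = F.nrow();
  tr->tris.resize(nf);
  tr->nrm.resize(nf);
  for (int i = 0; i < nf; ++i) {
    for (int c = 0; c < 3; ++c) {
      int vi = F(i, c) - 1;
      for (int k = 0; k < 3; ++k) tr->tris[i][3 * c + k] = V(vi, k);
    }
    const auto& t = tr->tris[i];
    double e1[3], e2[3], n[3];
    for (int k = 0; k < 3; ++k) {
      e1[k] = t[3 + k] - t[k];
      e2[k] = t[6 + k] - t[k];
    }
    n[0] = e1[1] * e2[2] - e1[2] * e2[1];
    n[1] = e1[2] * e2[0] - e1[0] * e2[2];
    n[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double ln = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    for (int k = 0; k < 3; ++k) tr->nrm[i][k] = n[k] / std::max(ln, 1e-300);
  }
  std::vector<int> ids(nf);
  for (int i = 0; i < nf; ++i) ids[i] = i;
  tr->root = build_rec(*tr, ids, 0, nf);
  XPtr<Tree> p(tr, true);
  return p;
}

// [[Rcpp::export]]
List cpp_aabb_nodes(SEXP treeptr) {
  XPtr<Tree> tr(treeptr);
  int n = (int)tr->nodes.size();
  NumericMatrix bmin(n, 3), bmax(n, 3);
  IntegerVector left(n), right(n), tri(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      bmin(i, k) = tr->nodes[i].bmin[k];
      bmax(i, k) = tr->nodes[i].bmax[k];
    }
    left[i] = tr->nodes[i].left + 1;    // 0 = none
    right[i] = tr->nodes[i].right + 1;
    tri[i] = tr->nodes[i].tri + 1;
  }
  return List::create(_["bmin"] = bmin, _["bmax"] = bmax, _["left"] = left,
                      _["right"] = right, _["tri"] = tri,
                      _["root"] = tr->root + 1);
}

static bool box_overlap(const double* amin, const double* amax,
                        const double* bmin, const double* bmax) {
  for (int k = 0; k < 3; ++k)
    if (amax[k] < bmin[k] || bmax[k] < amin[k]) return false;
  return true;
}

// [[Rcpp::export]]
IntegerVector cpp_aabb_query(SEXP treeptr, NumericVector bmin,
                             NumericVector bmax) {
  XPtr<Tree> tr(treeptr);
  std::vector<int> out, stack;
  stack.push_back(tr->root);
  while (!stack.empty()) {
    int id = stack.back();
    stack.pop_back();
    const Node& nd = tr->nodes[id];
    if (!box_overlap(nd.bmin, nd.bmax, bmin.begin(), bmax.begin())) continue;
    if (nd.tri >= 0) out.push_back(nd.tri + 1);
    else { stack.push_back(nd.left); stack.push_back(nd.right); }
  }
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// depth of the tree (edges on longest root-leaf path)
// [[Rcpp::export]]
int cpp_aabb_depth(SEXP treeptr) {
  XPtr<Tree> tr(treeptr);
  std::vector<std::pair<int, int>> stack{{tr->root, 0}};
  int dmax = 0;
  while (!stack.empty()) {
    auto [id, d] = stack.back();
    stack.pop_back();
    dmax = std::max(dmax, d);
    const Node& nd = tr->nodes[id];
    if (nd.tri < 0) {
      stack.push_back({nd.left, d + 1});
      stack.push_back({nd.right, d + 1});
    }
  }
  return dmax;
}

// Moller-Trumbore ray/triangle
static bool ray_tri(const double* o, const double* d,
                    const std::array<double, 9>& t, double& tout,
                    double eps = 1e-12) {
  double e1[3], e2[3], p[3], q[3], s[3];
  for (int k = 0; k < 3; ++k) {
    e1[k] = t[3 + k] - t[k];
    e2[k] = t[6 + k] - t[k];
  }
  p[0] = d[1] * e2[2] - d[2] * e2[1];
  p[1] = d[2] * e2[0] - d[0] * e2[2];
  p[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < 1e-300) return false;
  double inv = 1.0 / det;
  for (int k = 0; k < 3; ++k) s[k] = o[k] - t[k];
  double u = (s[0] * p[0] + s[1] * p[1] + s[2] * p[2]) * inv;
  if (u < -eps || u > 1 + eps) return false;
  q[0] = s[1] * e1[2] - s[2] * e1[1];
  q[1] = s[2] * e1[0] - s[0] * e1[2];
  q[2] = s[0] * e1[1] - s[1] * e1[0];
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < -eps || u + v > 1 + eps) return false;
  tout = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  return true;
}

// nearest ray hit; returns triangle id (1-based) or 0
// [[Rcpp::export]]
List cpp_ray_mesh(SEXP treeptr, NumericVector orig, NumericVector dir,
                  double tmin = 0.0) {
  XPtr<Tree> tr(treeptr);
  std::vector<int> stack{tr->root};
  double best = R_PosInf;
  int hit = -1;
  const double* o = orig.begin();
  const double* d = dir.begin();
  while (!stack.empty()) {
    int id = stack.back();
    stack.pop_back();
    const Node& nd = tr->nodes[id];
    // slab test
    double t0 = tmin, t1 = best;
    bool ok = true;
    for (int k = 0; k < 3 && ok; ++k) {
      if (std::fabs(d[k]) < 1e-300) {
        if (o[k] < nd.bmin[k] || o[k] > nd.bmax[k]) ok = false;
      } else {
        double ta = (nd.bmin[k] - o[k]) / d[k];
        double tb = (nd.bmax[k] - o[k]) / d[k];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
        if (t0 > t1) ok = false;
      }
    }
    if (!ok) continue;
    if (nd.tri >= 0) {
      double t;
      if (ray_tri(o, d, tr->tris[nd.tri], t) && t >= tmin && t < best) {
        best = t;
        hit = nd.tri;
      }
    } else {
      stack.push_back(nd.left);
      stack.push_back(nd.right);
    }
  }
  if (hit < 0) return List::create(_["hit"] = 0);
  return List::create(_["hit"] = hit + 1, _["t"] = best,
                      _["normal"] = NumericVector::create(
                          tr->nrm[hit][0], tr->nrm[hit][1], tr->nrm[hit][2]));
}

// Intersection segment of two triangles: chord of T1 on plane(T2) clipped to
// T2. Returns true with endpoints p, q; sets coplanar flag when the pair is
// (near) coplanar and is skipped.
static bool tri_tri_segment(const std::array<double, 9>& T1,
                            const std::array<double, 9>& T2, double* p,
                            double* q, bool& coplanar, double eps = 1e-12) {
  double n2[3], e1[3], e2[3];
  for (int k = 0; k < 3; ++k) {
    e1[k] = T2[3 + k] - T2[k];
    e2[k] = T2[6 + k] - T2[k];
  }
  n2[0] = e1[1] * e2[2] - e1[2] * e2[1];
  n2[1] = e1[2] * e2[0] - e1[0] * e2[2];
  n2[2] = e1[0] * e2[1] - e1[1] * e2[0];
  double ln = std::sqrt(n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2]);
  if (ln < 1e-300) return false;
  for (int k = 0; k < 3; ++k) n2[k] /= ln;
  double d2 = n2[0] * T2[0] + n2[1] * T2[1] + n2[2] * T2[2];
  double s[3];
  for (int c = 0; c < 3; ++c)
    s[c] = n2[0] * T1[3 * c] + n2[1] * T1[3 * c + 1] + n2[2] * T1[3 * c + 2] -
           d2;
  if (std::fabs(s[0]) < eps && std::fabs(s[1]) < eps && std::fabs(s[2]) < eps) {
    coplanar = true;
    return false;
  }
  if ((s[0] > -eps && s[1] > -eps && s[2] > -eps) ||
      (s[0] < eps && s[1] < eps && s[2] < eps))
    return false;
  // chord endpoints: T1 edges crossing plane of T2
  double pts[2][3];
  int np = 0;
  for (int c = 0; c < 3 && np < 2; ++c) {
    int c2 = (c + 1) % 3;
    if ((s[c] > 0) != (s[c2] > 0)) {
      double t = s[c] / (s[c] - s[c2]);
      for (int k = 0; k < 3; ++k)
        pts[np][k] = T1[3 * c + k] + t * (T1[3 * c2 + k] - T1[3 * c + k]);
      ++np;
    }
  }
  if (np < 2) return false;
  // clip chord [A,B] against half-planes of T2 edges (inside = toward
  // triangle interior within its plane)
  double lo = 0.0, hi = 1.0;
  for (int c = 0; c < 3; ++c) {
    int c2 = (c + 1) % 3;
    double ed[3], inw[3];
    for (int k = 0; k < 3; ++k) ed[k] = T2[3 * c2 + k] - T2[3 * c + k];
    inw[0] = n2[1] * ed[2] - n2[2] * ed[1];
    inw[1] = n2[2] * ed[0] - n2[0] * ed[2];
    inw[2] = n2[0] * ed[1] - n2[1] * ed[0];
    double fa = 0, fb = 0;
    for (int k = 0; k < 3; ++k) {
      fa += inw[k] * (pts[0][k] - T2[3 * c + k]);
      fb += inw[k] * (pts[1][k] - T2[3 * c + k]);
    }
    double den = fa - fb;  // f(t) = fa + t (fb - fa)
    if (std::fabs(den) < 1e-300) {
      if (fa < 0) return false;  // entirely outside this half-plane
      continue;
    }
    double t = fa / den;
    if (fa < fb) lo = std::max(lo, t);  // entering
    else hi = std::min(hi, t);          // leaving
    if (lo >= hi) return false;
  }
  for (int k = 0; k < 3; ++k) {
    p[k] = pts[0][k] + lo * (pts[1][k] - pts[0][k]);
    q[k] = pts[0][k] + hi * (pts[1][k] - pts[0][k]);
  }
  double seglen2 = 0;
  for (int k = 0; k < 3; ++k) seglen2 += (q[k] - p[k]) * (q[k] - p[k]);
  return seglen2 > eps * eps;
}

struct VKey {
  int64_t a, b, c;
  bool operator<(const VKey& o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

static VKey quantize(const double* p, double h = 1e-9) {
  return VKey{(int64_t)std::llround(p[0] / h), (int64_t)std::llround(p[1] / h),
              (int64_t)std::llround(p[2] / h)};
}

// Dual-tree mesh contact in frame of tree A. B supplied as posed triangles.
// Returns intersection segments, contours, involved A faces, and per-contour
// patch geometry. Indentation is computed in R (needs episode state there
// anyway) via cpp_ray_mesh, or here through cpp_mesh_contacts for speed.
// [[Rcpp::export]]
List cpp_mesh_contacts(SEXP treeAptr, NumericMatrix VB, IntegerMatrix FB,
                       NumericMatrix NB, NumericVector bcenter) {
  XPtr<Tree> trA(treeAptr);
  // broad phase: query A tree with each B triangle box
  std::vector<std::array<double, 9>> tb(FB.nrow());
  for (int i = 0; i < FB.nrow(); ++i)
    for (int c = 0; c < 3; ++c)
      for (int k = 0; k < 3; ++k) tb[i][3 * c + k] = VB(FB(i, c) - 1, k);
  struct Seg {
    double p[3], q[3];
    int ta, tb;
  };
  std::vector<Seg> segs;
  bool coplanar_any = false;
  for (int ib = 0; ib < (int)tb.size(); ++ib) {
    double bmin[3], bmax[3];
    tri_bounds(tb[ib], bmin, bmax);
    std::vector<int> stack{trA->root};
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      const Node& nd = trA->nodes[id];
      if (!box_overlap(nd.bmin, nd.bmax, bmin, bmax)) continue;
      if (nd.tri >= 0) {
        Seg sg;
        bool cop = false;
        if (tri_tri_segment(tb[ib], trA->tris[nd.tri], sg.p, sg.q, cop)) {
          sg.ta = nd.tri;
          sg.tb = ib;
          segs.push_back(sg);
        }
        if (cop) coplanar_any = true;
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
  }
  if (segs.empty())
    return List::create(_["n_patches"] = 0, _["coplanar"] = coplanar_any);

  // chain segments into contours via endpoint hashing
  int ns = (int)segs.size();
  std::map<VKey, std::vector<int>> ends;  // endpoint key -> segment ids
  for (int i = 0; i < ns; ++i) {
    ends[quantize(segs[i].p)].push_back(i);
    ends[quantize(segs[i].q)].push_back(i);
  }
  std::vector<int> comp(ns, -1);
  int ncomp = 0;
  for (int i = 0; i < ns; ++i) {
    if (comp[i] >= 0) continue;
    std::vector<int> stack{i};
    comp[i] = ncomp;
    while (!stack.empty()) {
      int s0 = stack.back();
      stack.pop_back();
      for (const double* e : {(const double*)segs[s0].p,
                              (const double*)segs[s0].q}) {
        for (int j : ends[quantize(e)]) {
          if (comp[j] < 0) {
            comp[j] = ncomp;
            stack.push_back(j);
          }
        }
      }
    }
    ++ncomp;
  }
  List patches(ncomp);
  for (int c = 0; c < ncomp; ++c) {
    std::vector<int> ids;
    for (int i = 0; i < ns; ++i)
      if (comp[i] == c) ids.push_back(i);
    // closed iff every endpoint key is shared by an even number of ends
    std::map<VKey, int> cnt;
    for (int i : ids) {
      cnt[quantize(segs[i].p)]++;
      cnt[quantize(segs[i].q)]++;
    }
    bool closed = true;
    for (auto& kv : cnt)
      if (kv.second % 2) { closed = false; break; }
    // contour points, centroid (weighted by segment length)
    double cen[3] = {0, 0, 0}, wsum = 0;
    NumericMatrix pts(2 * (int)ids.size(), 3);
    std::vector<int> afaces;
    for (size_t ii = 0; ii < ids.size(); ++ii) {
      const Seg& sg = segs[ids[ii]];
      double len = 0;
      for (int k = 0; k < 3; ++k) len += (sg.q[k] - sg.p[k]) * (sg.q[k] - sg.p[k]);
      len = std::sqrt(len);
      for (int k = 0; k < 3; ++k) {
        cen[k] += 0.5 * (sg.p[k] + sg.q[k]) * len;
        pts(2 * ii, k) = sg.p[k];
        pts(2 * ii + 1, k) = sg.q[k];
      }
      wsum += len;
      afaces.push_back(sg.ta);
    }
    for (int k = 0; k < 3; ++k) cen[k] /= std::max(wsum, 1e-300);
    // normal: area-weighted average of involved (penetrated) A-face normals
    std::sort(afaces.begin(), afaces.end());
    afaces.erase(std::unique(afaces.begin(), afaces.end()), afaces.end());
    double nrm[3] = {0, 0, 0};
    for (int fa : afaces) {
      const auto& t = trA->tris[fa];
      double e1[3], e2[3];
      for (int k = 0; k < 3; ++k) {
        e1[k] = t[3 + k] - t[k];
        e2[k] = t[6 + k] - t[k];
      }
      double cr[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                      e1[2] * e2[0] - e1[0] * e2[2],
                      e1[0] * e2[1] - e1[1] * e2[0]};
      double area = 0.5 * std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
      for (int k = 0; k < 3; ++k) nrm[k] += area * trA->nrm[fa][k];
    }
    double ln = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
    for (int k = 0; k < 3; ++k) nrm[k] /= std::max(ln, 1e-300);
    // orient from surface A toward body B
    double toB = 0;
    for (int k = 0; k < 3; ++k) toB += nrm[k] * (bcenter[k] - cen[k]);
    if (toB < 0)
      for (int k = 0; k < 3; ++k) nrm[k] = -nrm[k];
    // indentation: deepest B vertex below A's surface along the patch normal,
    // restricted to B vertices near the contour
    double bbmin[3], bbmax[3];
    for (int k = 0; k < 3; ++k) {
      bbmin[k] = R_PosInf;
      bbmax[k] = R_NegInf;
    }
    for (int r = 0; r < pts.nrow(); ++r)
      for (int k = 0; k < 3; ++k) {
        bbmin[k] = std::min(bbmin[k], pts(r, k));
        bbmax[k] = std::max(bbmax[k], pts(r, k));
      }
    double diag = 0;
    for (int k = 0; k < 3; ++k)
      diag += (bbmax[k] - bbmin[k]) * (bbmax[k] - bbmin[k]);
    diag = std::max(std::sqrt(diag), 1e-4);
    for (int k = 0; k < 3; ++k) {
      bbmin[k] -= diag;
      bbmax[k] += diag;
    }
    double delta = 0;
    int deepest = -1;
    for (int vi = 0; vi < VB.nrow(); ++vi) {
      double pv[3] = {VB(vi, 0), VB(vi, 1), VB(vi, 2)};
      bool inside = true;
      for (int k = 0; k < 3; ++k)
        if (pv[k] < bbmin[k] || pv[k] > bbmax[k]) { inside = false; break; }
      if (!inside) continue;
      // nearest surface hit along +normal
      std::vector<int> stack{trA->root};
      double best = R_PosInf;
      int hitf = -1;
      while (!stack.empty()) {
        int id = stack.back();
        stack.pop_back();
        const Node& nd = trA->nodes[id];
        double t0 = 0, t1 = best;
        bool ok = true;
        for (int k = 0; k < 3 && ok; ++k) {
          if (std::fabs(nrm[k]) < 1e-300) {
            if (pv[k] < nd.bmin[k] || pv[k] > nd.bmax[k]) ok = false;
          } else {
            double ta = (nd.bmin[k] - pv[k]) / nrm[k];
            double tbx = (nd.bmax[k] - pv[k]) / nrm[k];
            if (ta > tbx) std::swap(ta, tbx);
            t0 = std::max(t0, ta);
            t1 = std::min(t1, tbx);
            if (t0 > t1) ok = false;
          }
        }
        if (!ok) continue;
        if (nd.tri >= 0) {
          double t;
          if (ray_tri(pv, nrm, trA->tris[nd.tri], t) && t > 1e-12 && t < best) {
            // only front-facing exits count as "below the surface"
            double dp = 0;
            for (int k = 0; k < 3; ++k) dp += trA->nrm[nd.tri][k] * nrm[k];
            if (dp > 0) {
              best = t;
              hitf = nd.tri;
            }
          }
        } else {
          stack.push_back(nd.left);
          stack.push_back(nd.right);
        }
      }
      if (hitf >= 0 && best < 2 * diag && best > delta) {
        delta = best;
        deepest = vi;
      }
    }
    patches[c] = List::create(
        _["point"] = NumericVector::create(cen[0], cen[1], cen[2]),
        _["normal"] = NumericVector::create(nrm[0], nrm[1], nrm[2]),
        _["delta"] = delta, _["contour"] = pts, _["closed"] = closed,
        _["n_segments"] = (int)ids.size(), _["deepest_vertex"] = deepest + 1,
        _["a_faces"] = wrap(afaces));
  }
  return List::create(_["n_patches"] = ncomp, _["patches"] = patches,
                      _["coplanar"] = coplanar_any);
}
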
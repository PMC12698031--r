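#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Convex hull (volume + vertex set) in d dimensions, d <= 6, by the
// incremental beneath-beyond method with simplicial facets. Points at
// signed distance <= tol from a facet plane are treated as non-visible,
// so cohyperplanar inputs (common with discrete trait data) degrade to
// zero-volume sliver facets rather than corrupting the volume.

static double det_small(std::vector<double> a, int n) {
  // Gaussian elimination with partial pivoting; a is n*n row-major (copied).
  double det = 1.0;
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(a[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = std::fabs(a[r * n + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best == 0.0) return 0.0;
    if (piv != col) {
      for (int c = 0; c < n; ++c) std::swap(a[piv * n + c], a[col * n + c]);
      det = -det;
    }
    det *= a[col * n + col];
    for (int r = col + 1; r < n; ++r) {
      double f = a[r * n + col] / a[col * n + col];
      if (f != 0.0)
        for (int c = col; c < n; ++c) a[r * n + c] -= f * a[col * n + c];
    }
  }
  return det;
}

struct Facet {
  std::vector<int> verts;      // d point indices
  std::vector<double> normal;  // unit outward normal (may be zero for slivers)
  double offset;               // plane: normal . x = offset
  bool alive;
  bool sliver;                 // affinely dependent vertices: never visible
  std::vector<int> outside;
};

static double sdist(const Facet& f, const std::vector<double>& pts, int d, int i) {
  double s = -f.offset;
  for (int k = 0; k < d; ++k) s += f.normal[k] * pts[(size_t)i * d + k];
  return s;
}

// plane through d points; orient away from interior point
static void make_facet(Facet& f, const std::vector<double>& pts, int d,
                       const std::vector<double>& interior) {
  // edge matrix E: (d-1) x d, rows v_k - v_0
  std::vector<double> E((size_t)(d - 1) * d);
  for (int k = 1; k < d; ++k)
    for (int c = 0; c < d; ++c)
      E[(size_t)(k - 1) * d + c] =
        pts[(size_t)f.verts[k] * d + c] - pts[(size_t)f.verts[0] * d + c];
  std::vector<double> n(d);
  std::vector<double> minor((size_t)(d - 1) * (d - 1));
  double nn = 0.0;
  for (int j = 0; j < d; ++j) {
    for (int r = 0; r < d - 1; ++r) {
      int cc = 0;
      for (int c = 0; c < d; ++c) {
        if (c == j) continue;
        minor[(size_t)r * (d - 1) + cc++] = E[(size_t)r * d + c];
      }
    }
    double dv = (d == 1) ? 1.0 : det_small(minor, d - 1);
    n[j] = ((j % 2) ? -1.0 : 1.0) * dv;
    nn += n[j] * n[j];
  }
  nn = std::sqrt(nn);
  f.sliver = (nn <= 0.0);
  if (f.sliver) {
    f.normal.assign(d, 0.0);
    f.offset = 0.0;
    return;
  }
  for (int j = 0; j < d; ++j) n[j] /= nn;
  double off = 0.0;
  for (int j = 0; j < d; ++j) off += n[j] * pts[(size_t)f.verts[0] * d + j];
  double si = -off;
  for (int j = 0; j < d; ++j) si += n[j] * interior[j];
  if (si > 0) {  // flip so interior is below the plane
    for (int j = 0; j < d; ++j) n[j] = -n[j];
    off = -off;
  }
  f.normal = n;
  f.offset = off;
}

// [[Rcpp::export(name = ".convhull_cpp")]]
List convhull_cpp(NumericMatrix points) {
  const int n = points.nrow(), d = points.ncol();
  if (d < 1) stop("points must have at least one column");

  // flatten row-major
  std::vector<double> pts((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) pts[(size_t)i * d + j] = points(i, j);

  if (d == 1) {
    if (n < 2) return List::create(_["volume"] = 0.0,
                                   _["vertices"] = IntegerVector(0),
                                   _["degenerate"] = true);
    int lo = 0, hi = 0;
    for (int i = 1; i < n; ++i) {
      if (pts[i] < pts[lo]) lo = i;
      if (pts[i] > pts[hi]) hi = i;
    }
    double vol = pts[hi] - pts[lo];
    bool degen = (vol <= 0.0);
    return List::create(_["volume"] = vol,
                        _["vertices"] = IntegerVector::create(lo + 1, hi + 1),
                        _["degenerate"] = degen);
  }

  double scale = 0.0;
  for (int j = 0; j < d; ++j) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = pts[(size_t)i * d + j];
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    scale = std::max(scale, mx - mn);
  }
  const double tol = 1e-9 * std::max(scale, 1e-12);

  List degen_out = List::create(_["volume"] = NA_REAL,
                                _["vertices"] = IntegerVector(0),
                                _["degenerate"] = true);
  if (n < d + 1 || scale <= 0.0) return degen_out;

  // ---- initial simplex by greedy affine-span extension ----
  std::vector<int> simp;
  simp.push_back(0);
  {
    int far = -1; double best = tol;
    for (int i = 1; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double e = pts[(size_t)i * d + j] - pts[j];
        s += e * e;
      }
      s = std::sqrt(s);
      if (s > best) { best = s; far = i; }
    }
    if (far < 0) return degen_out;
    simp.push_back(far);
  }
  std::vector<std::vector<double> > basis;  // orthonormal, in R^d
  {
    std::vector<double> b(d);
    double nn = 0.0;
    for (int j = 0; j < d; ++j) {
      b[j] = pts[(size_t)simp[1] * d + j] - pts[(size_t)simp[0] * d + j];
      nn += b[j] * b[j];
    }
    nn = std::sqrt(nn);
    for (int j = 0; j < d; ++j) b[j] /= nn;
    basis.push_back(b);
  }
  while ((int)simp.size() < d + 1) {
    int bi = -1; double best = tol;
    std::vector<double> bres(d);
    for (int i = 0; i < n; ++i) {
      std::vector<double> r(d);
      for (int j = 0; j < d; ++j)
        r[j] = pts[(size_t)i * d + j] - pts[(size_t)simp[0] * d + j];
      for (size_t k = 0; k < basis.size(); ++k) {
        double dp = 0.0;
        for (int j = 0; j < d; ++j) dp += r[j] * basis[k][j];
        for (int j = 0; j < d; ++j) r[j] -= dp * basis[k][j];
      }
      double nn = 0.0;
      for (int j = 0; j < d; ++j) nn += r[j] * r[j];
      nn = std::sqrt(nn);
      if (nn > best) { best = nn; bi = i; bres = r; }
    }
    if (bi < 0) return degen_out;  // points span < d dimensions
    for (int j = 0; j < d; ++j) bres[j] /= best;
    basis.push_back(bres);
    simp.push_back(bi);
  }

  std::vector<double> interior(d, 0.0);
  for (int k = 0; k <= d; ++k)
    for (int j = 0; j < d; ++j)
      interior[j] += pts[(size_t)simp[k] * d + j] / (d + 1);

  std::vector<Facet> facets;
  for (int drop = 0; drop <= d; ++drop) {
    Facet f;
    f.alive = true;
    for (int k = 0; k <= d; ++k)
      if (k != drop) f.verts.push_back(simp[k]);
    make_facet(f, pts, d, interior);
    facets.push_back(f);
  }

  std::vector<bool> in_simplex(n, false);
  for (int k = 0; k <= d; ++k) in_simplex[simp[k]] = true;
  for (int i = 0; i < n; ++i) {
    if (in_simplex[i]) continue;
    int bf = -1; double best = tol;
    for (size_t fi = 0; fi < facets.size(); ++fi) {
      if (facets[fi].sliver) continue;
      double s = sdist(facets[fi], pts, d, i);
      if (s > best) { best = s; bf = (int)fi; }
    }
    if (bf >= 0) facets[bf].outside.push_back(i);
  }

  // ---- main loop ----
  for (long guard = 0; guard < 100000L; ++guard) {
    int fi = -1;
    for (size_t k = 0; k < facets.size(); ++k)
      if (facets[k].alive && !facets[k].outside.empty()) { fi = (int)k; break; }
    if (fi < 0) break;

    const Facet& host = facets[fi];
    int apex = host.outside[0];
    double best = sdist(host, pts, d, apex);
    for (size_t k = 1; k < host.outside.size(); ++k) {
      double s = sdist(host, pts, d, host.outside[k]);
      if (s > best) { best = s; apex = host.outside[k]; }
    }

    std::vector<int> visible;
    for (size_t k = 0; k < facets.size(); ++k) {
      if (!facets[k].alive || facets[k].sliver) continue;
      if (sdist(facets[k], pts, d, apex) > tol) visible.push_back((int)k);
    }
    if (visible.empty()) {  // numerically marginal point: discard it
      std::vector<int>& o = facets[fi].outside;
      o.erase(std::remove(o.begin(), o.end(), apex), o.end());
      continue;
    }

    std::map<std::vector<int>, int> ridge_count;
    std::vector<int> orphans;
    for (size_t v = 0; v < visible.size(); ++v) {
      Facet& f = facets[visible[v]];
      for (int drop = 0; drop < d; ++drop) {
        std::vector<int> ridge;
        for (int k = 0; k < d; ++k)
          if (k != drop) ridge.push_back(f.verts[k]);
        std::sort(ridge.begin(), ridge.end());
        ridge_count[ridge]++;
      }
      for (size_t k = 0; k < f.outside.size(); ++k)
        if (f.outside[k] != apex) orphans.push_back(f.outside[k]);
      f.alive = false;
      f.outside.clear();
    }

    std::vector<int> newf;
    for (std::map<std::vector<int>, int>::const_iterator it = ridge_count.begin();
         it != ridge_count.end(); ++it) {
      if (it->second != 1) continue;  // internal ridge
      Facet f;
      f.alive = true;
      f.verts = it->first;
      f.verts.push_back(apex);
      make_facet(f, pts, d, interior);
      newf.push_back((int)facets.size());
      facets.push_back(f);
    }

    std::sort(orphans.begin(), orphans.end());
    orphans.erase(std::unique(orphans.begin(), orphans.end()), orphans.end());
    for (size_t k = 0; k < orphans.size(); ++k) {
      int i = orphans[k];
      int bf = -1; double bs = tol;
      for (size_t m = 0; m < newf.size(); ++m) {
        const Facet& f = facets[newf[m]];
        if (f.sliver) continue;
        double s = sdist(f, pts, d, i);
        if (s > bs) { bs = s; bf = newf[m]; }
      }
      if (bf >= 0) facets[bf].outside.push_back(i);
    }
  }

  // ---- volume and vertex set ----
  double vol = 0.0;
  double dfact = 1.0;
  for (int k = 2; k <= d; ++k) dfact *= k;
  std::vector<bool> isvert(n, false);
  std::vector<double> M((size_t)d * d);
  for (size_t k = 0; k < facets.size(); ++k) {
    if (!facets[k].alive) continue;
    const Facet& f = facets[k];
    for (int r = 0; r < d; ++r)
      for (int c = 0; c < d; ++c)
        M[(size_t)r * d + c] = pts[(size_t)f.verts[r] * d + c] - interior[c];
    vol += std::fabs(det_small(M, d)) / dfact;
    for (int r = 0; r < d; ++r) isvert[f.verts[r]] = true;
  }
  IntegerVector verts;
  for (int i = 0; i < n; ++i)
    if (isvert[i]) verts.push_back(i + 1);

  return List::create(_["volume"] = vol,
                      _["vertices"] = verts,
                      _["degenerate"] = false);
}
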
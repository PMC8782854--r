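#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Connected components of a binary volume (26-connectivity, the standard
// foreground convention). Returns integer labels, 0 = background; labels are
// 1..ncomp in decreasing component size order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector fg, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> sizes;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!fg[s] || lab[s] != 0) continue;
    ++next;
    R_xlen_t sz = 0;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      ++sz;
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t t = lin(ii, jj, kk, nx, ny);
            if (fg[t] && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
          }
    }
    sizes.push_back(sz);
  }
  // relabel so that label 1 is the largest component
  std::vector<int> ord(next);
  for (int i = 0; i < next; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> newlab(next + 1, 0);
  for (int r = 0; r < next; ++r) newlab[ord[r] + 1] = r + 1;
  for (R_xlen_t s = 0; s < n; ++s) if (lab[s]) lab[s] = newlab[lab[s]];
  lab.attr("ncomp") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, kernel truncated at 3 sigma (voxel units).
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * rad + 1);
  double s = 0;
  for (int d = -rad; d <= rad; ++d) { w[d + rad] = std::exp(-0.5 * d * d / (sigma * sigma)); s += w[d + rad]; }
  for (auto &x : w) x /= s;
  NumericVector a = clone(vol), b(n);
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = dims[ax];
    const R_xlen_t st = strides[ax];
    for (R_xlen_t s0 = 0; s0 < n; ++s0) {
      // position along axis
      int pos;
      if (ax == 0) pos = (int)(s0 % nx);
      else if (ax == 1) pos = (int)((s0 / nx) % ny);
      else pos = (int)(s0 / ((R_xlen_t)nx * ny));
      double acc = 0;
      for (int d = -rad; d <= rad; ++d) {
        int p = pos + d;
        if (p < 0 || p >= len) continue; // zero outside
        acc += w[d + rad] * a[s0 + (R_xlen_t)d * st];
      }
      b[s0] = acc;
    }
    std::swap(a, b);
  }
  return a;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on the Freudenthal (Kuhn) 6-tet cube decomposition.
// Field values live at voxel centres, coordinates returned in continuous
// 0-based index units. Faces are oriented consistently afterwards in R.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 2, 3, 7}, {0, 2, 6, 7},
  {0, 4, 6, 7}, {0, 4, 5, 7}, {0, 1, 5, 7}
};

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dim, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tris;
  const int cx[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  R_xlen_t cidx[8];
  double val[8];
  auto edge_vertex = [&](R_xlen_t a, R_xlen_t b) -> int {
    if (a > b) std::swap(a, b);
    uint64_t key = ((uint64_t)a << 32) | (uint64_t)b;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double va = field[a], vb = field[b];
    double t = (iso - va) / (vb - va);
    int ia = (int)(a % nx), ja = (int)((a / nx) % ny), ka = (int)(a / ((R_xlen_t)nx * ny));
    int ib = (int)(b % nx), jb = (int)((b / nx) % ny), kb = (int)(b / ((R_xlen_t)nx * ny));
    vx.push_back(ia + t * (ib - ia));
    vy.push_back(ja + t * (jb - ja));
    vz.push_back(ka + t * (kb - ka));
    int id = (int)vx.size() - 1;
    vmap[key] = id;
    return id;
  };
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          cidx[c] = lin(i + cx[c], j + cy[c], k + cz[c], nx, ny);
          val[c] = field[cidx[c]];
          (val[c] >= iso ? anyIn : anyOut) = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4];
          int nin = 0;
          int inc[4], outc[4];
          int nout = 0;
          for (int c = 0; c < 4; ++c) {
            vi[c] = TETS[t][c];
            if (val[vi[c]] >= iso) inc[nin++] = vi[c]; else outc[nout++] = vi[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int A = inc[0];
            int e0 = edge_vertex(cidx[A], cidx[outc[0]]);
            int e1 = edge_vertex(cidx[A], cidx[outc[1]]);
            int e2 = edge_vertex(cidx[A], cidx[outc[2]]);
            tris.push_back(e0); tris.push_back(e1); tris.push_back(e2);
          } else if (nin == 3) {
            int A = outc[0];
            int e0 = edge_vertex(cidx[A], cidx[inc[0]]);
            int e1 = edge_vertex(cidx[A], cidx[inc[1]]);
            int e2 = edge_vertex(cidx[A], cidx[inc[2]]);
            tris.push_back(e0); tris.push_back(e1); tris.push_back(e2);
          } else { // 2 in, 2 out
            int A = inc[0], B = inc[1], C = outc[0], D = outc[1];
            int eAC = edge_vertex(cidx[A], cidx[C]);
            int eAD = edge_vertex(cidx[A], cidx[D]);
            int eBC = edge_vertex(cidx[B], cidx[C]);
            int eBD = edge_vertex(cidx[B], cidx[D]);
            tris.push_back(eAC); tris.push_back(eAD); tris.push_back(eBD);
            tris.push_back(eAC); tris.push_back(eBD); tris.push_back(eBC);
          }
        }
      }
  int nv = (int)vx.size(), nf = (int)tris.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v]; }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = tris[3 * f] + 1; F(f, 1) = tris[3 * f + 1] + 1; F(f, 2) = tris[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Make triangle orientations consistent by propagation across shared edges.
// Returns faces (1-based); connected manifold assumed per component.
// [[Rcpp::export]]
IntegerMatrix cpp_orient_faces(IntegerMatrix faces) {
  const int nf = faces.nrow();
  IntegerMatrix F = clone(faces);
  // edge (undirected) -> up to 2 incident faces
  std::unordered_map<uint64_t, std::pair<int, int>> emap;
  emap.reserve(nf * 2);
  auto ekey = [](int a, int b) {
    if (a > b) std::swap(a, b);
    return ((uint64_t)a << 32) | (uint64_t)b;
  };
  for (int f = 0; f < nf; ++f)
    for (int e = 0; e < 3; ++e) {
      uint64_t k = ekey(F(f, e), F(f, (e + 1) % 3));
      auto it = emap.find(k);
      if (it == emap.end()) emap[k] = {f, -1};
      else it->second.second = f;
    }
  std::vector<char> seen(nf, 0);
  std::queue<int> q;
  for (int root = 0; root < nf; ++root) {
    if (seen[root]) continue;
    seen[root] = 1;
    q.push(root);
    while (!q.empty()) {
      int f = q.front(); q.pop();
      for (int e = 0; e < 3; ++e) {
        int a = F(f, e), b = F(f, (e + 1) % 3);
        auto &pr = emap[ekey(a, b)];
        int g = (pr.first == f) ? pr.second : pr.first;
        if (g < 0 || seen[g]) continue;
        // g must traverse edge (a,b) as (b,a); if it has (a,b) flip g
        bool same = false;
        for (int e2 = 0; e2 < 3; ++e2)
          if (F(g, e2) == a && F(g, (e2 + 1) % 3) == b) same = true;
        if (same) { int tmp = F(g, 1); F(g, 1) = F(g, 2); F(g, 2) = tmp; }
        seen[g] = 1;
        q.push(g);
      }
    }
  }
  return F;
}

// ---------------------------------------------------------------------------
// Taubin lambda-mu mesh smoothing with uniform Laplacian weights.
// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix verts, IntegerMatrix faces,
                                int iterations, double lambda, double mu) {
  const int nv = verts.nrow(), nf = faces.nrow();
  std::vector<std::vector<int>> adj(nv);
  for (int f = 0; f < nf; ++f)
    for (int e = 0; e < 3; ++e) {
      int a = faces(f, e) - 1, b = faces(f, (e + 1) % 3) - 1;
      adj[a].push_back(b);
      adj[b].push_back(a);
    }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  NumericMatrix P = clone(verts);
  NumericMatrix Q(nv, 3);
  for (int it = 0; it < iterations; ++it) {
    for (int pass = 0; pass < 2; ++pass) {
      double fac = (pass == 0) ? lambda : mu;
      for (int v = 0; v < nv; ++v) {
        if (adj[v].empty()) { Q(v, 0) = P(v, 0); Q(v, 1) = P(v, 1); Q(v, 2) = P(v, 2); continue; }
        double cx = 0, cy = 0, cz = 0;
        for (int u : adj[v]) { cx += P(u, 0); cy += P(u, 1); cz += P(u, 2); }
        double m = (double)adj[v].size();
        Q(v, 0) = P(v, 0) + fac * (cx / m - P(v, 0));
        Q(v, 1) = P(v, 1) + fac * (cy / m - P(v, 1));
        Q(v, 2) = P(v, 2) + fac * (cz / m - P(v, 2));
      }
      std::swap(P, Q);
    }
  }
  return P;
}

// ---------------------------------------------------------------------------
// In-place cubic B-spline prefilter (Unser), mirror boundaries, all 3 axes.
// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector c = clone(vol);
  const double z1 = std::sqrt(3.0) - 2.0;
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  std::vector<double> line;
  for (int ax = 0; ax < 3; ++ax) {
    const int len = dims[ax];
    if (len < 2) continue;
    const R_xlen_t st = strides[ax];
    line.resize(len);
    const R_xlen_t nlines = n / len;
    for (R_xlen_t L = 0; L < nlines; ++L) {
      // start offset of this line
      R_xlen_t base;
      if (ax == 0) base = L * nx;
      else if (ax == 1) {
        R_xlen_t i = L % nx, k = L / nx;
        base = i + (R_xlen_t)nx * ny * k;
      } else {
        base = L; // i + nx*j
      }
      for (int p = 0; p < len; ++p) line[p] = c[base + p * st];
      // causal init (mirror boundary, truncated sum)
      int horiz = std::min(len, 30);
      double sum = line[0];
      double zn = z1;
      for (int p = 1; p < horiz; ++p) { sum += zn * line[p]; zn *= z1; }
      line[0] = sum;
      for (int p = 1; p < len; ++p) line[p] += z1 * line[p - 1];
      // anticausal init
      line[len - 1] = (z1 / (z1 * z1 - 1.0)) * (line[len - 1] + z1 * line[len - 2]);
      for (int p = len - 2; p >= 0; --p) line[p] = z1 * (line[p + 1] - line[p]);
      for (int p = 0; p < len; ++p) c[base + p * st] = 6.0 * line[p];
    }
  }
  return c;
}

static inline void bspline_w(double t, double w[4]) {
  // weights for samples floor(x)-1 .. floor(x)+2, t = frac(x)
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

static inline int mirror_idx(int p, int len) {
  if (len == 1) return 0;
  while (p < 0 || p >= len) {
    if (p < 0) p = -p;
    if (p >= len) p = 2 * (len - 1) - p;
  }
  return p;
}

// ---------------------------------------------------------------------------
// Resample a volume on an output grid via affine map to input continuous
// 0-based indices: ci = M %*% (i,j,k)_out + o.  method: 0 nearest, 1 linear,
// 3 cubic B-spline (vol must then hold prefiltered coefficients).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim,
                                  IntegerVector outdim, NumericMatrix M,
                                  NumericVector o, int method) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2);
  R_xlen_t s = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++s) {
        double x = m00 * i + m01 * j + m02 * k + o[0];
        double y = m10 * i + m11 * j + m12 * k + o[1];
        double z = m20 * i + m21 * j + m22 * k + o[2];
        if (method == 0) {
          int ii = (int)std::lround(x), jj = (int)std::lround(y), kk = (int)std::lround(z);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          out[s] = vol[lin(ii, jj, kk, nx, ny)];
        } else if (method == 1) {
          if (x < -1 || y < -1 || z < -1 || x > nx || y > ny || z > nz) continue;
          int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
          double tx = x - i0, ty = y - j0, tz = z - k0;
          double acc = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
                double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
                acc += w * vol[lin(ii, jj, kk, nx, ny)];
              }
          out[s] = acc;
        } else {
          if (x < -2 || y < -2 || z < -2 || x > nx + 1 || y > ny + 1 || z > nz + 1) continue;
          int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
          double wx[4], wy[4], wz[4];
          bspline_w(x - i0, wx); bspline_w(y - j0, wy); bspline_w(z - k0, wz);
          double acc = 0;
          for (int dk = 0; dk < 4; ++dk) {
            int kk = mirror_idx(k0 - 1 + dk, nz);
            for (int dj = 0; dj < 4; ++dj) {
              int jj = mirror_idx(j0 - 1 + dj, ny);
              double wyz = wy[dj] * wz[dk];
              for (int di = 0; di < 4; ++di) {
                int ii = mirror_idx(i0 - 1 + di, nx);
                acc += wx[di] * wyz * vol[lin(ii, jj, kk, nx, ny)];
              }
            }
          }
          out[s] = acc;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance (voxel units) from each foreground voxel to the
// nearest background voxel (outside the array counts as background).
// Felzenszwalb & Huttenlocher lower-envelope transform per axis.
static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &zb) {
  const int n = (int)f.size();
  int kk = 0;
  v[0] = 0;
  zb[0] = -1e300; zb[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) / (2.0 * q - 2.0 * v[kk]);
      if (s <= zb[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    zb[kk] = s;
    zb[kk + 1] = 1e300;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[kk + 1] < q) ++kk;
    double dq = q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dim, bool border_bg = true) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  // pad: a foreground voxel at the array border is 1 voxel from "outside";
  // handled by adding virtual background at -1 and len.
  const double BIG = 1e300;
  for (R_xlen_t s = 0; s < n; ++s) D[s] = fg[s] ? BIG : 0.0;
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = dims[ax];
    const R_xlen_t st = strides[ax];
    const R_xlen_t nlines = n / len;
    std::vector<double> f(len + 2), d(len + 2), zb(len + 3);
    std::vector<int> v(len + 2);
    for (R_xlen_t L = 0; L < nlines; ++L) {
      R_xlen_t base;
      if (ax == 0) base = L * nx;
      else if (ax == 1) { R_xlen_t i = L % nx, k = L / nx; base = i + (R_xlen_t)nx * ny * k; }
      else base = L;
      // virtual zero-distance sites just outside both ends (array border)
      f[0] = border_bg ? 0.0 : BIG;
      for (int p = 0; p < len; ++p) f[p + 1] = D[base + p * st];
      f[len + 1] = border_bg ? 0.0 : BIG;
      edt1d(f, d, v, zb);
      for (int p = 0; p < len; ++p) D[base + p * st] = d[p + 1];
    }
  }
  return D;
}

// ---------------------------------------------------------------------------
// Local thickness (largest inscribed sphere, Hildebrand & Rueegsegger):
// T(p) = 2 * max{ r(c) : |p - c| <= r(c) }, r = EDT.  Voxel units (diameter).
static NumericVector paint_spheres(const NumericVector &d2, LogicalVector centres,
                                   LogicalVector domain, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector T(n, 0.0);
  std::vector<R_xlen_t> idx;
  for (R_xlen_t s = 0; s < n; ++s) if (centres[s]) idx.push_back(s);
  std::sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) { return d2[a] > d2[b]; });
  const double rmax = std::max(nx, std::max(ny, nz));
  for (R_xlen_t c : idx) {
    double r = std::min(std::sqrt(d2[c]), rmax);
    double r2 = r * r;
    double diam = 2.0 * r;
    int ci = (int)(c % nx), cj = (int)((c / nx) % ny), ck = (int)(c / ((R_xlen_t)nx * ny));
    int ri = (int)std::floor(r);
    for (int dk = -ri; dk <= ri; ++dk) {
      int kk = ck + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -ri; dj <= ri; ++dj) {
        int jj = cj + dj;
        if (jj < 0 || jj >= ny) continue;
        double rem = r2 - (double)dk * dk - (double)dj * dj;
        if (rem < 0) continue;
        int rx = (int)std::floor(std::sqrt(rem));
        int ilo = std::max(0, ci - rx), ihi = std::min(nx - 1, ci + rx);
        R_xlen_t row = lin(ilo, jj, kk, nx, ny);
        for (int ii = ilo; ii <= ihi; ++ii, ++row)
          if (domain[row] && T[row] < diam) T[row] = diam;
      }
    }
  }
  return T;
}

// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector fg, IntegerVector dim) {
  NumericVector d2 = cpp_edt_sq(fg, dim, true);
  return paint_spheres(d2, fg, fg, dim);
}

// Local thickness of a cavity between obstacles: spheres are centred in
// `space`, their radius is the distance to the nearest `obstacle` voxel
// (open/air boundaries do not cap them), values reported over `space`.
// [[Rcpp::export]]
NumericVector cpp_local_thickness_between(LogicalVector space,
                                          LogicalVector obstacle,
                                          IntegerVector dim) {
  const R_xlen_t n = space.size();
  LogicalVector freev(n);
  for (R_xlen_t s = 0; s < n; ++s) freev[s] = !obstacle[s];
  NumericVector d2 = cpp_edt_sq(freev, dim, false);
  return paint_spheres(d2, space, space, dim);
}
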
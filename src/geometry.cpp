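// Low-level voxel geometry kernels: exact anisotropic Euclidean distance
// transform, 3-D connected-component labelling, separable Gaussian
// smoothing, multiscale Hessian tube response, and capsule rasterization.
// All grids are passed as flat vectors in R's column-major layout with an
// explicit dim; spacings are world millimetres per voxel along each axis.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double BIG = 1e15; // finite stand-in for "no seed on this line"

// ---------------------------------------------------------------------------
// Felzenszwalb-Huttenlocher 1-D squared distance transform with sample
// positions i*step (anisotropic voxels handled by per-axis step).
static void dt1d(const std::vector<double>& f, int n, double step,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double qs = q * step, s = 0.0;
    while (true) {
      double ps = v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + ps * ps)) / (2.0 * (qs - ps));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qs = q * step;
    while (z[k + 1] < qs) k++;
    double ps = v[k] * step;
    d[q] = (qs - ps) * (qs - ps) + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel to the nearest seed voxel.
// seeds: logical grid; spacing: mm per voxel along x, y, z.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector seeds, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  // pass 1 along x: two linear sweeps give exact 1-D distance
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      double dprev = BIG;
      for (int i = 0; i < nx; i++) {
        dprev = seeds[base + i] ? 0.0 : std::min(BIG, dprev + spacing[0]);
        g[base + i] = dprev;
      }
      dprev = BIG;
      for (int i = nx - 1; i >= 0; i--) {
        dprev = seeds[base + i] ? 0.0 : std::min(BIG, dprev + spacing[0]);
        if (dprev < g[base + i]) g[base + i] = dprev;
      }
      for (int i = 0; i < nx; i++) {
        double v = g[base + i];
        g[base + i] = (v >= BIG) ? BIG * BIG : v * v;
      }
    }
  }
  // pass 2 along y
  {
    int nmax = std::max(ny, nz);
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);
    for (int k = 0; k < nz; k++) {
      for (int i = 0; i < nx; i++) {
        for (int j = 0; j < ny; j++)
          f[j] = g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        dt1d(f, ny, spacing[1], d, v, z);
        for (int j = 0; j < ny; j++)
          g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
      }
    }
    // pass 3 along z
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++) {
        for (int k = 0; k < nz; k++)
          f[k] = g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        dt1d(f, nz, spacing[2], d, v, z);
        for (int k = 0; k < nz; k++)
          g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
      }
    }
  }
  for (R_xlen_t t = 0; t < n; t++)
    out[t] = (g[t] >= BIG) ? R_PosInf : std::sqrt(g[t]);
  return out;
}

// ---------------------------------------------------------------------------
// Connected components (6- or 26-connectivity), BFS flood fill.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t t = q.front();
      q.pop();
      int i = t % nx, j = (t / nx) % ny, k = t / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; dk++) {
        for (int dj = -1; dj <= 1; dj++) {
          for (int di = -1; di <= 1; di++) {
            int m = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (m == 0) continue;
            if (connectivity == 6 && m > 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[u] && lab[u] == 0) {
              lab[u] = next;
              q.push(u);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with clamp (replicate) boundary handling.
// sigma is in mm; converted per axis using spacing.
static void smooth_axis(std::vector<double>& a, int nx, int ny, int nz,
                        int axis, double sigma_vox) {
  if (sigma_vox <= 0) return;
  int r = (int)std::ceil(3.0 * sigma_vox);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; t++) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma_vox * sigma_vox));
    s += ker[t + r];
  }
  for (double& kv : ker) kv /= s;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), res(len);
  int n0 = axis == 0 ? ny : nx;
  int n1 = axis == 2 ? ny : nz;
  for (int b = 0; b < n1; b++) {
    for (int a0 = 0; a0 < n0; a0++) {
      for (int t = 0; t < len; t++) {
        int i, j, k;
        if (axis == 0) { i = t; j = a0; k = b; }
        else if (axis == 1) { i = a0; j = t; k = b; }
        else { i = a0; j = b; k = t; }
        line[t] = a[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      }
      for (int t = 0; t < len; t++) {
        double acc = 0;
        for (int u = -r; u <= r; u++) {
          int tt = t + u;
          if (tt < 0) tt = 0;
          if (tt >= len) tt = len - 1;
          acc += ker[u + r] * line[tt];
        }
        res[t] = acc;
      }
      for (int t = 0; t < len; t++) {
        int i, j, k;
        if (axis == 0) { i = t; j = a0; k = b; }
        else if (axis == 1) { i = a0; j = t; k = b; }
        else { i = a0; j = b; k = t; }
        a[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = res[t];
      }
    }
  }
}

// [[Rcpp::export(name = ".gaussian_smooth_cpp")]]
NumericVector gaussian_smooth_cpp(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, double sigma_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end());
  smooth_axis(a, nx, ny, nz, 0, sigma_mm / spacing[0]);
  smooth_axis(a, nx, ny, nz, 1, sigma_mm / spacing[1]);
  smooth_axis(a, nx, ny, nz, 2, sigma_mm / spacing[2]);
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// Eigenvalues of a symmetric 3x3 matrix (trigonometric method), ascending.
static void eig3sym(double a11, double a12, double a13, double a22,
                    double a23, double a33, double l[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    l[0] = a11; l[1] = a22; l[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                (a33 - q) * (a33 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23) -
                  b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    double e1 = q + 2.0 * p * std::cos(phi);
    double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    double e2 = 3.0 * q - e1 - e3;
    l[0] = e3; l[1] = e2; l[2] = e1; // ascending
  }
  // sort ascending (p1==0 branch may be unsorted)
  if (l[0] > l[1]) std::swap(l[0], l[1]);
  if (l[1] > l[2]) std::swap(l[1], l[2]);
  if (l[0] > l[1]) std::swap(l[0], l[1]);
}

// Single-scale tube response from a pre-smoothed volume. The Hessian is
// taken by central differences in world units and scale-normalized by
// sigma^2; the classic three-ratio bright-tube measure is returned.
// [[Rcpp::export(name = ".tube_response_cpp")]]
NumericVector tube_response_cpp(NumericVector sm, IntegerVector dim,
                                NumericVector spacing, double sigma_mm,
                                double alpha, double beta, double cnorm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, 0.0);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double s2 = sigma_mm * sigma_mm;
  const double ta = 2.0 * alpha * alpha, tb = 2.0 * beta * beta,
               tc = 2.0 * cnorm * cnorm;
#define V(i, j, k) sm[(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
  for (int k = 1; k < nz - 1; k++) {
    for (int j = 1; j < ny - 1; j++) {
      for (int i = 1; i < nx - 1; i++) {
        double c0 = V(i, j, k);
        double hxx = (V(i + 1, j, k) - 2 * c0 + V(i - 1, j, k)) / (sx * sx);
        double hyy = (V(i, j + 1, k) - 2 * c0 + V(i, j - 1, k)) / (sy * sy);
        double hzz = (V(i, j, k + 1) - 2 * c0 + V(i, j, k - 1)) / (sz * sz);
        double hxy = (V(i + 1, j + 1, k) - V(i + 1, j - 1, k) -
                      V(i - 1, j + 1, k) + V(i - 1, j - 1, k)) /
                     (4 * sx * sy);
        double hxz = (V(i + 1, j, k + 1) - V(i + 1, j, k - 1) -
                      V(i - 1, j, k + 1) + V(i - 1, j, k - 1)) /
                     (4 * sx * sz);
        double hyz = (V(i, j + 1, k + 1) - V(i, j + 1, k - 1) -
                      V(i, j - 1, k + 1) + V(i, j - 1, k - 1)) /
                     (4 * sy * sz);
        double l[3];
        eig3sym(s2 * hxx, s2 * hxy, s2 * hxz, s2 * hyy, s2 * hyz, s2 * hzz, l);
        // order by |lambda|: l1 smallest magnitude
        double a0 = std::fabs(l[0]), a1 = std::fabs(l[1]), a2 = std::fabs(l[2]);
        double lam[3] = {l[0], l[1], l[2]};
        double mag[3] = {a0, a1, a2};
        // insertion sort by magnitude
        for (int u = 1; u < 3; u++) {
          double mv = mag[u], lv = lam[u];
          int w = u - 1;
          while (w >= 0 && mag[w] > mv) {
            mag[w + 1] = mag[w];
            lam[w + 1] = lam[w];
            w--;
          }
          mag[w + 1] = mv;
          lam[w + 1] = lv;
        }
        double l2 = lam[1], l3 = lam[2];
        if (l2 >= 0.0 || l3 >= 0.0) continue; // bright tubes need l2,l3 < 0
        double m2 = std::fabs(l2), m3 = std::fabs(l3), m1 = std::fabs(lam[0]);
        double RA = m2 / m3;
        double RB = m1 / std::sqrt(m2 * m3);
        double S2 = lam[0] * lam[0] + l2 * l2 + l3 * l3;
        double v = (1.0 - std::exp(-RA * RA / ta)) *
                   std::exp(-RB * RB / tb) *
                   (1.0 - std::exp(-S2 / tc));
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = v;
      }
    }
  }
#undef V
  return out;
}

// ---------------------------------------------------------------------------
// Rasterize capsules (finite cylinders with hemispherical caps).
// segs: one row per segment, columns x0 y0 z0 x1 y1 z1 radius (world mm).
// Returns, per voxel, max over segments of (radius - distance to axis):
// >= 0 means inside some capsule. Grid assumed axis-aligned: world =
// origin + index * spacing (0-based indices).
// [[Rcpp::export(name = ".capsule_field_cpp")]]
NumericVector capsule_field_cpp(IntegerVector dim, NumericVector origin,
                                NumericVector spacing, NumericMatrix segs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, -1e9);
  for (int s = 0; s < segs.nrow(); s++) {
    double x0 = segs(s, 0), y0 = segs(s, 1), z0 = segs(s, 2);
    double x1 = segs(s, 3), y1 = segs(s, 4), z1 = segs(s, 5);
    double r = segs(s, 6);
    double pad = r + 2.0 * std::max(spacing[0], std::max(spacing[1], spacing[2]));
    int i0 = std::max(0, (int)std::floor((std::min(x0, x1) - pad - origin[0]) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::ceil((std::max(x0, x1) + pad - origin[0]) / spacing[0]));
    int j0 = std::max(0, (int)std::floor((std::min(y0, y1) - pad - origin[1]) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::ceil((std::max(y0, y1) + pad - origin[1]) / spacing[1]));
    int k0 = std::max(0, (int)std::floor((std::min(z0, z1) - pad - origin[2]) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::ceil((std::max(z0, z1) + pad - origin[2]) / spacing[2]));
    double ax = x1 - x0, ay = y1 - y0, az = z1 - z0;
    double len2 = ax * ax + ay * ay + az * az;
    for (int k = k0; k <= k1; k++) {
      double pz = origin[2] + k * spacing[2];
      for (int j = j0; j <= j1; j++) {
        double py = origin[1] + j * spacing[1];
        for (int i = i0; i <= i1; i++) {
          double px = origin[0] + i * spacing[0];
          double t = 0.0;
          if (len2 > 0)
            t = ((px - x0) * ax + (py - y0) * ay + (pz - z0) * az) / len2;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
          double dx = px - (x0 + t * ax), dy = py - (y0 + t * ay),
                 dz = pz - (z0 + t * az);
          double v = r - std::sqrt(dx * dx + dy * dy + dz * dz);
          R_xlen_t u = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (v > out[u]) out[u] = v;
        }
      }
    }
  }
  return out;
}

// Trilinear sampling of a volume at continuous 0-based voxel coordinates.
// Out-of-field points get `background`.
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericMatrix vox, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = vox.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; p++) {
    double x = vox(p, 0), y = vox(p, 1), z = vox(p, 2);
    if (!(x >= 0 && y >= 0 && z >= 0 && x <= nx - 1 && y <= ny - 1 &&
          z <= nz - 1)) {
      out[p] = background;
      continue;
    }
    int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
    if (i == nx - 1) i--;
    if (j == ny - 1) j--;
    if (k == nz - 1) k--;
    if (nx == 1) i = 0;
    if (ny == 1) j = 0;
    if (nz == 1) k = 0;
    double fx = x - i, fy = y - j, fz = z - k;
    if (nx == 1) fx = 0;
    if (ny == 1) fy = 0;
    if (nz == 1) fz = 0;
    int i2 = std::min(i + 1, nx - 1), j2 = std::min(j + 1, ny - 1),
        k2 = std::min(k + 1, nz - 1);
#define W(ii, jj, kk) vol[(ii) + (R_xlen_t)nx * ((jj) + (R_xlen_t)ny * (kk))]
    double c00 = W(i, j, k) * (1 - fx) + W(i2, j, k) * fx;
    double c10 = W(i, j2, k) * (1 - fx) + W(i2, j2, k) * fx;
    double c01 = W(i, j, k2) * (1 - fx) + W(i2, j, k2) * fx;
    double c11 = W(i, j2, k2) * (1 - fx) + W(i2, j2, k2) * fx;
#undef W
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
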
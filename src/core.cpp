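#include <Rcpp.h>
using namespace Rcpp;

// Mirror (symmetric, edge duplicated) index reflection into [0, n).
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Gaussian-weighted squared patch distance between voxels k and l.
// ringw[d] is the per-element weight for Chebyshev ring d (d = 0..s).
static double patch_dist(const double* img, int nx, int ny, int nz,
                         int kx, int ky, int kz,
                         int lx, int ly, int lz,
                         int s, const double* ringw) {
  double acc = 0.0;
  const int zlo = (nz == 1) ? 0 : -s, zhi = (nz == 1) ? 0 : s;
  for (int dz = zlo; dz <= zhi; ++dz) {
    int kz2 = refl(kz + dz, nz), lz2 = refl(lz + dz, nz);
    int adz = dz < 0 ? -dz : dz;
    for (int dy = -s; dy <= s; ++dy) {
      int ky2 = refl(ky + dy, ny), ly2 = refl(ly + dy, ny);
      int ady = dy < 0 ? -dy : dy;
      int dmax0 = ady > adz ? ady : adz;
      for (int dx = -s; dx <= s; ++dx) {
        int adx = dx < 0 ? -dx : dx;
        int d = adx > dmax0 ? adx : dmax0;
        double a = img[(size_t)kz2 * nx * ny + (size_t)ky2 * nx + refl(kx + dx, nx)];
        double b = img[(size_t)lz2 * nx * ny + (size_t)ly2 * nx + refl(lx + dx, nx)];
        double diff = a - b;
        acc += ringw[d] * diff * diff;
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
double cpp_patch_distance(NumericVector img, IntegerVector dims,
                          IntegerVector k0, IntegerVector l0,
                          int s, NumericVector ringw) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  int kz = k0.size() > 2 ? k0[2] : 0, lz = l0.size() > 2 ? l0[2] : 0;
  return patch_dist(REAL(img), nx, ny, nz, k0[0], k0[1], kz,
                    l0[0], l0[1], lz, s, REAL(ringw));
}

// Nonlocal-means similarity weights and weighted average.
// Search windows are clipped at the image border and renormalized; patches
// use mirror padding. Returns the nonlocal mean; optionally the dense
// per-pixel weight table (small images only).
// [[Rcpp::export]]
List cpp_nlm(NumericVector img, IntegerVector dims, int s, int u, double h,
             NumericVector ringw, bool want_weights) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  size_t N = (size_t)nx * ny * nz;
  const double* x = REAL(img);
  const double* rw = REAL(ringw);
  NumericVector xbar(N);

  int wside = 2 * u + 1;
  int W = (nz == 1) ? wside * wside : wside * wside * wside;
  NumericMatrix wts;
  IntegerMatrix idx;
  if (want_weights) {
    wts = NumericMatrix((int)N, W);
    idx = IntegerMatrix((int)N, W);
  }
  std::vector<double> dist(W);
  std::vector<int> lind(W);

  size_t k = 0;
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky)
      for (int kx = 0; kx < nx; ++kx, ++k) {
        int m = 0;
        double dmin = R_PosInf;
        const int zlo = (nz == 1) ? 0 : std::max(0, kz - u);
        const int zhi = (nz == 1) ? 0 : std::min(nz - 1, kz + u);
        for (int lz = zlo; lz <= zhi; ++lz)
          for (int ly = std::max(0, ky - u); ly <= std::min(ny - 1, ky + u); ++ly)
            for (int lx = std::max(0, kx - u); lx <= std::min(nx - 1, kx + u); ++lx) {
              double d = patch_dist(x, nx, ny, nz, kx, ky, kz, lx, ly, lz, s, rw);
              dist[m] = d;
              lind[m] = lz * nx * ny + ly * nx + lx;
              if (d < dmin) dmin = d;
              ++m;
            }
        // subtract the minimum before exponentiating for numerical safety;
        // cancels in the normalization
        double Z = 0.0, acc = 0.0;
        for (int j = 0; j < m; ++j) {
          double w = std::exp(-(dist[j] - dmin) / h);
          dist[j] = w;
          Z += w;
          acc += w * x[lind[j]];
        }
        xbar[k] = acc / Z;
        if (want_weights)
          for (int j = 0; j < m; ++j) {
            wts((int)k, j) = dist[j] / Z;
            idx((int)k, j) = lind[j] + 1;  // 1-based for R
          }
      }

  if (want_weights)
    return List::create(_["xbar"] = xbar, _["weights"] = wts, _["index"] = idx);
  return List::create(_["xbar"] = xbar);
}

// Per-voxel max and min of the search window of radius u (clipped).
// [[Rcpp::export]]
List cpp_window_range(NumericVector img, IntegerVector dims, int u) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  size_t N = (size_t)nx * ny * nz;
  const double* x = REAL(img);
  NumericVector wmax(N), wmin(N);
  size_t k = 0;
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky)
      for (int kx = 0; kx < nx; ++kx, ++k) {
        double mx = R_NegInf, mn = R_PosInf;
        const int zlo = (nz == 1) ? 0 : std::max(0, kz - u);
        const int zhi = (nz == 1) ? 0 : std::min(nz - 1, kz + u);
        for (int lz = zlo; lz <= zhi; ++lz)
          for (int ly = std::max(0, ky - u); ly <= std::min(ny - 1, ky + u); ++ly)
            for (int lx = std::max(0, kx - u); lx <= std::min(nx - 1, kx + u); ++lx) {
              double v = x[lz * nx * ny + ly * nx + lx];
              if (v > mx) mx = v;
              if (v < mn) mn = v;
            }
        wmax[k] = mx;
        wmin[k] = mn;
      }
  return List::create(_["max"] = wmax, _["min"] = wmin);
}

// Windowed weighted sum (K * field) with mirror padding.
// kernel is the full (2hx+1) x (2hy+1) x (2hz+1) weight array.
// [[Rcpp::export]]
NumericVector cpp_local_weighted_sum(NumericVector field, IntegerVector dims,
                                     NumericVector kernel, IntegerVector khalf) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  int hx = khalf[0], hy = khalf[1], hz = khalf.size() > 2 ? khalf[2] : 0;
  int kx1 = 2 * hx + 1, ky1 = 2 * hy + 1;
  const double* f = REAL(field);
  const double* K = REAL(kernel);
  size_t N = (size_t)nx * ny * nz;
  NumericVector out(N);
  size_t k = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++k) {
        double acc = 0.0;
        for (int dz = -hz; dz <= hz; ++dz) {
          int z2 = refl(z + dz, nz);
          for (int dy = -hy; dy <= hy; ++dy) {
            int y2 = refl(y + dy, ny);
            const double* Krow =
                K + ((size_t)(dz + hz) * ky1 + (dy + hy)) * kx1 + hx;
            const double* frow = f + (size_t)z2 * nx * ny + (size_t)y2 * nx;
            for (int dx = -hx; dx <= hx; ++dx)
              acc += Krow[dx] * frow[refl(x + dx, nx)];
          }
        }
        out[k] = acc;
      }
  return out;
}
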
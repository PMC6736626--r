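#include <Rcpp.h>
using namespace Rcpp;

// Interpolation support shared by resampling, registration and rendering.
// Coordinates are 0-based voxel indices; out-of-field samples return `fill`.
// order 1: trilinear on raw intensities.
// order 3: cubic B-spline; the volume passed in MUST already hold B-spline
//          coefficients (see prefilter3 below). Exact at grid points.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline int mirrori(int v, int n) {
  // whole-sample symmetric reflection, matching the prefilter boundary
  if (n == 1) return 0;
  if (v < 0) v = -v;
  if (v > n - 1) v = 2 * (n - 1) - v;
  return clampi(v, 0, n - 1);
}

static inline void bspline_w(double t, double* w) {
  // cubic B-spline weights for neighbours floor(x)-1 .. floor(x)+2
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

static inline double interp3(const double* v, int nx, int ny, int nz,
                             double x, double y, double z,
                             int order, double fill) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
    return fill;
  if (order == 1) {
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      int zz = clampi(z0 + dz, 0, nz - 1);
      double wz = dz ? fz : 1.0 - fz;
      for (int dy = 0; dy <= 1; ++dy) {
        int yy = clampi(y0 + dy, 0, ny - 1);
        double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          int xx = clampi(x0 + dx, 0, nx - 1);
          double wx = dx ? fx : 1.0 - fx;
          acc += wx * wy * wz * v[xx + nx * (yy + (size_t)ny * zz)];
        }
      }
    }
    return acc;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  bspline_w(x - x0, wx);
  bspline_w(y - y0, wy);
  bspline_w(z - z0, wz);
  double acc = 0.0;
  for (int dz = 0; dz < 4; ++dz) {
    int zz = mirrori(z0 - 1 + dz, nz);
    for (int dy = 0; dy < 4; ++dy) {
      int yy = mirrori(y0 - 1 + dy, ny);
      double wyz = wy[dy] * wz[dz];
      const double* base = v + nx * (yy + (size_t)ny * zz);
      double row = 0.0;
      for (int dx = 0; dx < 4; ++dx)
        row += wx[dx] * base[mirrori(x0 - 1 + dx, nx)];
      acc += wyz * row;
    }
  }
  return acc;
}

// In-place cubic B-spline prefilter along one line (Unser's recursion,
// mirror boundary), pole z1 = sqrt(3) - 2.
static void prefilter_line(double* c, int n, size_t stride) {
  if (n < 2) return;
  const double z1 = -0.26794919243112270647;  // sqrt(3) - 2
  for (int k = 0; k < n; ++k) c[k * stride] *= 6.0;
  // causal init, exact for the mirror-extended (whole-sample symmetric)
  // signal: c+(0) = sum_{k=0}^{2n-3} x~(k) z^k / (1 - z^{2n-2})
  double zn = z1, sum = c[0];
  for (int k = 1; k <= n - 2; ++k) {
    sum += zn * c[k * stride];
    zn *= z1;
  }
  sum += zn * c[(n - 1) * stride];
  zn *= z1;
  for (int k = n - 2; k >= 1; --k) {
    sum += zn * c[k * stride];
    zn *= z1;
  }
  c[0] = sum / (1.0 - zn);
  for (int k = 1; k < n; ++k)
    c[k * stride] += z1 * c[(k - 1) * stride];
  // anticausal init (mirror boundary)
  c[(n - 1) * stride] = (z1 / (z1 * z1 - 1.0)) *
    (c[(n - 1) * stride] + z1 * c[(n - 2) * stride]);
  for (int k = n - 2; k >= 0; --k)
    c[k * stride] = z1 * (c[(k + 1) * stride] - c[k * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_prefilter3(NumericVector vol) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out = clone(vol);
  double* v = out.begin();
  // x lines
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      prefilter_line(v + nx * (j + (size_t)ny * k), nx, 1);
  // y lines
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      prefilter_line(v + i + (size_t)nx * ny * k, ny, nx);
  // z lines
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      prefilter_line(v + i + (size_t)nx * j, nz, (size_t)nx * ny);
  out.attr("dim") = d;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pull_resample(NumericVector vol, NumericMatrix A,
                                int order, double fill) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector src = (order == 3) ? cpp_prefilter3(vol) : vol;
  NumericVector out((size_t)nx * ny * nz);
  const double* v = src.begin();
  double* o = out.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double sx = A(0,0)*i + A(0,1)*j + A(0,2)*k + A(0,3);
        double sy = A(1,0)*i + A(1,1)*j + A(1,2)*k + A(1,3);
        double sz = A(2,0)*i + A(2,1)*j + A(2,2)*k + A(2,3);
        o[idx] = interp3(v, nx, ny, nz, sx, sy, sz, order, fill);
      }
  out.attr("dim") = d;
  return out;
}

// Mean squared difference between ref and the moving volume pulled through
// A, over voxels where mask != 0 (empty mask vector = everywhere), at an
// integer stride. Output voxels within `margin` voxels of the array
// boundary are skipped: at the optimum those are exactly the samples whose
// source can touch fill-contaminated voxels of the moving volume (a rigid
// map preserves the distance to the field-of-view edge). Samples whose
// source falls outside the field are skipped too. For order 3 pass
// B-spline coefficients of the moving volume.
// [[Rcpp::export]]
double cpp_pull_ssd(NumericVector volc, NumericVector ref, NumericMatrix A,
                    int order, IntegerVector mask, int stride,
                    NumericVector margin) {
  IntegerVector d = ref.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  const double* v = volc.begin();
  const double* r = ref.begin();
  const int* m = mask.size() > 0 ? mask.begin() : (const int*)0;
  int mx = (int)margin[0], my = (int)margin[1], mz = (int)margin[2];
  double acc = 0.0;
  size_t n = 0;
  const double NAF = NA_REAL;
  for (int k = mz; k < nz - mz; k += stride)
    for (int j = my; j < ny - my; j += stride)
      for (int i = mx; i < nx - mx; i += stride) {
        size_t idx = i + nx * (j + (size_t)ny * k);
        if (m && !m[idx]) continue;
        double sx = A(0,0)*i + A(0,1)*j + A(0,2)*k + A(0,3);
        double sy = A(1,0)*i + A(1,1)*j + A(1,2)*k + A(1,3);
        double sz = A(2,0)*i + A(2,1)*j + A(2,2)*k + A(2,3);
        double val = interp3(v, nx, ny, nz, sx, sy, sz, order, NAF);
        if (ISNAN(val)) continue;
        double dd = val - r[idx];
        acc += dd * dd;
        ++n;
      }
  if (n == 0) return R_PosInf;
  return acc / (double)n;
}

// Render one slice plane per acquisition sample. For sample s (volume v,
// slice k = slice_k[s], 0-based) the instantaneous source volume is
//   base + sum_r bold(s, r) * amp_r
// and the observed plane is that volume pulled through the sample's rigid
// transform (row s of Amats: a flattened 3x4 pull matrix, column-major).
// For order 3, base and amps must hold B-spline coefficients.
// [[Rcpp::export]]
NumericMatrix cpp_render_planes(NumericVector base, NumericMatrix amps,
                                NumericMatrix bold, IntegerVector slice_k,
                                NumericMatrix Amats, IntegerVector dim3,
                                int order, double fill,
                                IntegerMatrix roi_z) {
  int nx = dim3[0], ny = dim3[1], nz = dim3[2];
  int ns = slice_k.size();
  int nroi = amps.ncol();
  NumericMatrix out(nx * ny, ns);
  const double* b = base.begin();
  const double NAF = NA_REAL;
  for (int s = 0; s < ns; ++s) {
    int k = slice_k[s];
    double a00 = Amats(s,0), a10 = Amats(s,1), a20 = Amats(s,2);
    double a01 = Amats(s,3), a11 = Amats(s,4), a21 = Amats(s,5);
    double a02 = Amats(s,6), a12 = Amats(s,7), a22 = Amats(s,8);
    double b0 = Amats(s,9), b1 = Amats(s,10), b2 = Amats(s,11);
    int p = 0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        double sx = a00*i + a01*j + a02*k + b0;
        double sy = a10*i + a11*j + a12*k + b1;
        double sz = a20*i + a21*j + a22*k + b2;
        double val = interp3(b, nx, ny, nz, sx, sy, sz, order, NAF);
        if (ISNAN(val)) { out(p, s) = fill; continue; }
        for (int r = 0; r < nroi; ++r) {
          double w = bold(s, r);
          // skip ROIs with no support near the sampled plane
          if (w != 0.0 && sz >= roi_z(r, 0) - 3 && sz <= roi_z(r, 1) + 3)
            val += w * interp3(&amps(0, r), nx, ny, nz, sx, sy, sz, order, 0.0);
        }
        out(p, s) = val;
      }
  }
  return out;
}
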
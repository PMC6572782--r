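#include <Rcpp.h>
using namespace Rcpp;

// Separable 1D convolution along one axis of a (nz, ny, nx) column-major
// array with replicate boundary handling. axis: 0 = z, 1 = y, 2 = x.
// Taps are accumulated in full streaming passes so every access is
// sequential in memory.
// [[Rcpp::export]]
NumericVector cpp_filter_axis(NumericVector vol, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const long nz = dims[0], ny = dims[1], nx = dims[2];
  const int nk = kernel.size(), r = (nk - 1) / 2;
  const long sy = nz, sx = nz * ny;
  NumericVector out(vol.size());
  double *o = out.begin();
  const double *v = vol.begin();
  for (int t = 0; t < nk; ++t) {
    const double k = kernel[t];
    if (k == 0.0) continue;
    const long off = t - r;
    for (long x = 0; x < nx; ++x) {
      long xs = axis == 2 ? x + off : x;
      if (xs < 0) xs = 0; else if (xs >= nx) xs = nx - 1;
      for (long y = 0; y < ny; ++y) {
        long ys = axis == 1 ? y + off : y;
        if (ys < 0) ys = 0; else if (ys >= ny) ys = ny - 1;
        double *po = o + y * sy + x * sx;
        const double *pv = v + ys * sy + xs * sx;
        if (axis == 0) {
          for (long z = 0; z < nz; ++z) {
            long zs = z + off;
            if (zs < 0) zs = 0; else if (zs >= nz) zs = nz - 1;
            po[z] += k * pv[zs];
          }
        } else {
          for (long z = 0; z < nz; ++z) po[z] += k * pv[z];
        }
      }
    }
  }
  return out;
}

// Maximum over the 3x3x3 neighbourhood: separable running max per axis,
// edges use the available neighbours only. Streaming passes as above.
// [[Rcpp::export]]
NumericVector cpp_boxmax3(NumericVector vol, IntegerVector dims) {
  const long nz = dims[0], ny = dims[1], nx = dims[2];
  const long sy = nz, sx = nz * ny;
  NumericVector a = clone(vol);
  NumericVector b(no_init(vol.size()));
  for (int axis = 0; axis < 3; ++axis) {
    double *pa = a.begin(), *pb = b.begin();
    if (axis == 0) {
      for (long c = 0; c < ny * nx; ++c) {
        double *col = pa + c * nz, *dst = pb + c * nz;
        for (long z = 0; z < nz; ++z) {
          double m = col[z];
          if (z > 0 && col[z - 1] > m) m = col[z - 1];
          if (z < nz - 1 && col[z + 1] > m) m = col[z + 1];
          dst[z] = m;
        }
      }
    } else {
      const long n_axis = axis == 1 ? ny : nx;
      const long stride = axis == 1 ? sy : sx;
      for (long x = 0; x < nx; ++x) {
        for (long y = 0; y < ny; ++y) {
          const long pos = axis == 1 ? y : x;
          const double *c0 = pa + y * sy + x * sx;
          const double *cm = pos > 0 ? c0 - stride : c0;
          const double *cp = pos < n_axis - 1 ? c0 + stride : c0;
          double *dst = pb + y * sy + x * sx;
          for (long z = 0; z < nz; ++z) {
            double m = c0[z];
            if (cm[z] > m) m = cm[z];
            if (cp[z] > m) m = cp[z];
            dst[z] = m;
          }
        }
      }
    }
    std::swap(a, b);
  }
  return a;
}

// Camera model in one streaming pass: offset + signal + variance-matched
// Gaussian counting noise + Gaussian read noise, rounded and clipped at 0.
// Uses R's RNG so results are reproducible under set.seed().
// Integer counts keep full-geometry stacks at half the memory of doubles.
// [[Rcpp::export]]
IntegerVector cpp_render_camera(NumericVector signal, double offset,
                                double read_var) {
  const R_xlen_t n = signal.size();
  IntegerVector out(no_init(n));
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mu = signal[i] + offset;
    double v = mu + ::norm_rand() * std::sqrt(mu + read_var);
    v = std::nearbyint(v);
    out[i] = v < 0.0 ? 0 : (int)v;
  }
  PutRNGstate();
  return out;
}
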
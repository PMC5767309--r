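#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// half-sample symmetric reflection of an out-of-range index
static inline int reflect_index(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Correlate a 3D volume with a 1D kernel along one axis (0, 1 or 2),
// symmetric boundary extension. vol is in R column-major order with
// dimensions d[0] x d[1] x d[2]; the kernel is centred (odd length).
// [[Rcpp::export(name = ".sep_correlate")]]
NumericVector sep_correlate(NumericVector vol, IntegerVector d,
                            NumericVector kernel, int axis) {
  const int nx = d[0], ny = d[1], nz = d[2];
  const int klen = kernel.size(), r = (klen - 1) / 2;
  NumericVector out(vol.size());
  const double *v = vol.begin();
  double *o = out.begin();
  const double *k = kernel.begin();
  const int n = d[axis];
  // strides in column-major layout
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  const long stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  const int nu = axis == 0 ? ny : nx;
  const int nv = axis == 2 ? ny : nz;
  const long su = axis == 0 ? sy : sx;
  const long sv = axis == 2 ? sy : sz;

  // copy each line into a reflect-padded buffer, then dense products
  std::vector<double> buf(n + 2 * r);
  for (int iv = 0; iv < nv; ++iv) {
    for (int iu = 0; iu < nu; ++iu) {
      const long base = su * iu + sv * iv;
      for (int p = 0; p < n; ++p) buf[r + p] = v[base + stride * p];
      for (int j = 0; j < r; ++j) {
        buf[j] = buf[r + reflect_index(j - r, n)];
        buf[r + n + j] = buf[r + reflect_index(n + j, n)];
      }
      for (int p = 0; p < n; ++p) {
        double acc = 0.0;
        const double *b = buf.data() + p;
        for (int j = 0; j < klen; ++j) acc += k[j] * b[j];
        o[base + stride * p] = acc;
      }
    }
  }
  return out;
}

// Strict local maxima of |stack| over the 3x3x3x3 scale-space
// neighbourhood (80 neighbours, clipped at the borders), restricted to
// masked spatial voxels and |response| >= thr. Ties are broken towards
// the lexicographically smallest linear index (scale-major). stack has
// dimensions nx x ny x nz x ns (column-major); mask holds 1-based
// linear spatial indices.
// [[Rcpp::export(name = ".scale_space_maxima")]]
DataFrame scale_space_maxima(NumericVector stack, IntegerVector d,
                             IntegerVector mask, double thr) {
  const int nx = d[0], ny = d[1], nz = d[2], ns = d[3];
  const long svox = (long)nx * ny * nz;
  const double *v = stack.begin();
  std::vector<int> bx, by, bz, bs;
  std::vector<double> resp;
  for (R_xlen_t mi = 0; mi < mask.size(); ++mi) {
    long lin = (long)mask[mi] - 1;  // spatial linear index, 0-based
    int x = lin % nx, y = (lin / nx) % ny, z = lin / ((long)nx * ny);
    for (int s = 0; s < ns; ++s) {
      long idx = lin + svox * s;
      double a = std::fabs(v[idx]);
      if (a < thr) continue;
      // global tie-break order: scale-major then z, y, x
      long my_key = ((long)s * nz + z); my_key = (my_key * ny + y) * nx + x;
      bool is_max = true;
      for (int ds = -1; ds <= 1 && is_max; ++ds) {
        int s2 = s + ds; if (s2 < 0 || s2 >= ns) continue;
        for (int dz = -1; dz <= 1 && is_max; ++dz) {
          int z2 = z + dz; if (z2 < 0 || z2 >= nz) continue;
          for (int dy = -1; dy <= 1 && is_max; ++dy) {
            int y2 = y + dy; if (y2 < 0 || y2 >= ny) continue;
            for (int dx = -1; dx <= 1 && is_max; ++dx) {
              if (ds == 0 && dz == 0 && dy == 0 && dx == 0) continue;
              int x2 = x + dx; if (x2 < 0 || x2 >= nx) continue;
              long idx2 = (long)x2 + (long)nx * (y2 + (long)ny * z2) +
                          svox * s2;
              double b = std::fabs(v[idx2]);
              if (b > a) { is_max = false; }
              else if (b == a) {
                long key2 = ((long)s2 * nz + z2);
                key2 = (key2 * ny + y2) * nx + x2;
                if (key2 < my_key) is_max = false;
              }
            }
          }
        }
      }
      if (is_max) {
        bx.push_back(x + 1); by.push_back(y + 1); bz.push_back(z + 1);
        bs.push_back(s + 1); resp.push_back(v[idx]);
      }
    }
  }
  return DataFrame::create(_["x"] = bx, _["y"] = by, _["z"] = bz,
                           _["scale_index"] = bs, _["response"] = resp);
}

// max |stack| over masked voxels, all scales
// [[Rcpp::export(name = ".masked_abs_max")]]
double masked_abs_max(NumericVector stack, IntegerVector d,
                      IntegerVector mask) {
  const long svox = (long)d[0] * d[1] * d[2];
  const int ns = d[3];
  const double *v = stack.begin();
  double mx = 0.0;
  for (R_xlen_t mi = 0; mi < mask.size(); ++mi) {
    long lin = (long)mask[mi] - 1;
    for (int s = 0; s < ns; ++s) {
      double a = std::fabs(v[lin + svox * s]);
      if (a > mx) mx = a;
    }
  }
  return mx;
}
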
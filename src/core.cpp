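#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Low-level image primitives for 3D fluorescence stacks stored as R arrays
// with dim = (ny, nx, nz): first index y (rows), second x (columns), third z
// (slices). All coordinates are 0-based internally and converted at the R
// interface.

// ---------------------------------------------------------------------------
// Running min/max filter along one axis of a 3D array (flat structuring
// segment). Window spans [i - w_before, i + w_after]; positions outside the
// array are ignored (equivalent to padding with +Inf for min / -Inf for max),
// which is the standard border rule for grey erosion/dilation.
// [[Rcpp::export]]
NumericVector cpp_minmax_filter_axis(NumericVector x, IntegerVector dim,
                                     int axis, int w_before, int w_after,
                                     bool do_max) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  NumericVector out(x.size());
  // strides for axis traversal in column-major (y fastest)
  const long sy = 1, sx = (long)ny, sz = (long)ny * nx;
  long stride, len, n_outer1, s_outer1, n_outer2, s_outer2;
  if (axis == 0) {        // along y
    stride = sy; len = ny; n_outer1 = nx; s_outer1 = sx; n_outer2 = nz; s_outer2 = sz;
  } else if (axis == 1) { // along x
    stride = sx; len = nx; n_outer1 = ny; s_outer1 = sy; n_outer2 = nz; s_outer2 = sz;
  } else {                // along z
    stride = sz; len = nz; n_outer1 = ny; s_outer1 = sy; n_outer2 = nx; s_outer2 = sx;
  }
  for (long o2 = 0; o2 < n_outer2; ++o2) {
    for (long o1 = 0; o1 < n_outer1; ++o1) {
      const long base = o1 * s_outer1 + o2 * s_outer2;
      for (long i = 0; i < len; ++i) {
        long lo = i - w_before; if (lo < 0) lo = 0;
        long hi = i + w_after;  if (hi > len - 1) hi = len - 1;
        double v = x[base + lo * stride];
        for (long j = lo + 1; j <= hi; ++j) {
          double xv = x[base + j * stride];
          if (do_max ? (xv > v) : (xv < v)) v = xv;
        }
        out[base + i * stride] = v;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable lower-envelope passes over the three axes. Input: integer mask
// (0 = background); output: squared distance to nearest background voxel,
// in voxel units (anisotropy deliberately ignored).

static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(IntegerVector mask, IntegerVector dim) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const long n = (long)ny * nx * nz;
  const double INF = 1e30;
  std::vector<double> d(n);
  for (long i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  int maxlen = std::max(ny, std::max(nx, nz));
  std::vector<double> f(maxlen), dd(maxlen), z(maxlen + 1);
  std::vector<int> v(maxlen);
  const long sy = 1, sx = (long)ny, sz = (long)ny * nx;
  // pass along y
  for (int zi = 0; zi < nz; ++zi)
    for (int xi = 0; xi < nx; ++xi) {
      long base = xi * sx + zi * sz;
      f.assign(ny, 0.0);
      for (int yi = 0; yi < ny; ++yi) f[yi] = d[base + yi * sy];
      dd.resize(ny); edt_1d(f, dd, v, z);
      for (int yi = 0; yi < ny; ++yi) d[base + yi * sy] = dd[yi];
    }
  // pass along x
  for (int zi = 0; zi < nz; ++zi)
    for (int yi = 0; yi < ny; ++yi) {
      long base = yi * sy + zi * sz;
      f.assign(nx, 0.0);
      for (int xi = 0; xi < nx; ++xi) f[xi] = d[base + xi * sx];
      dd.resize(nx); edt_1d(f, dd, v, z);
      for (int xi = 0; xi < nx; ++xi) d[base + xi * sx] = dd[xi];
    }
  // pass along z
  for (int xi = 0; xi < nx; ++xi)
    for (int yi = 0; yi < ny; ++yi) {
      long base = yi * sy + xi * sx;
      f.assign(nz, 0.0);
      for (int zi = 0; zi < nz; ++zi) f[zi] = d[base + zi * sz];
      dd.resize(nz); edt_1d(f, dd, v, z);
      for (int zi = 0; zi < nz; ++zi) d[base + zi * sz] = dd[zi];
    }
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = d[i];
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a 2D binary matrix (ny x nx), 4- or
// 8-connectivity, BFS flood fill. Labels 1..K in raster-scan discovery order.
// [[Rcpp::export]]
IntegerVector cpp_label2d(IntegerVector mask, int ny, int nx, int connectivity) {
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = IntegerVector::create(ny, nx);
  int next = 0;
  std::vector<long> stack;
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  for (int xi = 0; xi < nx; ++xi)
    for (int yi = 0; yi < ny; ++yi) {
      long idx = yi + (long)xi * ny;
      if (!mask[idx] || lab[idx]) continue;
      ++next;
      lab[idx] = next;
      stack.push_back(idx);
      while (!stack.empty()) {
        long cur = stack.back(); stack.pop_back();
        int cy = (int)(cur % ny), cx = (int)(cur / ny);
        for (int k = 0; k < nn; ++k) {
          int yy = cy + dy8[k], xx = cx + dx8[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          long nidx = yy + (long)xx * ny;
          if (mask[nidx] && !lab[nidx]) { lab[nidx] = next; stack.push_back(nidx); }
        }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a 3D binary array, 6- or 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim, int connectivity) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dim;
  const long sy = 1, sx = (long)ny, sz = (long)ny * nx;
  std::vector<int> dys, dxs, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manh = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dys.push_back(dy); dxs.push_back(dx); dzs.push_back(dz);
      }
  int next = 0;
  std::vector<long> stack;
  for (int zi = 0; zi < nz; ++zi)
    for (int xi = 0; xi < nx; ++xi)
      for (int yi = 0; yi < ny; ++yi) {
        long idx = yi * sy + xi * sx + zi * sz;
        if (!mask[idx] || lab[idx]) continue;
        ++next;
        lab[idx] = next;
        stack.push_back(idx);
        while (!stack.empty()) {
          long cur = stack.back(); stack.pop_back();
          int cy = (int)(cur % ny);
          int cx = (int)((cur / ny) % nx);
          int cz = (int)(cur / ((long)ny * nx));
          for (size_t k = 0; k < dys.size(); ++k) {
            int yy = cy + dys[k], xx = cx + dxs[k], zz = cz + dzs[k];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            long nidx = yy * sy + xx * sx + zz * sz;
            if (mask[nidx] && !lab[nidx]) { lab[nidx] = next; stack.push_back(nidx); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Grey erosion/dilation of a 2D image with a non-flat spherical-cap
// structuring element of the given radius (the "rolling ball"). Border rule:
// offsets falling outside the image are ignored.
// [[Rcpp::export]]
NumericMatrix cpp_ball_morph2d(NumericMatrix img, double radius, bool do_dilate) {
  const int ny = img.nrow(), nx = img.ncol();
  const int r = (int)std::floor(radius);
  // precompute structuring-element heights b(dy,dx) = sqrt(r^2 - d^2) - r  (<= 0)
  std::vector<int> oy, ox;
  std::vector<double> oh;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      double d2 = (double)dy * dy + (double)dx * dx;
      if (d2 > radius * radius) continue;
      oy.push_back(dy); ox.push_back(dx);
      oh.push_back(std::sqrt(radius * radius - d2) - radius);
    }
  NumericMatrix out(ny, nx);
  for (int xi = 0; xi < nx; ++xi)
    for (int yi = 0; yi < ny; ++yi) {
      double v = do_dilate ? -std::numeric_limits<double>::infinity()
                           : std::numeric_limits<double>::infinity();
      for (size_t k = 0; k < oy.size(); ++k) {
        int yy = yi + oy[k], xx = xi + ox[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        double cand = do_dilate ? img(yy, xx) + oh[k] : img(yy, xx) - oh[k];
        if (do_dilate ? (cand > v) : (cand < v)) v = cand;
      }
      out(yi, xi) = v;
    }
  return out;
}
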
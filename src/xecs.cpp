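// Compiled kernels for non-Cartesian gridding and small image utilities.
// Kaiser-Bessel interpolation/spreading is written as an exact
// transpose pair so the NUFFT forward/adjoint satisfy the dot-product
// test to rounding error.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int wrap_index(int g, int n) {
  int r = g % n;
  return (r < 0) ? r + n : r;
}

// Kaiser-Bessel window, normalized to 1 at u = 0; zero for |u| > width/2.
static inline double kb_val(double u, double halfw, double beta,
                            double i0beta) {
  double t = u / halfw;
  double s = 1.0 - t * t;
  if (s < 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(s), 0.0, 1.0) / i0beta;
}

// [[Rcpp::export]]
NumericVector cpp_kb_window(NumericVector u, double width, double beta) {
  const double halfw = width / 2.0;
  const double i0beta = R::bessel_i(beta, 0.0, 1.0);
  NumericVector out(u.size());
  for (R_xlen_t i = 0; i < u.size(); ++i)
    out[i] = kb_val(u[i], halfw, beta, i0beta);
  return out;
}

// Fine lookup table of the window over [0, halfw]; interpolation and
// spreading share it, so the operator pair stays an exact transpose.
#define KB_TABLE_N 4096
struct KbTable {
  double halfw, step;
  std::vector<double> v;
  KbTable(double width, double beta)
      : halfw(width / 2.0), step(halfw / (KB_TABLE_N - 1)),
        v(KB_TABLE_N + 1) {
    const double i0beta = R::bessel_i(beta, 0.0, 1.0);
    for (int i = 0; i < KB_TABLE_N; ++i)
      v[i] = kb_val(i * step, halfw, beta, i0beta);
    v[KB_TABLE_N] = 0.0;
  }
  inline double operator()(double u) const {
    const double a = std::fabs(u);
    if (a >= halfw) return 0.0;
    const double x = a / step;
    const int i = (int)x;
    const double f = x - i;
    return v[i] * (1.0 - f) + v[i + 1] * f;
  }
};

// Sample an oversampled Cartesian k-space grid at arbitrary coordinates
// (coords in 0-based grid units, DC at dim/2) by Kaiser-Bessel
// convolution interpolation with periodic wrap.
// [[Rcpp::export]]
ComplexVector cpp_kb_interp(NumericMatrix coords, ComplexVector grid,
                            IntegerVector dim, double width, double beta) {
  const int n = coords.nrow();
  const int gx = dim[0], gy = dim[1], gz = dim[2];
  const double halfw = width / 2.0;
  const KbTable kb(width, beta);
  ComplexVector out(n);
  const int maxw = (int)width + 3;
  std::vector<double> wx(maxw), wy(maxw), wz(maxw);
  std::vector<int> ix(maxw), iy(maxw), iz(maxw);
  for (int j = 0; j < n; ++j) {
    const double ux = coords(j, 0), uy = coords(j, 1), uz = coords(j, 2);
    const int lx = (int)std::ceil(ux - halfw), hx = (int)std::floor(ux + halfw);
    const int ly = (int)std::ceil(uy - halfw), hy = (int)std::floor(uy + halfw);
    const int lz = (int)std::ceil(uz - halfw), hz = (int)std::floor(uz + halfw);
    const int nx = hx - lx + 1, ny = hy - ly + 1, nz = hz - lz + 1;
    for (int a = 0; a < nx; ++a) {
      wx[a] = kb(lx + a - ux);
      ix[a] = wrap_index(lx + a, gx);
    }
    for (int a = 0; a < ny; ++a) {
      wy[a] = kb(ly + a - uy);
      iy[a] = wrap_index(ly + a, gy);
    }
    for (int a = 0; a < nz; ++a) {
      wz[a] = kb(lz + a - uz);
      iz[a] = wrap_index(lz + a, gz);
    }
    double sr = 0.0, si = 0.0;
    for (int c = 0; c < nz; ++c) {
      const double wzz = wz[c];
      const R_xlen_t offz = (R_xlen_t)iz[c] * gx * gy;
      for (int b = 0; b < ny; ++b) {
        const double wyz = wy[b] * wzz;
        const R_xlen_t offyz = offz + (R_xlen_t)iy[b] * gx;
        for (int a = 0; a < nx; ++a) {
          const double w = wx[a] * wyz;
          const Rcomplex v = grid[offyz + ix[a]];
          sr += w * v.r;
          si += w * v.i;
        }
      }
    }
    out[j].r = sr;
    out[j].i = si;
  }
  return out;
}

// Exact transpose of cpp_kb_interp: spread non-Cartesian samples onto
// the oversampled Cartesian grid.
// [[Rcpp::export]]
ComplexVector cpp_kb_spread(NumericMatrix coords, ComplexVector vals,
                            IntegerVector dim, double width, double beta) {
  const int n = coords.nrow();
  const int gx = dim[0], gy = dim[1], gz = dim[2];
  const double halfw = width / 2.0;
  const KbTable kb(width, beta);
  const R_xlen_t ng = (R_xlen_t)gx * gy * gz;
  std::vector<double> gre(ng, 0.0), gim(ng, 0.0);
  const int maxw = (int)width + 3;
  std::vector<double> wx(maxw), wy(maxw), wz(maxw);
  std::vector<int> ix(maxw), iy(maxw), iz(maxw);
  for (int j = 0; j < n; ++j) {
    const double ux = coords(j, 0), uy = coords(j, 1), uz = coords(j, 2);
    const int lx = (int)std::ceil(ux - halfw), hx = (int)std::floor(ux + halfw);
    const int ly = (int)std::ceil(uy - halfw), hy = (int)std::floor(uy + halfw);
    const int lz = (int)std::ceil(uz - halfw), hz = (int)std::floor(uz + halfw);
    const int nx = hx - lx + 1, ny = hy - ly + 1, nz = hz - lz + 1;
    for (int a = 0; a < nx; ++a) {
      wx[a] = kb(lx + a - ux);
      ix[a] = wrap_index(lx + a, gx);
    }
    for (int a = 0; a < ny; ++a) {
      wy[a] = kb(ly + a - uy);
      iy[a] = wrap_index(ly + a, gy);
    }
    for (int a = 0; a < nz; ++a) {
      wz[a] = kb(lz + a - uz);
      iz[a] = wrap_index(lz + a, gz);
    }
    const double vr = vals[j].r, vi = vals[j].i;
    for (int c = 0; c < nz; ++c) {
      const double wzz = wz[c];
      const R_xlen_t offz = (R_xlen_t)iz[c] * gx * gy;
      for (int b = 0; b < ny; ++b) {
        const double wyz = wy[b] * wzz;
        const R_xlen_t offyz = offz + (R_xlen_t)iy[b] * gx;
        for (int a = 0; a < nx; ++a) {
          const double w = wx[a] * wyz;
          gre[offyz + ix[a]] += w * vr;
          gim[offyz + ix[a]] += w * vi;
        }
      }
    }
  }
  ComplexVector out(ng);
  for (R_xlen_t i = 0; i < ng; ++i) {
    out[i].r = gre[i];
    out[i].i = gim[i];
  }
  return out;
}

// 6-connectivity connected-component labelling of a 3D logical mask.
// Labels are 1..n_components in discovery order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      const int x = cur % nx;
      const int y = (cur / nx) % ny;
      const int z = cur / ((R_xlen_t)nx * ny);
      for (int d = 0; d < 6; ++d) {
        const int x2 = x + dxs[d], y2 = y + dys[d], z2 = z + dzs[d];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        const R_xlen_t idx = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next_label;
          stack.push_back(idx);
        }
      }
    }
  }
  return labels;
}

// Brute-force nearest-site assignment (used by the discrete Voronoi
// density-compensation estimate). Returns 1-based site index per query.
// [[Rcpp::export]]
IntegerVector cpp_nearest_site(NumericMatrix sites, NumericMatrix queries) {
  const int ns = sites.nrow(), nq = queries.nrow();
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const double qx = queries(q, 0), qy = queries(q, 1), qz = queries(q, 2);
    double best = R_PosInf;
    int besti = 1;
    for (int s = 0; s < ns; ++s) {
      const double dx = sites(s, 0) - qx;
      const double dy = sites(s, 1) - qy;
      const double dz = sites(s, 2) - qz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) {
        best = d;
        besti = s + 1;
      }
    }
    out[q] = besti;
  }
  return out;
}
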
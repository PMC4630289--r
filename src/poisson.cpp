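// Indicator-function (Poisson) reconstruction on a regular grid:
// trilinear splatting of oriented normals, separable Gaussian smoothing,
// central-difference divergence, and a matrix-free conjugate-gradient
// solve of the Neumann-Laplace system.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Splat per-point unit normals into a collocated vector field with
// trilinear weights. Grid node (i,j,k) sits at origin + spacing*(i,j,k).
// [[Rcpp::export]]
List cpp_splat_normals(NumericMatrix points, NumericMatrix normals,
                       IntegerVector dims, NumericVector origin,
                       double spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  NumericVector vx(ncell), vy(ncell), vz(ncell);
  int n = points.nrow();
  for (int p = 0; p < n; ++p) {
    double gx = (points(p, 0) - origin[0]) / spacing;
    double gy = (points(p, 1) - origin[1]) / spacing;
    double gz = (points(p, 2) - origin[2]) / spacing;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          int i = i0 + di, j = j0 + dj, k = k0 + dk;
          if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          R_xlen_t id = idx3(i, j, k, nx, ny);
          vx[id] += w * normals(p, 0);
          vy[id] += w * normals(p, 1);
          vz[id] += w * normals(p, 2);
        }
  }
  return List::create(_["vx"] = vx, _["vy"] = vy, _["vz"] = vz);
}

static void smooth_axis(std::vector<double>& f, int nx, int ny, int nz,
                        const std::vector<double>& kern, int axis) {
  int rad = ((int)kern.size() - 1) / 2;
  std::vector<double> out(f.size());
  int n[3] = { nx, ny, nz };
  int stride[3] = { 1, nx, nx * ny };
  int na = n[axis], sa = stride[axis];
  // iterate over all lines along `axis`
  int nb = (axis == 0) ? ny : nx;
  int nc = (axis == 2) ? ny : nz;
  int sb = (axis == 0) ? stride[1] : stride[0];
  int sc = (axis == 2) ? stride[1] : stride[2];
  for (int c = 0; c < nc; ++c)
    for (int b = 0; b < nb; ++b) {
      R_xlen_t base = (R_xlen_t)b * sb + (R_xlen_t)c * sc;
      for (int a = 0; a < na; ++a) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t) {
          int aa = a + t;
          if (aa < 0) aa = 0;          // clamp: consistent with Neumann edges
          if (aa >= na) aa = na - 1;
          acc += kern[t + rad] * f[base + (R_xlen_t)aa * sa];
        }
        out[base + (R_xlen_t)a * sa] = acc;
      }
    }
  f.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_smooth_field(NumericVector field, IntegerVector dims,
                               double sigma_cells) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> f(field.begin(), field.end());
  if (sigma_cells > 0) {
    int rad = std::max(1, (int)std::ceil(3.0 * sigma_cells));
    std::vector<double> kern(2 * rad + 1);
    double s = 0.0;
    for (int t = -rad; t <= rad; ++t) {
      kern[t + rad] = std::exp(-0.5 * (t * t) / (sigma_cells * sigma_cells));
      s += kern[t + rad];
    }
    for (double& k : kern) k /= s;
    smooth_axis(f, nx, ny, nz, kern, 0);
    smooth_axis(f, nx, ny, nz, kern, 1);
    smooth_axis(f, nx, ny, nz, kern, 2);
  }
  return NumericVector(f.begin(), f.end());
}

// Central-difference divergence (one-sided at boundaries), spacing h.
// [[Rcpp::export]]
NumericVector cpp_divergence(NumericVector vx, NumericVector vy,
                             NumericVector vz, IntegerVector dims, double h) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  NumericVector div(ncell);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = idx3(i, j, k, nx, ny);
        double dx, dy, dz;
        if (i == 0) dx = (vx[idx3(1, j, k, nx, ny)] - vx[id]) / h;
        else if (i == nx - 1) dx = (vx[id] - vx[idx3(nx - 2, j, k, nx, ny)]) / h;
        else dx = (vx[idx3(i + 1, j, k, nx, ny)] - vx[idx3(i - 1, j, k, nx, ny)]) / (2 * h);
        if (j == 0) dy = (vy[idx3(i, 1, k, nx, ny)] - vy[id]) / h;
        else if (j == ny - 1) dy = (vy[id] - vy[idx3(i, ny - 2, k, nx, ny)]) / h;
        else dy = (vy[idx3(i, j + 1, k, nx, ny)] - vy[idx3(i, j - 1, k, nx, ny)]) / (2 * h);
        if (k == 0) dz = (vz[idx3(i, j, 1, nx, ny)] - vz[id]) / h;
        else if (k == nz - 1) dz = (vz[id] - vz[idx3(i, j, nz - 2, nx, ny)]) / h;
        else dz = (vz[idx3(i, j, k + 1, nx, ny)] - vz[idx3(i, j, k - 1, nx, ny)]) / (2 * h);
        div[id] = dx + dy + dz;
      }
  return div;
}

// Apply the (negated) Neumann graph Laplacian: (A x)_c = sum_nb (x_c - x_nb).
static void apply_laplacian(const std::vector<double>& x, std::vector<double>& ax,
                            int nx, int ny, int nz) {
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = idx3(i, j, k, nx, ny);
        double xc = x[id], acc = 0.0;
        if (i > 0)      acc += xc - x[id - 1];
        if (i < nx - 1) acc += xc - x[id + 1];
        if (j > 0)      acc += xc - x[id - nx];
        if (j < ny - 1) acc += xc - x[id + nx];
        if (k > 0)      acc += xc - x[id - (R_xlen_t)nx * ny];
        if (k < nz - 1) acc += xc - x[id + (R_xlen_t)nx * ny];
        ax[id] = acc;
      }
}

// Solve Laplacian(chi) = rhs (Neumann) by CG on the semidefinite system;
// rhs is projected onto zero mean so the system is consistent.
// rhs here is h^2 * divergence (the h^2 scaling folds into the stencil).
// [[Rcpp::export]]
List cpp_cg_poisson(NumericVector rhs, IntegerVector dims, double tol,
                    int max_iter) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> b(rhs.begin(), rhs.end());
  double mean_b = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) mean_b += b[i];
  mean_b /= (double)n;
  for (R_xlen_t i = 0; i < n; ++i) b[i] -= mean_b;

  std::vector<double> x(n, 0.0), r(b), p(b), ap(n);
  double rr = 0.0, bnorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) { rr += r[i] * r[i]; bnorm += b[i] * b[i]; }
  bnorm = std::sqrt(bnorm);
  double target = tol * (bnorm > 0 ? bnorm : 1.0);
  int it = 0;
  for (; it < max_iter; ++it) {
    if (std::sqrt(rr) <= target) break;
    apply_laplacian(p, ap, nx, ny, nz);
    double pap = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) pap += p[i] * ap[i];
    if (pap <= 0) break; // p in the null space: done
    double alpha = rr / pap;
    double rr_new = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * ap[i];
      rr_new += r[i] * r[i];
    }
    double beta = rr_new / rr;
    rr = rr_new;
    for (R_xlen_t i = 0; i < n; ++i) p[i] = r[i] + beta * p[i];
  }
  double mean_x = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) mean_x += x[i];
  mean_x /= (double)n;
  for (R_xlen_t i = 0; i < n; ++i) x[i] -= mean_x;
  NumericVector out(x.begin(), x.end());
  return List::create(_["chi"] = out, _["iterations"] = it,
                      _["residual"] = std::sqrt(rr));
}

// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector field, IntegerVector dims,
                                   NumericVector origin, double spacing,
                                   NumericMatrix points) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = points.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double gx = (points(p, 0) - origin[0]) / spacing;
    double gy = (points(p, 1) - origin[1]) / spacing;
    double gz = (points(p, 2) - origin[2]) / spacing;
    gx = std::min(std::max(gx, 0.0), nx - 1.000001);
    gy = std::min(std::max(gy, 0.0), ny - 1.000001);
    gz = std::min(std::max(gz, 0.0), nz - 1.000001);
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          acc += w * field[idx3(i0 + di, j0 + dj, k0 + dk, nx, ny)];
        }
    out[p] = acc;
  }
  return out;
}
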
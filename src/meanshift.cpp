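#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Density grid convention: values is an R array (column-major) of dim (nx,ny,nz);
// voxel (i,j,k), 0-based here, sits at origin + (i,j,k)*spacing (Angstrom).

static inline double kern(double r2, double sigma) {
  return std::exp(-1.5 * r2 / (sigma * sigma));
}

// One full mean-shift sweep (Gaussian kernel, weighted by grid density).
// Returns an M x 4 matrix: updated x,y,z and the kernel-weighted denominator.
// A zero denominator marks a dead seed (no density support within the cutoff).
// [[Rcpp::export]]
NumericMatrix ms_sweep_cpp(NumericVector values, IntegerVector dim,
                           NumericVector origin, NumericVector spacing,
                           NumericMatrix pos, double sigma, double cutoff) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = pos.nrow();
  const double c2 = cutoff * cutoff;
  NumericMatrix out(m, 4);
  for (int s = 0; s < m; ++s) {
    double y0 = pos(s, 0), y1 = pos(s, 1), y2 = pos(s, 2);
    int lo[3], hi[3];
    double yy[3] = {y0, y1, y2};
    for (int a = 0; a < 3; ++a) {
      int l = (int)std::ceil((yy[a] - cutoff - origin[a]) / spacing[a]);
      int h = (int)std::floor((yy[a] + cutoff - origin[a]) / spacing[a]);
      int dmax = (a == 0 ? nx : (a == 1 ? ny : nz)) - 1;
      lo[a] = l < 0 ? 0 : l;
      hi[a] = h > dmax ? dmax : h;
    }
    double num0 = 0, num1 = 0, num2 = 0, den = 0;
    for (int k = lo[2]; k <= hi[2]; ++k) {
      double pz = origin[2] + k * spacing[2], dz = pz - y2;
      for (int j = lo[1]; j <= hi[1]; ++j) {
        double py = origin[1] + j * spacing[1], dy = py - y1;
        double dzy = dz * dz + dy * dy;
        if (dzy > c2) continue;
        const double *col = &values[(R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double phi = col[i];
          if (phi <= 0) continue;
          double px = origin[0] + i * spacing[0], dx = px - y0;
          double r2 = dzy + dx * dx;
          if (r2 > c2) continue;
          double w = kern(r2, sigma) * phi;
          num0 += w * px; num1 += w * py; num2 += w * pz;
          den += w;
        }
      }
    }
    if (den > 0) {
      out(s, 0) = num0 / den; out(s, 1) = num1 / den; out(s, 2) = num2 / den;
    } else {
      out(s, 0) = y0; out(s, 1) = y1; out(s, 2) = y2;
    }
    out(s, 3) = den;
  }
  return out;
}

// Kernel density estimate Theta(y) = (1/N) sum_n k(y - x_n) Phi(x_n),
// with the same cutoff as the mean-shift update.
// [[Rcpp::export]]
NumericVector ms_theta_cpp(NumericVector values, IntegerVector dim,
                           NumericVector origin, NumericVector spacing,
                           NumericMatrix pos, double sigma, double cutoff) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = pos.nrow();
  const double c2 = cutoff * cutoff;
  const double nvox = (double)nx * ny * nz;
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    double y0 = pos(s, 0), y1 = pos(s, 1), y2 = pos(s, 2);
    int lo[3], hi[3];
    double yy[3] = {y0, y1, y2};
    for (int a = 0; a < 3; ++a) {
      int l = (int)std::ceil((yy[a] - cutoff - origin[a]) / spacing[a]);
      int h = (int)std::floor((yy[a] + cutoff - origin[a]) / spacing[a]);
      int dmax = (a == 0 ? nx : (a == 1 ? ny : nz)) - 1;
      lo[a] = l < 0 ? 0 : l;
      hi[a] = h > dmax ? dmax : h;
    }
    double acc = 0;
    for (int k = lo[2]; k <= hi[2]; ++k) {
      double dz = origin[2] + k * spacing[2] - y2;
      for (int j = lo[1]; j <= hi[1]; ++j) {
        double dy = origin[1] + j * spacing[1] - y1;
        double dzy = dz * dz + dy * dy;
        if (dzy > c2) continue;
        const double *col = &values[(R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double phi = col[i];
          if (phi <= 0) continue;
          double dx = origin[0] + i * spacing[0] - y0;
          double r2 = dzy + dx * dx;
          if (r2 > c2) continue;
          acc += kern(r2, sigma) * phi;
        }
      }
    }
    out[s] = acc / nvox;
  }
  return out;
}
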
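#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a zero-padded volume at continuous 0-based voxel
// coordinates (x, y, z).  Optionally also returns the spatial gradient
// with respect to the voxel coordinates.
static inline double trilinear(const double* vol, int d1, int d2, int d3,
                               double x, double y, double z,
                               bool want_grad, double* grad) {
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)d1 || y >= (double)d2 || z >= (double)d3) {
    if (want_grad) { grad[0] = grad[1] = grad[2] = 0.0; }
    return 0.0;
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double c[2][2][2];
  for (int di = 0; di < 2; ++di) {
    int ii = i0 + di;
    for (int dj = 0; dj < 2; ++dj) {
      int jj = j0 + dj;
      for (int dk = 0; dk < 2; ++dk) {
        int kk = k0 + dk;
        double v = 0.0;
        if (ii >= 0 && ii < d1 && jj >= 0 && jj < d2 && kk >= 0 && kk < d3)
          v = vol[ii + (size_t)d1 * (jj + (size_t)d2 * kk)];
        c[di][dj][dk] = v;
      }
    }
  }
  double c00 = c[0][0][0] * (1 - fx) + c[1][0][0] * fx;
  double c10 = c[0][1][0] * (1 - fx) + c[1][1][0] * fx;
  double c01 = c[0][0][1] * (1 - fx) + c[1][0][1] * fx;
  double c11 = c[0][1][1] * (1 - fx) + c[1][1][1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  double val = c0 * (1 - fz) + c1 * fz;
  if (want_grad) {
    // d/dx
    double g00 = c[1][0][0] - c[0][0][0];
    double g10 = c[1][1][0] - c[0][1][0];
    double g01 = c[1][0][1] - c[0][0][1];
    double g11 = c[1][1][1] - c[0][1][1];
    grad[0] = ((g00 * (1 - fy) + g10 * fy) * (1 - fz) +
               (g01 * (1 - fy) + g11 * fy) * fz);
    // d/dy
    grad[1] = ((c10 - c00) * (1 - fz) + (c11 - c01) * fz);
    // d/dz
    grad[2] = (c1 - c0);
  }
  return val;
}

// Shared geometry set-up for forward and backward passes.
struct RayCtx {
  double S[3];        // source position in C-arm frame
  double detz;        // detector plane z
  double ps, ppr, ppc;
  double Rt[9];       // transpose of pose rotation (cam -> world)
  double tv[3];       // pose translation
  double A[9], b[3];  // world -> voxel affine
  double cc[3];       // volume bounding-sphere center, camera frame
  double rho;         // bounding-sphere radius + margin
  double step;
};

static void setup_ctx(RayCtx& cx, NumericMatrix world2vox,
                      NumericMatrix Rpose, NumericVector tpose,
                      double f, double d_iso, double ps,
                      double ppr, double ppc,
                      NumericVector center_world, double radius,
                      double step) {
  cx.S[0] = 0.0; cx.S[1] = 0.0; cx.S[2] = -d_iso;
  cx.detz = f - d_iso;
  cx.ps = ps; cx.ppr = ppr; cx.ppc = ppc;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      cx.Rt[3 * i + j] = Rpose(j, i);
      cx.A[3 * i + j] = world2vox(i, j);
    }
  for (int i = 0; i < 3; ++i) {
    cx.tv[i] = tpose[i];
    cx.b[i] = world2vox(i, 3);
  }
  // bounding-sphere center in camera frame: R * cw + t
  for (int i = 0; i < 3; ++i) {
    cx.cc[i] = cx.tv[i];
    for (int j = 0; j < 3; ++j) cx.cc[i] += Rpose(i, j) * center_world[j];
  }
  cx.rho = radius + 2.0 * step;
  cx.step = step;
}

// [[Rcpp::export]]
NumericMatrix cpp_render_drr(NumericVector vol, IntegerVector dims,
                             NumericMatrix world2vox,
                             NumericMatrix Rpose, NumericVector tpose,
                             double f, double d_iso,
                             int nrow, int ncol, double ps,
                             double ppr, double ppc,
                             NumericVector center_world, double radius,
                             double step) {
  RayCtx cx;
  setup_ctx(cx, world2vox, Rpose, tpose, f, d_iso, ps, ppr, ppc,
            center_world, radius, step);
  const double* v = vol.begin();
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericMatrix out(nrow, ncol);
  for (int c = 0; c < ncol; ++c) {
    double px = (c - ppc) * ps;
    for (int r = 0; r < nrow; ++r) {
      double py = (r - ppr) * ps;
      double D[3] = {px - cx.S[0], py - cx.S[1], cx.detz - cx.S[2]};
      double L = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
      double dir[3] = {D[0] / L, D[1] / L, D[2] / L};
      double tc = dir[0] * (cx.cc[0] - cx.S[0]) + dir[1] * (cx.cc[1] - cx.S[1]) +
                  dir[2] * (cx.cc[2] - cx.S[2]);
      double t0 = tc - cx.rho, t1 = tc + cx.rho;
      if (t0 < 1e-6) t0 = 1e-6;
      if (t1 <= t0) continue;
      int n = (int)std::ceil((t1 - t0) / cx.step);
      double h = (t1 - t0) / n;
      double acc = 0.0;
      for (int s = 0; s < n; ++s) {
        double t = t0 + (s + 0.5) * h;
        double Xc[3] = {cx.S[0] + t * dir[0], cx.S[1] + t * dir[1],
                        cx.S[2] + t * dir[2]};
        // world point: R^T (Xc - t)
        double dc[3] = {Xc[0] - cx.tv[0], Xc[1] - cx.tv[1], Xc[2] - cx.tv[2]};
        double Xw[3];
        for (int i = 0; i < 3; ++i)
          Xw[i] = cx.Rt[3 * i] * dc[0] + cx.Rt[3 * i + 1] * dc[1] +
                  cx.Rt[3 * i + 2] * dc[2];
        double vx[3];
        for (int i = 0; i < 3; ++i)
          vx[i] = cx.A[3 * i] * Xw[0] + cx.A[3 * i + 1] * Xw[1] +
                  cx.A[3 * i + 2] * Xw[2] + cx.b[i];
        acc += trilinear(v, d1, d2, d3, vx[0], vx[1], vx[2], false, nullptr);
      }
      out(r, c) = acc * h;
    }
  }
  return out;
}

// Backward pass: given per-pixel upstream derivatives dL/dpixel, accumulate
//   s_tr  = sum w * grad_w V(Xw)          (world frame)
//   s_rot = sum w * (grad_w V(Xw) x Xw)   (world frame)
// with w = h * dLdp(r, c).  The R wrapper chains these with the tangent
// parametrization (right Jacobian / rotation of the local increment).
// [[Rcpp::export]]
NumericVector cpp_drr_backward(NumericVector vol, IntegerVector dims,
                               NumericMatrix world2vox,
                               NumericMatrix Rpose, NumericVector tpose,
                               double f, double d_iso,
                               int nrow, int ncol, double ps,
                               double ppr, double ppc,
                               NumericVector center_world, double radius,
                               double step, NumericMatrix dLdp) {
  RayCtx cx;
  setup_ctx(cx, world2vox, Rpose, tpose, f, d_iso, ps, ppr, ppc,
            center_world, radius, step);
  const double* v = vol.begin();
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  double s_rot[3] = {0, 0, 0}, s_tr[3] = {0, 0, 0};
  for (int c = 0; c < ncol; ++c) {
    double px = (c - ppc) * ps;
    for (int r = 0; r < nrow; ++r) {
      double u = dLdp(r, c);
      if (u == 0.0) continue;
      double py = (r - ppr) * ps;
      double D[3] = {px - cx.S[0], py - cx.S[1], cx.detz - cx.S[2]};
      double L = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
      double dir[3] = {D[0] / L, D[1] / L, D[2] / L};
      double tc = dir[0] * (cx.cc[0] - cx.S[0]) + dir[1] * (cx.cc[1] - cx.S[1]) +
                  dir[2] * (cx.cc[2] - cx.S[2]);
      double t0 = tc - cx.rho, t1 = tc + cx.rho;
      if (t0 < 1e-6) t0 = 1e-6;
      if (t1 <= t0) continue;
      int n = (int)std::ceil((t1 - t0) / cx.step);
      double h = (t1 - t0) / n;
      double w = h * u;
      for (int s = 0; s < n; ++s) {
        double t = t0 + (s + 0.5) * h;
        double Xc[3] = {cx.S[0] + t * dir[0], cx.S[1] + t * dir[1],
                        cx.S[2] + t * dir[2]};
        double dc[3] = {Xc[0] - cx.tv[0], Xc[1] - cx.tv[1], Xc[2] - cx.tv[2]};
        double Xw[3];
        for (int i = 0; i < 3; ++i)
          Xw[i] = cx.Rt[3 * i] * dc[0] + cx.Rt[3 * i + 1] * dc[1] +
                  cx.Rt[3 * i + 2] * dc[2];
        double vx[3];
        for (int i = 0; i < 3; ++i)
          vx[i] = cx.A[3 * i] * Xw[0] + cx.A[3 * i + 1] * Xw[1] +
                  cx.A[3 * i + 2] * Xw[2] + cx.b[i];
        double gv[3];
        double val = trilinear(v, d1, d2, d3, vx[0], vx[1], vx[2], true, gv);
        (void)val;
        if (gv[0] == 0.0 && gv[1] == 0.0 && gv[2] == 0.0) continue;
        // grad in world frame: A^T * grad_vox
        double gw[3];
        for (int i = 0; i < 3; ++i)
          gw[i] = cx.A[i] * gv[0] + cx.A[3 + i] * gv[1] + cx.A[6 + i] * gv[2];
        s_tr[0] += w * gw[0]; s_tr[1] += w * gw[1]; s_tr[2] += w * gw[2];
        s_rot[0] += w * (gw[1] * Xw[2] - gw[2] * Xw[1]);
        s_rot[1] += w * (gw[2] * Xw[0] - gw[0] * Xw[2]);
        s_rot[2] += w * (gw[0] * Xw[1] - gw[1] * Xw[0]);
      }
    }
  }
  NumericVector out(6);
  out[0] = s_rot[0]; out[1] = s_rot[1]; out[2] = s_rot[2];
  out[3] = s_tr[0];  out[4] = s_tr[1];  out[5] = s_tr[2];
  return out;
}
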
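// Core numerics: trilinear sampling, oriented template rendering,
// constrained grid-search alignment, 26-connectivity labeling.
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Trilinear interpolation at continuous 0-based (x,y,z); zero outside.
static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)nx || y >= (double)ny || z >= (double)nz)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        out += wx * wy * wz * v[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      }
    }
  }
  return out;
}

// Sum one rotated+shifted template copy per site into a volume.
// pos: n x 3 (0-based voxel coords), mats: n x 9 (column-major 3x3, local->tomo).
// [[Rcpp::export]]
NumericVector render_sites_cpp(IntegerVector dim, NumericMatrix pos,
                               NumericMatrix mats, NumericVector tpl,
                               IntegerVector tdim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((size_t)nx * ny * nz);
  double cx = (tx - 1) / 2.0, cy = (ty - 1) / 2.0, cz = (tz - 1) / 2.0;
  double rad = 0.5 * std::sqrt(3.0) * std::max(tx, std::max(ty, tz)) + 1.0;
  const double *tp = REAL(tpl);
  for (int s = 0; s < pos.nrow(); ++s) {
    double px = pos(s, 0), py = pos(s, 1), pz = pos(s, 2);
    double R[9];
    for (int k = 0; k < 9; ++k) R[k] = mats(s, k); // column-major
    int x0 = std::max(0, (int)std::ceil(px - rad));
    int x1 = std::min(nx - 1, (int)std::floor(px + rad));
    int y0 = std::max(0, (int)std::ceil(py - rad));
    int y1 = std::min(ny - 1, (int)std::floor(py + rad));
    int z0 = std::max(0, (int)std::ceil(pz - rad));
    int z1 = std::min(nz - 1, (int)std::floor(pz + rad));
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double dx = x - px, dy = y - py, dz = z - pz;
          // local = R^T * (v - p)   (R column-major: R[col*3+row])
          double lx = R[0] * dx + R[1] * dy + R[2] * dz;
          double ly = R[3] * dx + R[4] * dy + R[5] * dz;
          double lz = R[6] * dx + R[7] * dy + R[8] * dz;
          double val = trilinear(tp, tx, ty, tz, cx + lx, cy + ly, cz + lz);
          if (val != 0.0)
            out[x + (size_t)nx * (y + (size_t)ny * z)] += val;
        }
  }
  return out;
}

// Exhaustive masked-CC grid search around one prior pose.
// rots: 9 x nrot, each column a full candidate pose Q (local->tomo, col-major).
// shifts: nshift x 3 (must be integer-valued: they translate the extraction
// window on the tomogram grid). ref/mask share rdim; center is 0-based
// continuous. The subvolume is taken at raw grid voxels — all interpolation
// happens on the reference side, where the fractional part of the center is
// folded into the sampling coordinates. A volume rendered by one
// interpolation pass is then compared against a reference sampled by one
// interpolation pass, so the correlation optimum is not biased by
// asymmetric smoothing.
// Ties: larger cc; then smaller shift norm; then smaller rot-offset norm;
// then enumeration order (rotation-major, shift-minor).
// [[Rcpp::export]]
List grid_align_cpp(NumericVector tomo, IntegerVector dim, NumericVector center,
                    NumericMatrix rots, NumericVector rotnorm,
                    NumericMatrix shifts, NumericVector shiftnorm,
                    NumericVector ref, IntegerVector rdim, NumericVector mask,
                    int izero_rot, int izero_shift) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int bx = rdim[0], by = rdim[1], bz = rdim[2];
  size_t nvox = (size_t)bx * by * bz;
  int nrot = rots.ncol(), nshift = shifts.nrow();
  double cx = (bx - 1) / 2.0, cy = (by - 1) / 2.0, cz = (bz - 1) / 2.0;
  const double *tp = REAL(tomo), *rp = REAL(ref);

  arma::vec m(REAL(mask), nvox);
  double sumw = arma::accu(m);

  int base[3];
  double frac[3];
  for (int k = 0; k < 3; ++k) {
    base[k] = (int)std::lround(center[k]);
    frac[k] = center[k] - base[k];
  }

  // subvolumes at raw grid voxels, one row per (integer) shift
  arma::mat A(nshift, nvox);
  for (int s = 0; s < nshift; ++s) {
    int ox = base[0] + (int)std::lround(shifts(s, 0));
    int oy = base[1] + (int)std::lround(shifts(s, 1));
    int oz = base[2] + (int)std::lround(shifts(s, 2));
    int hx = (bx - 1) / 2, hy = (by - 1) / 2, hz = (bz - 1) / 2;
    size_t q = 0;
    for (int z = 0; z < bz; ++z)
      for (int y = 0; y < by; ++y)
        for (int x = 0; x < bx; ++x, ++q) {
          int xx = ox + x - hx, yy = oy + y - hy, zz = oz + z - hz;
          A(s, q) = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                     zz >= nz)
                        ? 0.0
                        : tp[xx + (size_t)nx * (yy + (size_t)ny * zz)];
        }
  }
  // rotated references, one row per rotation; the fractional center offset
  // enters the sampling coordinates (window voxel minus continuous center)
  int hx = (bx - 1) / 2, hy = (by - 1) / 2, hz = (bz - 1) / 2;
  arma::mat B(nrot, nvox);
  for (int r = 0; r < nrot; ++r) {
    double R[9];
    for (int k = 0; k < 9; ++k) R[k] = rots(k, r);
    size_t q = 0;
    for (int z = 0; z < bz; ++z)
      for (int y = 0; y < by; ++y)
        for (int x = 0; x < bx; ++x, ++q) {
          double dx = (x - hx) - frac[0];
          double dy = (y - hy) - frac[1];
          double dz = (z - hz) - frac[2];
          double lx = R[0] * dx + R[1] * dy + R[2] * dz;
          double ly = R[3] * dx + R[4] * dy + R[5] * dz;
          double lz = R[6] * dx + R[7] * dy + R[8] * dz;
          B(r, q) = trilinear(rp, bx, by, bz, cx + lx, cy + ly, cz + lz);
        }
  }

  arma::vec sa = A * m, sb = B * m;
  arma::vec saa = (A % A) * m, sbb = (B % B) * m;
  arma::mat Bm = B.each_row() % m.t();
  arma::mat cross = Bm * A.t(); // nrot x nshift

  arma::vec va = saa - arma::square(sa) / sumw;
  arma::vec vb = sbb - arma::square(sb) / sumw;

  const double vtol = 1e-12, ctol = 1e-12;
  int bi = 0, bj = 0;
  double bcc = -2.0, bsn = R_PosInf, brn = R_PosInf;
  double cc0 = 0.0;
  NumericVector rot_best_cc(nrot), rot_best_shift(nrot);
  for (int i = 0; i < nrot; ++i) {
    double rb = -2.0; int rbj = 0;
    for (int j = 0; j < nshift; ++j) {
      double cc;
      if (vb[i] < vtol || va[j] < vtol)
        cc = 0.0;
      else
        cc = (cross(i, j) - sb[i] * sa[j] / sumw) / std::sqrt(vb[i] * va[j]);
      if (i == izero_rot && j == izero_shift) cc0 = cc;
      if (cc > rb + ctol ||
          (cc > rb - ctol && shiftnorm[j] < shiftnorm[rbj] - ctol)) {
        rb = cc; rbj = j;
      }
      bool take = false;
      if (cc > bcc + ctol)
        take = true;
      else if (cc > bcc - ctol) {
        if (shiftnorm[j] < bsn - ctol)
          take = true;
        else if (shiftnorm[j] < bsn + ctol && rotnorm[i] < brn - ctol)
          take = true;
      }
      if (take) {
        bi = i; bj = j; bcc = cc;
        bsn = shiftnorm[j]; brn = rotnorm[i];
      }
    }
    rot_best_cc[i] = rb;
    rot_best_shift[i] = rbj + 1;
  }
  return List::create(_["irot"] = bi + 1, _["ishift"] = bj + 1,
                      _["cc"] = bcc, _["cc_prior"] = cc0,
                      _["rot_best_cc"] = rot_best_cc,
                      _["rot_best_shift"] = rot_best_shift);
}

// Masked CC of the subvolume around a continuous center against the
// reference rotated by pose Q (column-major). Used by the sub-grid polish.
// [[Rcpp::export]]
double cc_at_pose_cpp(NumericVector tomo, IntegerVector dim,
                      NumericVector center, NumericVector Q,
                      NumericVector ref, IntegerVector rdim,
                      NumericVector mask) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int bx = rdim[0], by = rdim[1], bz = rdim[2];
  double cx = (bx - 1) / 2.0, cy = (by - 1) / 2.0, cz = (bz - 1) / 2.0;
  const double *tp = REAL(tomo), *rp = REAL(ref), *mp = REAL(mask);
  double R[9];
  for (int k = 0; k < 9; ++k) R[k] = Q[k];
  int base[3];
  double frac[3];
  for (int k = 0; k < 3; ++k) {
    base[k] = (int)std::lround(center[k]);
    frac[k] = center[k] - base[k];
  }
  int hx = (bx - 1) / 2, hy = (by - 1) / 2, hz = (bz - 1) / 2;
  double sumw = 0, sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  size_t q = 0;
  for (int z = 0; z < bz; ++z)
    for (int y = 0; y < by; ++y)
      for (int x = 0; x < bx; ++x, ++q) {
        double w = mp[q];
        if (w == 0.0) continue;
        int xx = base[0] + x - hx, yy = base[1] + y - hy,
            zz = base[2] + z - hz;
        double a = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                    zz >= nz)
                       ? 0.0
                       : tp[xx + (size_t)nx * (yy + (size_t)ny * zz)];
        double dx = (x - hx) - frac[0], dy = (y - hy) - frac[1],
               dz = (z - hz) - frac[2];
        double lx = R[0] * dx + R[1] * dy + R[2] * dz;
        double ly = R[3] * dx + R[4] * dy + R[5] * dz;
        double lz = R[6] * dx + R[7] * dy + R[8] * dz;
        double b = trilinear(rp, bx, by, bz, cx + lx, cy + ly, cz + lz);
        sumw += w; sa += w * a; sb += w * b;
        saa += w * a * a; sbb += w * b * b; sab += w * a * b;
      }
  double va = saa - sa * sa / sumw, vb = sbb - sb * sb / sumw;
  if (va < 1e-12 || vb < 1e-12) return 0.0;
  return (sab - sa * sb / sumw) / std::sqrt(va * vb);
}

// Batched variant of cc_at_pose_cpp: one pose per column of Qs.
// [[Rcpp::export]]
NumericVector cc_at_poses_cpp(NumericVector tomo, IntegerVector dim,
                              NumericVector center, NumericMatrix Qs,
                              NumericVector ref, IntegerVector rdim,
                              NumericVector mask) {
  int n = Qs.ncol();
  NumericVector out(n);
  NumericVector q(9);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 9; ++k) q[k] = Qs(k, i);
    out[i] = cc_at_pose_cpp(tomo, dim, center, q, ref, rdim, mask);
  }
  return out;
}

// 26-connectivity labeling of a binary volume. Returns integer labels
// (0 = background), same length as the input.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < n; ++i) {
    if (!vol[i] || lab[i]) continue;
    lab[i] = ++cur;
    stack.push_back(i);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            size_t w = xx + (size_t)nx * (yy + (size_t)ny * zz);
            if (vol[w] && !lab[w]) {
              lab[w] = cur;
              stack.push_back(w);
            }
          }
    }
  }
  return lab;
}

// Trilinear probe used by tests and by the renderer's oracle path.
// [[Rcpp::export]]
NumericVector trilinear_sample_cpp(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *vp = REAL(vol);
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = trilinear(vp, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}
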
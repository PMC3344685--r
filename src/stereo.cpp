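#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Voxel labels shared with the R side: 1 lumen, 2 epithelium, 3 stroma.
// Voxel (i,j,k) (0-based) has its physical center at ((i+0.5)*vs, ...).

// Label a voxel grid with straight capped cylinders ("tubules").
// tubes: one row per tubule: x0,y0,z0, x1,y1,z1, r_in, r_out (mm).
// A tubule claims a voxel when the voxel center lies within r_out of its
// centerline segment; among claimants the nearest centerline wins (ties go
// to the earlier row, which makes the result order-deterministic). Claimed
// voxels are lumen when the axial projection falls inside [0, L] and the
// radial distance is <= r_in, otherwise epithelium — so the end caps are
// epithelium and tubules are closed.
// [[Rcpp::export]]
IntegerVector cpp_label_tubules(IntegerVector dims, double vs,
                                NumericMatrix tubes) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 3);
  std::vector<float> best(n, std::numeric_limits<float>::max());

  for (int t = 0; t < tubes.nrow(); ++t) {
    const double p0x = tubes(t, 0), p0y = tubes(t, 1), p0z = tubes(t, 2);
    const double p1x = tubes(t, 3), p1y = tubes(t, 4), p1z = tubes(t, 5);
    const double rin = tubes(t, 6), rout = tubes(t, 7);
    const double dx = p1x - p0x, dy = p1y - p0y, dz = p1z - p0z;
    const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double ux = L > 0 ? dx / L : 0.0;
    const double uy = L > 0 ? dy / L : 0.0;
    const double uz = L > 0 ? dz / L : 0.0;
    const double step = 0.5 * vs;
    const int nsteps = L > 0 ? (int)std::ceil(L / step) : 0;
    const double pad = rout + vs;  // covers every voxel the segment can claim

    for (int s = 0; s <= nsteps; ++s) {
      const double tt = std::min(L, s * step);
      const double cx = p0x + ux * tt, cy = p0y + uy * tt, cz = p0z + uz * tt;
      const int i0 = std::max(0, (int)std::floor((cx - pad) / vs - 0.5));
      const int i1 = std::min(nx - 1, (int)std::ceil((cx + pad) / vs - 0.5));
      const int j0 = std::max(0, (int)std::floor((cy - pad) / vs - 0.5));
      const int j1 = std::min(ny - 1, (int)std::ceil((cy + pad) / vs - 0.5));
      const int k0 = std::max(0, (int)std::floor((cz - pad) / vs - 0.5));
      const int k1 = std::min(nz - 1, (int)std::ceil((cz + pad) / vs - 0.5));
      for (int k = k0; k <= k1; ++k) {
        const double vz = (k + 0.5) * vs;
        for (int j = j0; j <= j1; ++j) {
          const double vy = (j + 0.5) * vs;
          for (int i = i0; i <= i1; ++i) {
            const double vx = (i + 0.5) * vs;
            const double wx = vx - p0x, wy = vy - p0y, wz = vz - p0z;
            const double tp = wx * ux + wy * uy + wz * uz;
            const double tcl = std::min(L, std::max(0.0, tp));
            const double ex = wx - ux * tcl, ey = wy - uy * tcl,
                         ez = wz - uz * tcl;
            const double d = std::sqrt(ex * ex + ey * ey + ez * ez);
            if (d <= rout) {
              const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
              if (d < best[idx]) {
                best[idx] = (float)d;
                lab[idx] = (tp >= 0.0 && tp <= L && d <= rin) ? 1 : 2;
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

// Label a voxel grid with concentric spherical shells ("ball suspension"):
// core (r <= r_in) is lumen, shell (r_in < r <= r_out) epithelium.
// balls: one row per ball: cx, cy, cz, r_in, r_out (mm).
// [[Rcpp::export]]
IntegerVector cpp_label_balls(IntegerVector dims, double vs,
                              NumericMatrix balls) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 3);
  std::vector<float> best(n, std::numeric_limits<float>::max());

  for (int b = 0; b < balls.nrow(); ++b) {
    const double cx = balls(b, 0), cy = balls(b, 1), cz = balls(b, 2);
    const double rin = balls(b, 3), rout = balls(b, 4);
    const double pad = rout + vs;
    const int i0 = std::max(0, (int)std::floor((cx - pad) / vs - 0.5));
    const int i1 = std::min(nx - 1, (int)std::ceil((cx + pad) / vs - 0.5));
    const int j0 = std::max(0, (int)std::floor((cy - pad) / vs - 0.5));
    const int j1 = std::min(ny - 1, (int)std::ceil((cy + pad) / vs - 0.5));
    const int k0 = std::max(0, (int)std::floor((cz - pad) / vs - 0.5));
    const int k1 = std::min(nz - 1, (int)std::ceil((cz + pad) / vs - 0.5));
    for (int k = k0; k <= k1; ++k) {
      const double vz = (k + 0.5) * vs - cz;
      for (int j = j0; j <= j1; ++j) {
        const double vy = (j + 0.5) * vs - cy;
        for (int i = i0; i <= i1; ++i) {
          const double vx = (i + 0.5) * vs - cx;
          const double d = std::sqrt(vx * vx + vy * vy + vz * vz);
          if (d <= rout) {
            const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            if (d < best[idx]) {
              best[idx] = (float)d;
              lab[idx] = d <= rin ? 1 : 2;
            }
          }
        }
      }
    }
  }
  return lab;
}

// Count voxel faces separating label a from label b (either order) along the
// three grid axes. Multiplied by vs^2 on the R side this gives the "naive"
// digitized interface area, which overestimates smooth surfaces by a
// direction-averaged factor of 3/2 (calibrated on digital spheres).
// [[Rcpp::export]]
double cpp_face_count(IntegerVector lab, IntegerVector dims, int a, int b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double faces = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        const int l0 = lab[idx];
        if (i + 1 < nx) {
          const int l1 = lab[idx + 1];
          if ((l0 == a && l1 == b) || (l0 == b && l1 == a)) faces += 1.0;
        }
        if (j + 1 < ny) {
          const int l1 = lab[idx + nx];
          if ((l0 == a && l1 == b) || (l0 == b && l1 == a)) faces += 1.0;
        }
        if (k + 1 < nz) {
          const int l1 = lab[idx + (R_xlen_t)nx * ny];
          if ((l0 == a && l1 == b) || (l0 == b && l1 == a)) faces += 1.0;
        }
      }
  return faces;
}

// Connected component labeling of a binary image (column-major, nr x nc)
// with 4- or 8-connectivity. Returns 0 for background, 1..n for components.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector img, int nr, int nc,
                                   int conn = 4) {
  IntegerVector out((R_xlen_t)nr * nc, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int nq = conn == 8 ? 8 : 4;
  for (R_xlen_t start = 0; start < (R_xlen_t)nr * nc; ++start) {
    if (img[start] == 0 || out[start] != 0) continue;
    ++next;
    stack.push_back(start);
    out[start] = next;
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int i = (int)(p % nr), j = (int)(p / nr);
      const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1},
                dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
      for (int q = 0; q < nq; ++q) {
        const int ii = i + di[q], jj = j + dj[q];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const R_xlen_t pp = ii + (R_xlen_t)nr * jj;
        if (img[pp] != 0 && out[pp] == 0) {
          out[pp] = next;
          stack.push_back(pp);
        }
      }
    }
  }
  return out;
}
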
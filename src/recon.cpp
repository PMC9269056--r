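// Ray-driven reconstruction kernels: exact-length voxel traversal (Siddon /
// Amanatides-Woo), back-projection, list-mode MLEM with an optional median
// root prior, and small event-stream utilities.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Traverse the segment p0 -> p1 through a regular grid with `n` voxels per
// axis, voxel sizes `vs` and lower corner `v0`; append crossed voxel indices
// (0-based, ix + nx*iy + nx*ny*iz) and exact intersection lengths.
static void ray_trace(const double p0[3], const double p1[3],
                      const int n[3], const double v0[3], const double vs[3],
                      std::vector<int> &idx, std::vector<double> &len) {
  double d[3], L2 = 0.0;
  for (int a = 0; a < 3; ++a) { d[a] = p1[a] - p0[a]; L2 += d[a] * d[a]; }
  const double L = std::sqrt(L2);
  if (L <= 0.0) return;

  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    const double lo = v0[a], hi = v0[a] + n[a] * vs[a];
    if (d[a] == 0.0) {
      if (p0[a] < lo || p0[a] >= hi) return;
    } else {
      double t1 = (lo - p0[a]) / d[a];
      double t2 = (hi - p0[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1);
      tmax = std::min(tmax, t2);
    }
  }
  if (tmin >= tmax) return;

  const double eps = 1e-12;
  int i[3], step[3];
  double tNext[3], tDelta[3];
  for (int a = 0; a < 3; ++a) {
    const double s = p0[a] + (tmin + eps) * d[a];
    int ii = (int)std::floor((s - v0[a]) / vs[a]);
    if (ii < 0) ii = 0;
    if (ii >= n[a]) ii = n[a] - 1;
    i[a] = ii;
    if (d[a] > 0.0) {
      step[a] = 1;
      tNext[a] = ((ii + 1) * vs[a] + v0[a] - p0[a]) / d[a];
      tDelta[a] = vs[a] / d[a];
    } else if (d[a] < 0.0) {
      step[a] = -1;
      tNext[a] = (ii * vs[a] + v0[a] - p0[a]) / d[a];
      tDelta[a] = -vs[a] / d[a];
    } else {
      step[a] = 0;
      tNext[a] = R_PosInf;
      tDelta[a] = R_PosInf;
    }
  }

  double tcur = tmin;
  const int nxy = n[0] * n[1];
  while (tcur < tmax - 1e-15) {
    int amin = 0;
    if (tNext[1] < tNext[amin]) amin = 1;
    if (tNext[2] < tNext[amin]) amin = 2;
    const double tn = std::min(tNext[amin], tmax);
    const double seg = (tn - tcur) * L;
    if (seg > 0.0) {
      idx.push_back(i[0] + n[0] * i[1] + nxy * i[2]);
      len.push_back(seg);
    }
    tcur = tn;
    if (tn >= tmax) break;
    i[amin] += step[amin];
    if (i[amin] < 0 || i[amin] >= n[amin]) break;
    tNext[amin] += tDelta[amin];
  }
}

static void unpack_grid(const IntegerVector &dims, const NumericVector &vsize,
                        const NumericVector &origin, int n[3], double vs[3],
                        double v0[3]) {
  for (int a = 0; a < 3; ++a) {
    n[a] = dims[a];
    vs[a] = vsize[a];
    v0[a] = origin[a];
  }
}

// Voxel indices (1-based) and intersection lengths for one ray.
// [[Rcpp::export]]
List cpp_ray_lengths(NumericVector p0, NumericVector p1, IntegerVector dims,
                     NumericVector vsize, NumericVector origin) {
  int n[3]; double vs[3], v0[3];
  unpack_grid(dims, vsize, origin, n, vs, v0);
  double a[3] = {p0[0], p0[1], p0[2]}, b[3] = {p1[0], p1[1], p1[2]};
  std::vector<int> idx; std::vector<double> len;
  ray_trace(a, b, n, v0, vs, idx, len);
  IntegerVector ri(idx.size());
  NumericVector rl(len.size());
  for (size_t k = 0; k < idx.size(); ++k) { ri[k] = idx[k] + 1; rl[k] = len[k]; }
  return List::create(_["index"] = ri, _["length"] = rl);
}

// Back-projection: each LOR adds its exact intersection length to every
// voxel it crosses. Endpoints are (x1,y1,zA) and (x2,y2,zB).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericMatrix ep, double zA, double zB,
                              IntegerVector dims, NumericVector vsize,
                              NumericVector origin) {
  int n[3]; double vs[3], v0[3];
  unpack_grid(dims, vsize, origin, n, vs, v0);
  NumericVector img((R_xlen_t)n[0] * n[1] * n[2]);
  std::vector<int> idx; std::vector<double> len;
  for (int e = 0; e < ep.nrow(); ++e) {
    double a[3] = {ep(e, 0), ep(e, 1), zA};
    double b[3] = {ep(e, 2), ep(e, 3), zB};
    idx.clear(); len.clear();
    ray_trace(a, b, n, v0, vs, idx, len);
    for (size_t k = 0; k < idx.size(); ++k) img[idx[k]] += len[k];
  }
  return img;
}

// 3x3x3 median filter with clamped borders.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector arr, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> buf;
  buf.reserve(27);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        buf.clear();
        for (int dz = -1; dz <= 1; ++dz) {
          int z = std::min(std::max(iz + dz, 0), nz - 1);
          for (int dy = -1; dy <= 1; ++dy) {
            int y = std::min(std::max(iy + dy, 0), ny - 1);
            for (int dx = -1; dx <= 1; ++dx) {
              int x = std::min(std::max(ix + dx, 0), nx - 1);
              buf.push_back(arr[x + nx * y + nx * ny * z]);
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + 13, buf.end());
        out[ix + nx * iy + nx * ny * iz] = buf[13];
      }
  return out;
}

// List-mode MLEM with optional median root prior. `sens` has length
// nx*ny*nz (or length 0 for a uniform sensitivity of 1). Returns the image
// and the Poisson log-likelihood evaluated at the start of each iteration.
// [[Rcpp::export]]
List cpp_mlem(NumericMatrix ep, double zA, double zB, IntegerVector dims,
              NumericVector vsize, NumericVector origin, int niter,
              NumericVector sens, double beta, bool use_mrp) {
  int n[3]; double vs[3], v0[3];
  unpack_grid(dims, vsize, origin, n, vs, v0);
  const R_xlen_t nvox = (R_xlen_t)n[0] * n[1] * n[2];
  const int nev = ep.nrow();
  const bool have_sens = sens.size() == nvox;

  // precompute sparse system rows
  std::vector<size_t> off(nev + 1, 0);
  std::vector<int> idx;
  std::vector<double> len;
  {
    std::vector<int> ti; std::vector<double> tl;
    for (int e = 0; e < nev; ++e) {
      double a[3] = {ep(e, 0), ep(e, 1), zA};
      double b[3] = {ep(e, 2), ep(e, 3), zB};
      ti.clear(); tl.clear();
      ray_trace(a, b, n, v0, vs, ti, tl);
      idx.insert(idx.end(), ti.begin(), ti.end());
      len.insert(len.end(), tl.begin(), tl.end());
      off[e + 1] = idx.size();
    }
  }

  NumericVector lambda(nvox, 1.0);
  NumericVector loglik(niter);
  std::vector<double> num(nvox);

  for (int it = 0; it < niter; ++it) {
    std::fill(num.begin(), num.end(), 0.0);
    double ll = 0.0;
    for (int e = 0; e < nev; ++e) {
      double p = 0.0;
      for (size_t k = off[e]; k < off[e + 1]; ++k) p += len[k] * lambda[idx[k]];
      if (p <= 0.0) continue;
      ll += std::log(p);
      const double inv = 1.0 / p;
      for (size_t k = off[e]; k < off[e + 1]; ++k) num[idx[k]] += len[k] * inv;
    }
    double expected = 0.0;
    for (R_xlen_t j = 0; j < nvox; ++j)
      expected += (have_sens ? sens[j] : 1.0) * lambda[j];
    loglik[it] = ll - expected;

    for (R_xlen_t j = 0; j < nvox; ++j) {
      const double s = have_sens ? sens[j] : 1.0;
      lambda[j] = s > 0.0 ? lambda[j] * num[j] / s : 0.0;
      if (!std::isfinite(lambda[j]))
        stop("MLEM diverged: non-finite voxel at iteration %d", it + 1);
    }

    if (use_mrp && beta > 0.0) {
      NumericVector med = cpp_median_filter3(lambda, dims);
      for (R_xlen_t j = 0; j < nvox; ++j) {
        const double m = med[j];
        if (m > 0.0) {
          lambda[j] = lambda[j] / (1.0 + beta * (lambda[j] - m) / m);
          if (lambda[j] < 0.0) lambda[j] = 0.0;
          if (!std::isfinite(lambda[j]))
            stop("MRP produced a non-finite voxel at iteration %d", it + 1);
        }
      }
    }
  }
  return List::create(_["lambda"] = lambda, _["loglik"] = loglik);
}

// Non-paralyzable dead time: an accepted event blocks the detector for tau;
// events arriving while blocked are dropped and do not extend the block.
// [[Rcpp::export]]
LogicalVector cpp_nonparalyzable_keep(NumericVector t, double tau) {
  const int n = t.size();
  LogicalVector keep(n);
  double free_at = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (t[i] >= free_at) {
      keep[i] = true;
      free_at = t[i] + tau;
    } else {
      keep[i] = false;
    }
  }
  return keep;
}
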
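// Low-level voxel kernels: exact Euclidean distance transform, connected
// components, hole filling, local-thickness sphere painting, ball/tube
// voxelisation, and batched 3x3 symmetric eigendecomposition.
#include <RcppArmadillo.h>
#include <queue>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DINF = std::numeric_limits<double>::infinity();

// 1D lower-envelope-of-parabolas distance transform (squared distances).
// Sites with f == INF carry no information and are skipped.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = -1;
  for (int q = 0; q < n; q++) {
    if (f[q] == DINF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DINF; z[1] = DINF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        k--;
        if (k < 0) break;
      } else break;
    }
    k++; v[k] = q; z[k] = s; z[k + 1] = DINF;
  }
  if (k < 0) { for (int q = 0; q < n; q++) d[q] = DINF; return; }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < q) j++;
    d[q] = (double)(q - v[j]) * (q - v[j]) + f[v[j]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// FALSE voxel of `mask`. Voxels outside the grid are ignored (treat the
// grid as the whole world); pad in R to impose a background border.
// Integer-valued squared distances are exact in doubles.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; i++) d[i] = mask[i] ? DINF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t off = (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
      for (int i = 0; i < nx; i++) f[i] = d[off + i];
      dt1d(f, g, v, z, nx);
      for (int i = 0; i < nx; i++) d[off + i] = g[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t off = (R_xlen_t)i + (R_xlen_t)k * nx * ny;
      for (int j = 0; j < ny; j++) f[j] = d[off + (R_xlen_t)j * nx];
      dt1d(f, g, v, z, ny);
      for (int j = 0; j < ny; j++) d[off + (R_xlen_t)j * nx] = g[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t off = (R_xlen_t)i + (R_xlen_t)j * nx;
      for (int k = 0; k < nz; k++) f[k] = d[off + (R_xlen_t)k * nx * ny];
      dt1d(f, g, v, z, nz);
      for (int k = 0; k < nz; k++) d[off + (R_xlen_t)k * nx * ny] = g[k];
    }
  return d;
}

static void neighbour_offsets(int connectivity, int nx, int ny,
                              std::vector<std::array<int,3>>& offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

// Connected-component labelling (6, 18 or 26 connectivity); labels start
// at 1 in scan order, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  neighbour_offsets(connectivity, nx, ny, offs);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / ((R_xlen_t)nx * ny);
      for (auto& o : offs) {
        int x = cx + o[0], y = cy + o[1], z = cz + o[2];
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
        R_xlen_t idx = (R_xlen_t)x + (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny;
        if (mask[idx] && lab[idx] == 0) { lab[idx] = next; q.push(idx); }
      }
    }
  }
  return lab;
}

// Fill interior cavities: background components (6-connected) not touching
// the grid border become foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector inv(n);
  for (R_xlen_t i = 0; i < n; i++) inv[i] = !mask[i];
  IntegerVector lab = label_components_cpp(inv, dim, 6);
  int nlab = 0;
  for (R_xlen_t i = 0; i < n; i++) if (lab[i] > nlab) nlab = lab[i];
  std::vector<bool> touches(nlab + 1, false);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        int l = lab[(R_xlen_t)i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny];
        if (l > 0) touches[l] = true;
      }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = mask[i] || (lab[i] > 0 && !touches[lab[i]]);
  return out;
}

// Local thickness by sphere painting from every foreground voxel: the
// sphere centred at c of radius sqrt(r2[c]) covers x iff |x-c|^2 < r2[c].
// Returns, per voxel, the largest r2 among covering spheres (0 off support).
// r2 must be the squared distance to the nearest background voxel
// (border included), so spheres never protrude from the mask.
// [[Rcpp::export]]
NumericVector thickness_paint_cpp(LogicalVector mask, IntegerVector dim,
                                  NumericVector r2) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th2(n, 0.0);
  for (int cz = 0; cz < nz; cz++)
    for (int cy = 0; cy < ny; cy++)
      for (int cx = 0; cx < nx; cx++) {
        R_xlen_t c = (R_xlen_t)cx + (R_xlen_t)cy * nx + (R_xlen_t)cz * nx * ny;
        if (!mask[c]) continue;
        double rr = r2[c];
        if (rr <= 0) continue;
        int r = (int)std::floor(std::sqrt(rr));
        int x0 = std::max(0, cx - r), x1 = std::min(nx - 1, cx + r);
        int y0 = std::max(0, cy - r), y1 = std::min(ny - 1, cy + r);
        int z0 = std::max(0, cz - r), z1 = std::min(nz - 1, cz + r);
        for (int z = z0; z <= z1; z++)
          for (int y = y0; y <= y1; y++) {
            double dzy = (double)(z - cz) * (z - cz) +
                         (double)(y - cy) * (y - cy);
            if (dzy >= rr) continue;
            R_xlen_t row = (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny;
            for (int x = x0; x <= x1; x++) {
              double dd = dzy + (double)(x - cx) * (x - cx);
              if (dd < rr && th2[row + x] < rr) th2[row + x] = rr;
            }
          }
      }
  return th2;
}

// Voxelise a union of balls: voxel (0-based integer centre) is set iff its
// centre lies within radius r_i of some point p_i. Points and radii are in
// voxel units. Densely sampled polylines painted this way realise the
// "voxel centre within radius of the centreline" rule.
// [[Rcpp::export]]
LogicalVector paint_balls_cpp(NumericMatrix pts, NumericVector radii,
                              IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  for (int i = 0; i < pts.nrow(); i++) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double r = radii[i], r2 = r * r;
    int x0 = std::max(0, (int)std::ceil(px - r));
    int x1 = std::min(nx - 1, (int)std::floor(px + r));
    int y0 = std::max(0, (int)std::ceil(py - r));
    int y1 = std::min(ny - 1, (int)std::floor(py + r));
    int z0 = std::max(0, (int)std::ceil(pz - r));
    int z1 = std::min(nz - 1, (int)std::floor(pz + r));
    for (int z = z0; z <= z1; z++)
      for (int y = y0; y <= y1; y++) {
        double dzy = (z - pz) * (z - pz) + (y - py) * (y - py);
        if (dzy > r2) continue;
        R_xlen_t row = (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny;
        for (int x = x0; x <= x1; x++)
          if (dzy + (x - px) * (x - px) <= r2) out[row + x] = true;
      }
  }
  return out;
}

// Batched symmetric 3x3 eigendecomposition. S columns: xx, yy, zz, xy, xz,
// yz. Returns minor eigenvectors (rows) and eigenvalues in descending order.
// [[Rcpp::export]]
List minor_eigs_cpp(NumericMatrix S) {
  int n = S.nrow();
  NumericMatrix p(n, 3);
  NumericMatrix mu(n, 3);
  arma::mat33 M;
  arma::vec3 ev;
  arma::mat33 V;
  for (int i = 0; i < n; i++) {
    M(0,0) = S(i,0); M(1,1) = S(i,1); M(2,2) = S(i,2);
    M(0,1) = M(1,0) = S(i,3);
    M(0,2) = M(2,0) = S(i,4);
    M(1,2) = M(2,1) = S(i,5);
    arma::eig_sym(ev, V, M);   // ascending
    p(i,0) = V(0,0); p(i,1) = V(1,0); p(i,2) = V(2,0);
    mu(i,0) = ev(2); mu(i,1) = ev(1); mu(i,2) = ev(0);
  }
  return List::create(Named("p") = p, Named("mu") = mu);
}
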